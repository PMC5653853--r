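#' Pipeline configuration
#'
#' Collects paths and thresholds for [run_pipeline()]. All thresholds default
#' to the standard regime: >1% frequency, >=100x coverage, mean-Q30/length-50
#' read filter, six-configuration grid with a 2-SD agreement band.
#'
#' @param reference Path to the reference FASTA, or a [reference_genome()].
#' @param r1,r2 Paired FASTQ paths (ignored when `reads` given).
#' @param sam Path(s) to externally mapped SAM file(s); when given, the
#'   internal aligner is skipped and one SAM per configuration-grid row is
#'   expected (or a single SAM shared by all rows).
#' @param annotation Optional GFF3 path or [gene_annotation()].
#' @param reads Optional in-memory `read_set` (overrides `r1`/`r2`).
#' @param outdir Output directory.
#' @param min_freq,min_depth,k_sd Calling thresholds (see
#'   [run_multi_config()]).
#' @param qc_min_mean_q,qc_min_len Read-filter thresholds (see
#'   [variant_read_filter()]).
#' @param trim Apply sliding-window trimming during QC.
#' @param grid Configuration grid (see [run_multi_config()]).
#' @param max_span,min_informative Co-occurrence settings (see
#'   [cooccurrence_matrix()]).
#' @param k,step,max_mismatch_frac Aligner settings.
#' @param seed Integer seed recorded in output headers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference, r1 = NULL, r2 = NULL, sam = NULL,
                            annotation = NULL, reads = NULL,
                            outdir = tempfile("quasipop_run_"),
                            min_freq = 0.01, min_depth = 100L, k_sd = 2,
                            qc_min_mean_q = 30, qc_min_len = 50L,
                            trim = TRUE, grid = default_config_grid(),
                            max_span = 900L, min_informative = 20L,
                            k = 21L, step = 10L, max_mismatch_frac = 0.1,
                            seed = 1L) {
  if (!(min_freq > 0 && min_freq < 1))
    stop("min_freq must be strictly between 0 and 1")
  if (min_depth < 1L) stop("min_depth must be positive")
  if (k_sd <= 0) stop("k_sd must be positive")
  structure(list(reference = reference, r1 = r1, r2 = r2, sam = sam,
                 annotation = annotation, reads = reads, outdir = outdir,
                 min_freq = min_freq, min_depth = as.integer(min_depth),
                 k_sd = k_sd, qc_min_mean_q = qc_min_mean_q,
                 qc_min_len = as.integer(qc_min_len), trim = trim,
                 grid = as.data.frame(grid), max_span = as.integer(max_span),
                 min_informative = as.integer(min_informative),
                 k = as.integer(k), step = as.integer(step),
                 max_mismatch_frac = max_mismatch_frac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # outdir excluded so identical analyses hash identically wherever written
  js <- jsonlite::toJSON(config[setdiff(names(config), c("reads", "outdir"))],
                         auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' QC -> alignment (or SAM ingest) -> pileup -> sample consensus ->
#' multi-configuration calling with the 2-SD agreement filter -> pairwise
#' co-occurrence -> gene-module annotation. Writes `calls.vcf`, `calls.tsv`,
#' `cooccurrence.tsv`, `category_summary.tsv` (when an annotation is given)
#' and `run_log.txt`; every output carries the configuration hash and seed.
#' Stage failures abort with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return list: `calls` (all sites), `pass` (PASS subset), `consensus`,
#'   `cooccurrence`, `annotated`, `category_summary`, `qc_stats`, `paths`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  hash <- config_hash(config)
  note("quasipop %s | config %s | seed %d",
       as.character(utils::packageVersion("quasipop")), hash, config$seed)

  ref <- stage("reference", {
    if (inherits(config$reference, "reference_genome")) config$reference
    else read_reference(config$reference)
  })
  ann <- stage("annotation", {
    if (is.null(config$annotation)) NULL
    else if (inherits(config$annotation, "gene_annotation")) config$annotation
    else read_annotation(config$annotation, genome_length = ref$length)
  })

  if (!is.null(config$sam)) {
    aln <- stage("sam_ingest", {
      sams <- lapply(config$sam, read_sam, reference = ref)
      note("SAM ingest: %d file(s)", length(sams))
      if (length(sams) == 1L) sams[[1L]] else sams
    })
  } else {
    reads <- stage("reads", {
      if (!is.null(config$reads)) config$reads
      else read_fastq_pair(config$r1, config$r2)
    })
    reads <- stage("qc", {
      out <- qc_read_set(reads, trim = config$trim,
                         min_mean_q = config$qc_min_mean_q,
                         min_len = config$qc_min_len)
      st <- attr(out, "qc_stats")
      note("qc: %d/%d pairs kept, %d/%d bases kept", st$pairs_kept,
           st$pairs_in, st$bases_kept, st$bases_in)
      out
    })
    qc_stats <- attr(reads, "qc_stats")
    aln <- stage("align", {
      a <- align_read_set(reads, ref, k = config$k, step = config$step,
                          max_mismatch_frac = config$max_mismatch_frac)
      note("align: %d reads mapped of %d", nrow(a), 2L * length(reads$id))
      a
    })
  }
  if (!exists("qc_stats", inherits = FALSE)) qc_stats <- NULL

  calls <- stage("call", {
    cl <- run_multi_config(aln, ref, grid = config$grid,
                           min_freq = config$min_freq,
                           min_depth = config$min_depth, k_sd = config$k_sd)
    note("call: %d candidate site(s), %d PASS", nrow(cl),
         sum(cl$filter == "PASS"))
    cl
  })
  pass <- calls[calls$filter == "PASS", , drop = FALSE]

  cooc <- stage("linkage", {
    a1 <- if (inherits(aln, "alignments")) aln else aln[[1L]]
    cooccurrence_matrix(a1, pass, max_span = config$max_span,
                        min_informative = config$min_informative)
  })

  annotated <- NULL
  category_summary <- NULL
  if (!is.null(ann)) {
    annotated <- stage("annotate", annotate_variants(pass, ann, ref))
    category_summary <- stage("annotate", summarise_categories(
      annotated, ann, roll_up_structural = TRUE))
  }

  paths <- stage("write", {
    hdr <- sprintf("##quasipop_config_hash=%s", hash)
    seed_hdr <- sprintf("##quasipop_seed=%d", config$seed)
    vcf <- file.path(config$outdir, "calls.vcf")
    write_vcf(calls, vcf, extra_header = c(hdr, seed_hdr))
    tsv_hdr <- sprintf("# quasipop config=%s seed=%d", hash, config$seed)
    write_tsv_commented <- function(d, p) {
      writeLines(tsv_hdr, p)
      suppressWarnings(data.table::fwrite(d, p, sep = "\t", append = TRUE,
                                          col.names = TRUE))
      p
    }
    out <- c(vcf = vcf,
             calls = write_tsv_commented(as.data.frame(calls),
                                         file.path(config$outdir,
                                                   "calls.tsv")),
             cooccurrence = write_tsv_commented(
               cooc, file.path(config$outdir, "cooccurrence.tsv")))
    if (!is.null(category_summary))
      out <- c(out, category_summary = write_tsv_commented(
        category_summary, file.path(config$outdir, "category_summary.tsv")))
    log_path <- file.path(config$outdir, "run_log.txt")
    out <- c(out, log = log_path)
    out
  })
  writeLines(log_lines, paths[["log"]])

  list(calls = calls, pass = pass,
       consensus = attr(calls, "consensus"),
       cooccurrence = cooc, annotated = annotated,
       category_summary = category_summary, qc_stats = qc_stats,
       paths = paths, config_hash = hash)
}

#' Compare calls to simulation truth
#'
#' Replaces by-eye inspection of called sites with an automated truth-table
#' comparison: calls and truth variants are matched on (position,
#' alternative allele).
#'
#' @param calls A call table (`pos`, `alt`, `freq`), e.g. the PASS subset of
#'   [run_multi_config()].
#' @param truth Truth variant table with `pos`, `alt`, `freq` (e.g.
#'   `pop$truth$frequencies` or the simulator's `truth_variants.tsv`).
#' @param callable_min_freq Truth sites at or below this frequency are not
#'   expected to be called; recall is computed over the supra-threshold
#'   subset.
#' @return list: `n_calls`, `n_truth`, `n_truth_callable`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `mean_abs_freq_error` (over matched sites), and
#'   the per-site `matches` table.
#' @export
compare_to_truth <- function(calls, truth, callable_min_freq = 0.01) {
  calls <- as.data.frame(calls)
  truth <- as.data.frame(truth)
  key_c <- paste(calls$pos, calls$alt)
  key_t <- paste(truth$pos, truth$alt)
  callable <- truth$freq > callable_min_freq
  m <- match(key_c, key_t)
  tp <- sum(!is.na(m))
  fp <- sum(is.na(m))
  fn <- sum(callable & !(key_t %in% key_c))
  matches <- data.frame(
    pos = calls$pos, alt = calls$alt, called_freq = calls$freq,
    truth_freq = truth$freq[m],
    abs_error = abs(calls$freq - truth$freq[m]))
  list(n_calls = nrow(calls), n_truth = nrow(truth),
       n_truth_callable = sum(callable), tp = tp, fp = fp, fn = fn,
       precision = if (nrow(calls) > 0) tp / nrow(calls) else NA_real_,
       recall = if (sum(callable) > 0)
         sum(callable & key_t %in% key_c) / sum(callable) else NA_real_,
       mean_abs_freq_error = if (tp > 0)
         mean(matches$abs_error, na.rm = TRUE) else NA_real_,
       matches = matches)
}
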