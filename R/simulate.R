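#' Read-simulation configuration
#'
#' Defaults emulate the sequencing design this pipeline targets: 2 x 300 bp
#' MiSeq pairs, deep coverage, substitution-only errors at a low per-base
#' rate, constant base quality Q35 emitted independently of the error process
#' (which keeps the truth tractable). Insert sizes are Normal, truncated to
#' `[read_length, genome length]`.
#'
#' @param read_length Read length in bases (>= 50).
#' @param insert_mean,insert_sd Fragment (insert) size distribution, bases.
#' @param mean_coverage Target mean per-base coverage (total sequenced bases /
#'   genome length).
#' @param substitution_error_rate Per-base i.i.d. substitution error
#'   probability, in `[0, 0.05)`.
#' @param quality Constant Phred quality, or a per-position integer profile of
#'   length `read_length`.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(read_length = 300L, insert_mean = 600L,
                       insert_sd = 60L, mean_coverage = 1000,
                       substitution_error_rate = 0.002, quality = 35L,
                       seed = NULL) {
  read_length <- as.integer(read_length)
  if (read_length < 50L) stop("read_length must be >= 50")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (substitution_error_rate < 0 || substitution_error_rate >= 0.05)
    stop("substitution_error_rate must be in [0, 0.05)")
  if (!length(quality) %in% c(1L, read_length))
    stop("quality must be scalar or one value per read position")
  if (any(quality < 0) || any(quality > 60)) stop("quality must be in 0..60")
  structure(list(read_length = read_length,
                 insert_mean = as.numeric(insert_mean),
                 insert_sd = as.numeric(insert_sd),
                 mean_coverage = as.numeric(mean_coverage),
                 substitution_error_rate = as.numeric(substitution_error_rate),
                 quality = as.integer(quality),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

quality_string <- function(config) {
  q <- config$quality
  if (length(q) == 1L) q <- rep(q, config$read_length)
  intToUtf8(q + 33L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads from a haplotype population
#'
#' Fragments are drawn from haplotypes proportional to their weights with
#' uniform start positions; substitution errors are injected i.i.d. at the
#' configured rate; per-base qualities follow the quality model. Output is
#' deterministic (byte-identical) under a fixed `config$seed`. The truth
#' table records each pair's source haplotype and origin coordinates.
#'
#' @param pop A `haplotype_population` (see [build_population()]).
#' @param config A [sim_config()].
#' @param n_pairs Override the pair count implied by `mean_coverage`.
#' @param id_prefix Read-name prefix.
#' @return A `read_set`: list with `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (parallel character vectors), `truth` data.frame (`id`,
#'   `source`, `haplotype`, `start`, `insert`, `strand`), `reference_id`,
#'   `read_length`.
#' @export
simulate_reads <- function(pop, config, n_pairs = NULL, id_prefix = "sim") {
  stopifnot(inherits(pop, "haplotype_population"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- pop$reference
  L <- ref$length
  rl <- config$read_length
  if (is.null(n_pairs))
    n_pairs <- round(config$mean_coverage * L / (2 * rl))
  if (n_pairs < 1L) stop("configuration yields fewer than one fragment")
  if (config$insert_mean < rl)
    warning("insert_mean < read_length: mates will fully overlap")

  insert <- as.integer(pmax(rl, pmin(L, round(
    rnorm(n_pairs, config$insert_mean, config$insert_sd)))))
  start <- 1L + as.integer(floor(runif(n_pairs) * (L - insert + 1)))
  hap <- sample.int(length(pop$weights), n_pairs, replace = TRUE,
                    prob = pop$weights)

  frag <- substring(ref$sequence, start, start + insert - 1L)
  frag <- apply_haplotype_variants(frag, start, hap, pop)
  r1 <- substring(frag, 1L, rl)
  r2 <- revcomp(substring(frag, insert - rl + 1L, insert))
  e <- config$substitution_error_rate
  if (e > 0) {
    r1 <- cpp_inject_errors(r1, e)
    r2 <- cpp_inject_errors(r2, e)
  }
  qs <- quality_string(config)
  ids <- sprintf("%s_%07d", id_prefix, seq_len(n_pairs))
  truth <- data.frame(id = ids, source = ref$id, haplotype = hap,
                      start = start, insert = insert, strand = "+")
  structure(list(id = ids, r1_seq = r1, r1_qual = rep(qs, n_pairs),
                 r2_seq = r2, r2_qual = rep(qs, n_pairs),
                 truth = truth, reference_id = ref$id, read_length = rl),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d pairs (reference %s)\n", length(x$id),
              paste(unique(x$reference_id), collapse = ",")))
  invisible(x)
}

#' Simulate a two-phage co-infection read pool
#'
#' A single read pool in which each fragment is drawn from population A with
#' probability `mix_fraction`, else from B — the sequencing analogue of
#' co-infecting one host with two phages and extracting pooled DNA. Note that
#' equal genome-copy mixtures of genomes with different lengths contribute
#' fragments proportional to length: use [mix_fraction_equal_copies()] for
#' the fragment-level fraction giving both genomes equal coverage.
#'
#' @param pop_a,pop_b `haplotype_population`s with distinct reference ids.
#' @param mix_fraction Probability a fragment originates from A, strictly in
#'   (0, 1).
#' @param config A [sim_config()]; `mean_coverage` is interpreted over the
#'   summed genome lengths, so the total pair count is
#'   `mean_coverage * (L_A + L_B) / (2 * read_length)`.
#' @return A `read_set` whose `truth$source` labels each pair's genome.
#' @export
simulate_coinfection_pool <- function(pop_a, pop_b, mix_fraction, config) {
  stopifnot(inherits(pop_a, "haplotype_population"),
            inherits(pop_b, "haplotype_population"))
  if (identical(pop_a$reference$id, pop_b$reference$id))
    stop("co-infecting references must have distinct ids")
  if (!(mix_fraction > 0 && mix_fraction < 1))
    stop("mix_fraction must be strictly between 0 and 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  la <- pop_a$reference$length
  lb <- pop_b$reference$length
  n_total <- round(config$mean_coverage * (la + lb) / (2 * config$read_length))
  if (n_total < 1L) stop("configuration yields fewer than one fragment")
  n_a <- rbinom(1L, n_total, mix_fraction)
  sub <- config
  sub$seed <- NULL
  set_a <- simulate_reads(pop_a, sub, n_pairs = max(n_a, 1L),
                          id_prefix = "poolA")
  set_b <- simulate_reads(pop_b, sub, n_pairs = max(n_total - n_a, 1L),
                          id_prefix = "poolB")
  ord <- sample.int(length(set_a$id) + length(set_b$id))
  merged <- list(
    id = c(set_a$id, set_b$id)[ord],
    r1_seq = c(set_a$r1_seq, set_b$r1_seq)[ord],
    r1_qual = c(set_a$r1_qual, set_b$r1_qual)[ord],
    r2_seq = c(set_a$r2_seq, set_b$r2_seq)[ord],
    r2_qual = c(set_a$r2_qual, set_b$r2_qual)[ord],
    truth = rbind(set_a$truth, set_b$truth)[ord, , drop = FALSE],
    reference_id = c(pop_a$reference$id, pop_b$reference$id),
    read_length = config$read_length)
  rownames(merged$truth) <- NULL
  structure(merged, class = "read_set")
}

#' @rdname simulate_coinfection_pool
#' @export
mix_fraction_equal_copies <- function(pop_a, pop_b) {
  la <- pop_a$reference$length
  lb <- pop_b$reference$length
  la / (la + lb)
}

#' FASTQ input/output for read sets
#'
#' `write_read_set()` writes Sanger Phred+33 paired FASTQ (`<prefix>_R1.fastq`
#' and `<prefix>_R2.fastq`) plus the truth table (`<prefix>_truth.tsv`) when
#' present. `read_fastq_pair()` loads two FASTQ files into a `read_set`
#' (without truth).
#'
#' @param reads A `read_set`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `write_read_set()`: invisible named vector of paths;
#'   `read_fastq_pair()`: a `read_set`.
#' @export
write_read_set <- function(reads, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  write_fastq_one(reads$id, reads$r1_seq, reads$r1_qual, p1)
  write_fastq_one(reads$id, reads$r2_seq, reads$r2_qual, p2)
  out <- c(r1 = p1, r2 = p2)
  if (!is.null(reads$truth)) {
    pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
    data.table::fwrite(reads$truth, pt, sep = "\t")
    out <- c(out, truth = pt)
  }
  invisible(out)
}

write_fastq_one <- function(id, seq, qual, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seq, id)),
    Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname write_read_set
#' @param r1,r2 Paths to mate-1 and mate-2 FASTQ files.
#' @export
read_fastq_pair <- function(r1, r2) {
  # suppressed: Biostrings warns about dropped metadata columns on FASTQ load
  a <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  b <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
  if (length(a) != length(b)) stop("mate files differ in read count")
  structure(list(id = sub("\\s.*$", "", names(a)),
                 r1_seq = as.character(a),
                 r1_qual = as.character(Biostrings::quality(a)),
                 r2_seq = as.character(b),
                 r2_qual = as.character(Biostrings::quality(b)),
                 truth = NULL, reference_id = NA_character_,
                 read_length = max(Biostrings::width(a))),
            class = "read_set")
}
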