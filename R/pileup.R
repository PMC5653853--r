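#' Build a per-position pileup with mate-overlap resolution
#'
#' Tallies reference-oriented read bases per position, split by strand, after
#' excluding bases below `min_base_q`. Where mates of one fragment overlap,
#' the fragment contributes a single base: the higher-quality mate's call
#' wins (ties go to mate 1), so overlapping 2 x 300 bp libraries are not
#' double-counted.
#'
#' @param aln An `alignments` object (see [align_read_set()], [read_sam()]).
#' @param reference The [reference_genome()] the reads are mapped to.
#' @param min_base_q Minimum base quality for a base to be counted.
#' @return A `pileup`: list with `counts` (L x 4 total), `counts_fwd`,
#'   `counts_rev`, `qualsum` (per-allele quality sums), `depth`, `min_base_q`
#'   and the reference.
#' @export
build_pileup <- function(aln, reference, min_base_q = 20L) {
  stopifnot(inherits(aln, "alignments"),
            identical(attr(aln, "reference_id"), reference$id))
  res <- cpp_build_pileup(reference$length, aln$start, aln$seq, aln$qual,
                          aln$strand, aln$frag, as.integer(min_base_q))
  counts <- res$counts_fwd + res$counts_rev
  colnames(counts) <- colnames(res$counts_fwd) <- colnames(res$counts_rev) <-
    colnames(res$qualsum) <- DNA_BASES
  structure(list(counts = counts, counts_fwd = res$counts_fwd,
                 counts_rev = res$counts_rev, qualsum = res$qualsum,
                 depth = as.integer(rowSums(counts)),
                 min_base_q = as.integer(min_base_q), reference = reference),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d bp, mean depth %.1f (min base Q%d)\n",
              x$reference$id, x$reference$length, mean(x$depth),
              x$min_base_q))
  invisible(x)
}

#' Inspect one pileup column
#'
#' @param pileup A [build_pileup()] result.
#' @param pos 1-based position.
#' @return list: `position`, per-allele `counts` (+/- strand split),
#'   `depth`, `mean_qual` per allele.
#' @export
pileup_column <- function(pileup, pos) {
  stopifnot(pos >= 1L, pos <= pileup$reference$length)
  cnt <- pileup$counts[pos, ]
  list(position = as.integer(pos),
       counts = cnt,
       counts_fwd = pileup$counts_fwd[pos, ],
       counts_rev = pileup$counts_rev[pos, ],
       depth = pileup$depth[pos],
       mean_qual = ifelse(cnt > 0, pileup$qualsum[pos, ] / cnt, NA_real_))
}

#' Derive the sample consensus from a pileup
#'
#' Per position the consensus base is the modal allele; ties and zero-depth
#' positions fall back to the reference base. Calling variants against this
#' sample consensus (rather than a database reference) prevents majority
#' changes of the sequenced population from masquerading as low-frequency
#' variants.
#'
#' @param pileup A [build_pileup()] result.
#' @return A `consensus_sequence`: list with `sequence` and per-position
#'   `support` (modal-allele fraction of depth; 0 where depth is 0).
#' @export
call_consensus <- function(pileup) {
  counts <- pileup$counts
  L <- nrow(counts)
  refv <- strsplit(pileup$reference$sequence, "")[[1L]]
  ref_idx <- match(refv, DNA_BASES)
  rowmax <- do.call(pmax, as.data.frame(counts))
  ref_count <- counts[cbind(seq_len(L), ref_idx)]
  # reference base retained on ties (including depth 0); otherwise the
  # first modal allele in A<C<G<T order (deterministic)
  take_ref <- ref_count == rowmax
  cons_idx <- max.col(counts, ties.method = "first")
  cons_idx[take_ref] <- ref_idx[take_ref]
  depth <- pileup$depth
  structure(list(
    sequence = paste(DNA_BASES[cons_idx], collapse = ""),
    support = ifelse(depth > 0, rowmax / depth, 0)),
    class = "consensus_sequence")
}

#' Call low-frequency variants from a pileup
#'
#' Emits one call per non-consensus allele at positions meeting the coverage
#' rule (`depth >= min_depth`), the abundance rule
#' (`alt_count / depth > min_freq`, strict) and `alt_count >= min_alt_count`
#' (suppresses singleton sequencing errors). Multi-allelic positions emit one
#' call per alternative allele. The reported `ref` is the sample-consensus
#' base.
#'
#' @param pileup A [build_pileup()] result.
#' @param consensus A [call_consensus()] result from the same sample (built
#'   from this or a sibling pileup).
#' @param min_freq Frequency threshold, strict, in (0, 1). Default 0.01: only
#'   variants above the 1\% threshold are reported.
#' @param min_depth Minimum qualifying coverage (default 100x).
#' @param min_alt_count Minimum supporting reads for the alternative allele.
#' @return data.frame: `pos`, `ref`, `alt`, `alt_count`, `depth`, `freq`,
#'   `mean_alt_qual`.
#' @export
call_variants <- function(pileup, consensus, min_freq = 0.01,
                          min_depth = 100L, min_alt_count = 2L) {
  if (!(min_freq > 0 && min_freq < 1))
    stop("min_freq must be strictly between 0 and 1")
  counts <- pileup$counts
  L <- nrow(counts)
  depth <- pileup$depth
  cons_idx <- match(strsplit(consensus$sequence, "")[[1L]], DNA_BASES)
  alt_counts <- counts
  alt_counts[cbind(seq_len(L), cons_idx)] <- 0L
  ok_depth <- depth >= min_depth
  hits <- which(alt_counts >= min_alt_count &
                  alt_counts > min_freq * depth &
                  ok_depth, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), alt_count = integer(0),
                      depth = integer(0), freq = numeric(0),
                      mean_alt_qual = numeric(0)))
  pos <- hits[, 1L]
  ai <- hits[, 2L]
  out <- data.frame(
    pos = pos,
    ref = DNA_BASES[cons_idx[pos]],
    alt = DNA_BASES[ai],
    alt_count = counts[hits],
    depth = depth[pos],
    freq = counts[hits] / depth[pos],
    mean_alt_qual = pileup$qualsum[hits] / counts[hits])
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-standard-deviation agreement filter across caller configurations
#'
#' A site passes when every per-configuration frequency estimate lies within
#' `k_sd` sample standard deviations (n-1 denominator) of their mean. All
#' estimates equal (zero SD) passes. The decision is scale-invariant.
#'
#' @param estimates Numeric vector of frequency estimates, one per
#'   configuration (length >= 2); configurations that did not detect the site
#'   contribute 0.
#' @param k_sd Width of the inclusion band in standard deviations.
#' @return `TRUE` (include) or `FALSE` (exclude).
#' @export
consensus_filter <- function(estimates, k_sd = 2) {
  if (length(estimates) < 2L)
    stop("consensus_filter needs at least 2 estimates")
  s <- sd(estimates)
  if (s == 0) return(TRUE)
  all(abs(estimates - mean(estimates)) <= k_sd * s)
}

default_config_grid <- function() {
  expand.grid(min_base_q = c(15L, 20L, 25L), min_alt_count = c(2L, 4L),
              KEEP.OUT.ATTRS = FALSE)
}

#' Multi-configuration variant calling with agreement filtering
#'
#' Emulates the mapper-by-caller grid of a multi-tool consensus pipeline with
#' internal parameterizations (default: `min_base_q` in {15, 20, 25} crossed
#' with `min_alt_count` in {2, 4} — six configurations). Alternatively pass a
#' list of `alignments` objects (e.g. six externally mapped SAM files read
#' with [read_sam()]), each paired with a grid row, to reproduce an external
#' multi-mapper design. Per site the frequency vector across configurations
#' (0 where undetected) is assembled, [consensus_filter()] applied, and the
#' mean of the estimates reported as the site frequency.
#'
#' @param aln An `alignments` object, or a list of them (one per grid row).
#' @param reference The mapped-to [reference_genome()].
#' @param grid data.frame of configurations with columns `min_base_q`,
#'   `min_alt_count` (default six-configuration grid). A single-row grid skips
#'   the agreement filter with a notice.
#' @param min_freq,min_depth Calling thresholds, see [call_variants()].
#' @param k_sd Agreement band width, see [consensus_filter()].
#' @param consensus_base_q Base-quality cutoff of the pileup from which the
#'   sample consensus is derived.
#' @return A `variant_calls` data.frame: `pos`, `ref`, `alt`, `freq` (mean
#'   across configurations), `depth`, `alt_count` (first-configuration
#'   values), `nconf` (configurations detecting the site), `filter` (`PASS`,
#'   `sd2_fail`, `low_freq` or `low_cov`); attributes `estimates` (site x
#'   configuration matrix), `grid`, `consensus`, `reference_id`.
#' @export
run_multi_config <- function(aln, reference, grid = default_config_grid(),
                             min_freq = 0.01, min_depth = 100L, k_sd = 2,
                             consensus_base_q = 20L) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("min_base_q", "min_alt_count") %in% names(grid)))
  nconf <- nrow(grid)
  aln_list <- if (inherits(aln, "alignments")) rep(list(aln), nconf) else aln
  if (length(aln_list) != nconf)
    stop("need one alignment set per configuration (or a single shared one)")
  rid <- unique(vapply(aln_list, function(a) attr(a, "reference_id"),
                       character(1)))
  if (length(rid) != 1L || !identical(rid, reference$id))
    stop("all configurations must be mapped to the same reference")

  # pileups are cached per (alignment set, min_base_q)
  cache <- new.env(parent = emptyenv())
  get_pileup <- function(i, q) {
    key <- paste0(if (inherits(aln, "alignments")) "shared" else i, "_", q)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_pileup(aln_list[[i]], reference, q)
    cache[[key]]
  }
  consensus <- call_consensus(get_pileup(1L, as.integer(consensus_base_q)))

  per_conf <- lapply(seq_len(nconf), function(i) {
    call_variants(get_pileup(i, grid$min_base_q[i]), consensus,
                  min_freq = min_freq, min_depth = min_depth,
                  min_alt_count = grid$min_alt_count[i])
  })
  if (nconf == 1L) {
    message("single configuration: agreement filter skipped")
    out <- per_conf[[1L]]
    out$nconf <- rep(1L, nrow(out))
    out$filter <- rep("PASS", nrow(out))
    est <- matrix(out$freq, ncol = 1L)
  } else {
    key <- unique(do.call(rbind, lapply(per_conf, function(d)
      d[, c("pos", "alt")])))
    key <- key[order(key$pos, key$alt), , drop = FALSE]
    est <- matrix(0, nrow = nrow(key), ncol = nconf)
    for (i in seq_len(nconf)) {
      d <- per_conf[[i]]
      idx <- match(paste(d$pos, d$alt), paste(key$pos, key$alt))
      est[idx, i] <- d$freq
    }
    if (nrow(key) == 0L) {
      out <- per_conf[[1L]][0, ]
      out$nconf <- integer(0)
      out$filter <- character(0)
    } else {
      include <- apply(est, 1L, consensus_filter, k_sd = k_sd)
      # depth / alt_count / ref reported from the first configuration's pileup
      p1 <- get_pileup(1L, grid$min_base_q[1L])
      cons_chars <- strsplit(consensus$sequence, "")[[1L]]
      mean_freq <- rowMeans(est)
      filter <- ifelse(!include, "sd2_fail",
                       ifelse(p1$depth[key$pos] < min_depth, "low_cov",
                              ifelse(mean_freq <= min_freq, "low_freq",
                                     "PASS")))
      out <- data.frame(
        pos = key$pos,
        ref = cons_chars[key$pos],
        alt = key$alt,
        freq = mean_freq,
        depth = p1$depth[key$pos],
        alt_count = p1$counts[cbind(key$pos, match(key$alt, DNA_BASES))],
        nconf = as.integer(rowSums(est > 0)),
        filter = filter)
    }
  }
  rownames(out) <- NULL
  structure(out, estimates = est, grid = grid, consensus = consensus,
            reference_id = reference$id,
            class = c("variant_calls", "data.frame"))
}

#' Classify a nucleotide substitution
#'
#' Transitions are purine<->purine or pyrimidine<->pyrimidine (A<->G, C<->T);
#' everything else is a transversion. The mutation-spectrum class separates
#' AT->GC changes (A->G, T->C) from GC->AT (G->A, C->T).
#'
#' @param ref,alt Single-base reference and alternative alleles (vectorised).
#' @return data.frame: `type` (`transition`/`transversion`), `spectrum`
#'   (`AT_to_GC`, `GC_to_AT`, `other`).
#' @export
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(ref == alt)) stop("ref and alt must differ")
  if (!all(ref %in% DNA_BASES) || !all(alt %in% DNA_BASES))
    stop("alleles must be A/C/G/T")
  pair <- paste0(ref, alt)
  type <- ifelse(pair %in% c("AG", "GA", "CT", "TC"),
                 "transition", "transversion")
  spectrum <- ifelse(pair %in% c("AG", "TC"), "AT_to_GC",
                     ifelse(pair %in% c("GA", "CT"), "GC_to_AT", "other"))
  data.frame(type = type, spectrum = spectrum)
}

#' Write variant calls as VCF 4.2
#'
#' One record per call with INFO fields `AF` (mean frequency across
#' configurations), `DP`, `AC` and `NCONF`, and FILTER `PASS`, `sd2_fail`,
#' `low_freq` or `low_cov`. A TSV mirror of the call table sits alongside VCF
#' for spreadsheet use via [data.table::fwrite()].
#'
#' @param calls A `variant_calls` object ([run_multi_config()]).
#' @param path Output VCF path.
#' @param extra_header Character vector of extra `##`-lines (e.g. the run's
#'   seed and configuration hash).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, extra_header = character(0)) {
  rid <- attr(calls, "reference_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=quasipop",
    sprintf("##contig=<ID=%s>", rid),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mean alternative allele frequency across configurations\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Qualifying read depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternative allele read count\">",
    "##INFO=<ID=NCONF,Number=1,Type=Integer,Description=\"Number of configurations detecting the site\">",
    "##FILTER=<ID=sd2_fail,Description=\"Estimate outside mean +/- 2 SD across configurations\">",
    "##FILTER=<ID=low_freq,Description=\"Mean frequency at or below threshold\">",
    "##FILTER=<ID=low_cov,Description=\"Depth below minimum coverage\">",
    extra_header,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0L) {
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%.8g;DP=%d;AC=%d;NCONF=%d",
      rid, calls$pos, calls$ref, calls$alt, calls$filter, calls$freq,
      calls$depth, calls$alt_count, calls$nconf), con)
  }
  invisible(path)
}

#' Read a quasipop VCF back into a call table
#'
#' Minimal reader for VCFs written by [write_vcf()] (single-sample,
#' INFO-only records).
#'
#' @param path VCF path.
#' @return A `variant_calls` data.frame.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  rid <- sub("##contig=<ID=([^>,]+).*", "\\1",
             grep("^##contig=", lines, value = TRUE)[1L])
  body <- lines[!grepl("^#", lines)]
  info_field <- function(info, key) {
    sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", info, perl = TRUE)
  }
  if (!length(body)) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), freq = numeric(0),
                      depth = integer(0), alt_count = integer(0),
                      nconf = integer(0), filter = character(0))
  } else {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    out <- data.frame(
      pos = as.integer(f[, 2L]), ref = f[, 4L], alt = f[, 5L],
      freq = as.numeric(info_field(f[, 8L], "AF")),
      depth = as.integer(info_field(f[, 8L], "DP")),
      alt_count = as.integer(info_field(f[, 8L], "AC")),
      nconf = as.integer(info_field(f[, 8L], "NCONF")),
      filter = f[, 7L])
  }
  structure(out, reference_id = rid,
            class = c("variant_calls", "data.frame"))
}
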