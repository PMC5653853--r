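# Decode Phred+33 quality strings to integer vectors, caching by unique
# string (simulated sets carry few distinct quality strings).
decode_quals <- function(qual) {
  uq <- unique(qual)
  dec <- lapply(uq, function(q) utf8ToInt(q) - 33L)
  dec[match(qual, uq)]
}

mean_qual <- function(qual) {
  uq <- unique(qual)
  m <- vapply(uq, function(q) mean(utf8ToInt(q) - 33L), numeric(1))
  m[match(qual, uq)]
}

# Kept length for one decoded quality vector under sliding-window trimming.
# Windows advance one base at a time (final sub-window tail judged by its own
# mean); at the first failing window the read is cut just before the first
# below-threshold base inside that window (Trimmomatic-style), so isolated
# good bases at the drop point are retained.
keep_length <- function(q, window, min_mean_q) {
  # iterate to a fixed point: truncation shortens tail windows, which can
  # newly fail, and trimming must be idempotent
  k <- keep_length_once(q, window, min_mean_q)
  while (k > 0L) {
    k2 <- keep_length_once(q[seq_len(k)], window, min_mean_q)
    if (k2 == k) break
    k <- k2
  }
  k
}

keep_length_once <- function(q, window, min_mean_q) {
  n <- length(q)
  if (n == 0L) return(0L)
  cs <- cumsum(c(0, q))
  i <- seq_len(n)
  hi <- pmin(i + window - 1L, n)
  means <- (cs[hi + 1L] - cs[i]) / (hi - i + 1L)
  f <- which(means < min_mean_q)
  if (!length(f)) return(n)
  f <- f[1L]
  w <- q[f:hi[f]]
  b <- which(w < min_mean_q)[1L] # exists: a window mean below threshold
  f + b - 2L
}

#' Sliding-window quality trimming
#'
#' Scans 5' to 3' and truncates the read at the first `window`-base window
#' whose mean Phred quality falls below `min_mean_q` (the standard
#' Trimmomatic-style SLIDINGWINDOW:5:20 regime). A read truncated to length 0
#' is dropped (empty sequence returned). The trailing sub-window tail is
#' judged by its own mean.
#'
#' @param seq Nucleotide string.
#' @param qual Phred+33 quality string of equal length.
#' @param window Window size in bases.
#' @param min_mean_q Minimum mean Phred quality per window.
#' @return list(seq, qual), truncated.
#' @export
sliding_window_trim <- function(seq, qual, window = 5L, min_mean_q = 20) {
  stopifnot(window >= 1L, nchar(seq) == nchar(qual))
  k <- keep_length(utf8ToInt(qual) - 33L, window, min_mean_q)
  list(seq = substr(seq, 1L, k), qual = substr(qual, 1L, k))
}

# Vectorised trim points for many reads; returns kept length per read.
trim_lengths <- function(qual, window = 5L, min_mean_q = 20) {
  uq <- unique(qual)
  keep <- vapply(uq, function(q)
    keep_length(utf8ToInt(q) - 33L, window, min_mean_q), integer(1))
  keep[match(qual, uq)]
}

#' Variant-calling read filter
#'
#' Keep/drop decision applied before variant calling: with `rule = "or"`
#' (default) a read is removed when its mean Phred quality is below
#' `min_mean_q` *or* its length is below `min_len`; `rule = "and"` removes
#' only reads failing both (the literal reading of some protocol wordings,
#' kept as a switch).
#'
#' @param seq Nucleotide string(s).
#' @param qual Phred+33 quality string(s).
#' @param min_mean_q Minimum mean read quality (default 30).
#' @param min_len Minimum read length (default 50; a 49-base read is dropped).
#' @param rule `"or"` or `"and"` (see Details).
#' @return Logical vector: `TRUE` = keep.
#' @export
variant_read_filter <- function(seq, qual, min_mean_q = 30, min_len = 50L,
                                rule = c("or", "and")) {
  rule <- match.arg(rule)
  len <- nchar(seq)
  mq <- mean_qual(qual)
  low_q <- mq < min_mean_q
  short <- len < min_len
  if (rule == "or") !(low_q | short) else !(low_q & short)
}

#' Quality control of a paired read set
#'
#' Applies [sliding_window_trim()] to every mate, then the
#' [variant_read_filter()] keep/drop rule; a pair is dropped when either mate
#' fails (mates are kept or dropped together so downstream fragment logic
#' stays consistent). Both stages are idempotent.
#'
#' @param reads A `read_set`.
#' @param trim Apply the sliding-window trimming stage.
#' @param window,trim_min_q Trimming parameters.
#' @param filter Apply the mean-quality/length read filter.
#' @param min_mean_q,min_len,rule Filter parameters, see
#'   [variant_read_filter()].
#' @return The filtered `read_set`, with a `qc_stats` attribute: pairs in,
#'   pairs kept, bases in, bases kept.
#' @export
qc_read_set <- function(reads, trim = TRUE, window = 5L, trim_min_q = 20,
                        filter = TRUE, min_mean_q = 30, min_len = 50L,
                        rule = "or") {
  stopifnot(inherits(reads, "read_set"))
  n_in <- length(reads$id)
  bases_in <- sum(nchar(reads$r1_seq)) + sum(nchar(reads$r2_seq))
  if (trim) {
    k1 <- trim_lengths(reads$r1_qual, window, trim_min_q)
    k2 <- trim_lengths(reads$r2_qual, window, trim_min_q)
    reads$r1_seq <- substr(reads$r1_seq, 1L, k1)
    reads$r1_qual <- substr(reads$r1_qual, 1L, k1)
    reads$r2_seq <- substr(reads$r2_seq, 1L, k2)
    reads$r2_qual <- substr(reads$r2_qual, 1L, k2)
    keep <- k1 > 0L & k2 > 0L
  } else {
    keep <- rep(TRUE, n_in)
  }
  if (filter) {
    keep <- keep &
      variant_read_filter(reads$r1_seq, reads$r1_qual, min_mean_q, min_len,
                          rule) &
      variant_read_filter(reads$r2_seq, reads$r2_qual, min_mean_q, min_len,
                          rule)
  }
  out <- reads
  for (f in c("id", "r1_seq", "r1_qual", "r2_seq", "r2_qual"))
    out[[f]] <- reads[[f]][keep]
  if (!is.null(reads$truth))
    out$truth <- reads$truth[keep, , drop = FALSE]
  attr(out, "qc_stats") <- data.frame(
    pairs_in = n_in, pairs_kept = sum(keep), bases_in = bases_in,
    bases_kept = sum(nchar(out$r1_seq)) + sum(nchar(out$r2_seq)))
  out
}
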