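#' Exact k-mer index of a reference
#'
#' Forward-strand k-mer to sorted 1-based position lists; reverse-strand
#' placements are found by looking up the reverse-complemented read against
#' this forward index.
#'
#' @param reference A [reference_genome()].
#' @param k k-mer size (default 21; must not exceed the reference length).
#' @return A `kmer_index` wrapping the native index.
#' @export
index_reference <- function(reference, k = 21L) {
  stopifnot(inherits(reference, "reference_genome"))
  if (k > reference$length) stop("k exceeds reference length")
  structure(list(ptr = cpp_index_reference(reference$sequence, as.integer(k)),
                 k = as.integer(k), reference = reference),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<kmer_index> %s: k=%d, %d distinct k-mers over %d bp\n",
              x$reference$id, info$k, info$n_kmers, info$ref_length))
  invisible(x)
}

#' Look up one k-mer's positions in the index
#'
#' @param index A [index_reference()] result.
#' @param kmer Character scalar of length `k`.
#' @return Sorted integer vector of 1-based occurrence positions (empty when
#'   absent).
#' @export
index_lookup <- function(index, kmer) {
  cpp_index_lookup(index$ptr, toupper(kmer))
}

#' Map reads to an indexed reference (ungapped)
#'
#' Seed-and-extend, substitution-only mapping: k-mer seeds are sampled every
#' `step` bases along the read (plus the terminal k-mer) on both orientations;
#' every candidate placement is scored by full ungapped mismatch count and the
#' best is reported when its mismatches do not exceed
#' `max_mismatch_frac * length`. Ties are broken deterministically by smallest
#' start then `+` strand; a mismatch-count tie between distinct placements
#' yields mapping confidence 0, otherwise confidence scales with the score gap
#' to the runner-up (max 60).
#'
#' @param seqs Character vector of read sequences.
#' @param index A [index_reference()] result.
#' @param step Seed sampling stride along the read.
#' @param max_mismatch_frac Maximum mismatch fraction for an accepted
#'   placement.
#' @return data.frame: `mapped`, `start`, `strand`, `nm` (mismatches), `mapq`.
#' @export
map_reads <- function(seqs, index, step = 10L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(index, "kmer_index"))
  res <- cpp_map_reads(index$ptr, toupper(seqs), as.integer(step),
                       max_mismatch_frac)
  as.data.frame(res)
}

#' @rdname map_reads
#' @param seq A single read sequence.
#' @export
map_read <- function(seq, index, step = 10L, max_mismatch_frac = 0.1) {
  map_reads(seq, index, step, max_mismatch_frac)[1L, , drop = FALSE]
}

new_alignments <- function(df, reference) {
  df <- df[order(df$frag, df$mate), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, reference_id = reference$id,
            reference_length = reference$length,
            class = c("alignments", "data.frame"))
}

#' Align a paired read set to a reference
#'
#' Maps both mates with [map_reads()]; mapped reads are retained (reverse
#' placements are stored reference-oriented: sequence reverse-complemented,
#' qualities reversed), unmapped mates are dropped, and mates share a fragment
#' id so pileup and co-occurrence stages can merge overlapping mates.
#'
#' @param reads A `read_set`.
#' @param reference A [reference_genome()].
#' @param k,step,max_mismatch_frac See [index_reference()] and [map_reads()].
#' @param index Optional prebuilt [index_reference()] (overrides `k`).
#' @return An `alignments` data.frame: `qname`, `frag`, `mate`, `start`,
#'   `strand`, `seq`, `qual` (reference-oriented), `nm`, `mapq`; attributes
#'   `reference_id`, `reference_length`.
#' @export
align_read_set <- function(reads, reference, k = 21L, step = 10L,
                           max_mismatch_frac = 0.1, index = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(index)) index <- index_reference(reference, k)
  n <- length(reads$id)
  m1 <- map_reads(reads$r1_seq, index, step, max_mismatch_frac)
  m2 <- map_reads(reads$r2_seq, index, step, max_mismatch_frac)
  build <- function(m, seq, qual, mate) {
    keep <- which(m$mapped)
    if (!length(keep))
      return(data.frame(qname = character(0), frag = integer(0),
                        mate = integer(0), start = integer(0),
                        strand = character(0), seq = character(0),
                        qual = character(0), nm = integer(0),
                        mapq = integer(0)))
    s <- seq[keep]
    q <- qual[keep]
    neg <- m$strand[keep] == "-"
    if (any(neg)) {
      s[neg] <- revcomp(s[neg])
      q[neg] <- as.character(Biostrings::reverse(Biostrings::BStringSet(q[neg])))
    }
    data.frame(qname = reads$id[keep], frag = keep, mate = mate,
               start = m$start[keep], strand = m$strand[keep],
               seq = s, qual = q, nm = m$nm[keep], mapq = m$mapq[keep])
  }
  df <- rbind(build(m1, reads$r1_seq, reads$r1_qual, 1L),
              build(m2, reads$r2_seq, reads$r2_qual, 2L))
  new_alignments(df, reference)
}

#' Write alignments as text SAM
#'
#' Minimal SAM 1.6 with `@HD`/`@SQ`/`@PG` header and the mandatory `NM` tag.
#' Sequences are stored reference-oriented, matching SAM convention.
#'
#' @param aln An `alignments` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  rid <- attr(aln, "reference_id")
  rlen <- attr(aln, "reference_length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", rid, rlen),
               "@PG\tID:quasipop\tPN:quasipop"), con)
  paired <- ave(seq_len(nrow(aln)), aln$frag, FUN = length) == 2L
  flag <- ifelse(paired, 1L, 0L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(paired & aln$mate == 1L, 64L, 0L) +
    ifelse(paired & aln$mate == 2L, 128L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                   aln$qname, flag, rid, aln$start, aln$mapq,
                   nchar(aln$seq), aln$seq, aln$qual, aln$nm)
  writeLines(lines, con)
  invisible(path)
}

# CIGAR -> list(ok, left soft clip, aligned length). Only M/=/X (merged) plus
# soft clips are representable in the ungapped model.
parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (ops[1L] == -1L) return(list(ok = FALSE))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  if (any(!op %in% c("M", "=", "X", "S"))) return(list(ok = FALSE))
  core <- which(op %in% c("M", "=", "X"))
  if (!length(core)) return(list(ok = FALSE))
  # soft clips only at the ends
  if (any(op[seq(min(core), max(core))] == "S")) return(list(ok = FALSE))
  left <- if (op[1L] == "S") n[1L] else 0L
  right <- if (op[length(op)] == "S") n[length(op)] else 0L
  list(ok = TRUE, left = left, right = right, alen = sum(n[core]))
}

#' Read a text SAM file into alignments
#'
#' Consumes externally produced (or [write_sam()]-written) SAM. Records whose
#' CIGAR contains anything beyond matches/mismatches (`M`/`=`/`X`) and
#' terminal soft clips are skipped with a counted warning, as are unmapped
#' records; soft-clipped bases are removed. Coordinates stay 1-based; reverse
#' (flag 16) records are stored as-is, since SAM sequences are already
#' reference-oriented. Mates are paired by query name.
#'
#' @param path SAM file path.
#' @param reference The [reference_genome()] records are mapped to; the `@SQ`
#'   header length must match.
#' @return An `alignments` object; attribute `skipped` counts skipped records.
#' @export
read_sam <- function(path, reference) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  if (length(sq)) {
    ln <- as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq[1L]))
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq[1L])
    if (!is.na(ln) && ln != reference$length)
      stop("SAM header length (", ln, ") does not match reference (",
           reference$length, ")")
    if (!identical(sn, reference$id))
      stop("SAM header sequence name does not match reference id")
  }
  body <- which(!hdr)
  skipped <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln_no <- body[i]
    f <- strsplit(lines[ln_no], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed SAM line ", ln_no, ": fewer than 11 fields")
    flag <- suppressWarnings(as.integer(f[2L]))
    pos <- suppressWarnings(as.integer(f[4L]))
    if (is.na(flag) || is.na(pos))
      stop("malformed SAM line ", ln_no, ": non-numeric FLAG or POS")
    if (bitwAnd(flag, 4L) > 0L) { skipped <- skipped + 1L; next }
    cg <- parse_cigar(f[6L])
    if (!cg$ok) { skipped <- skipped + 1L; next }
    seq <- f[10L]
    qual <- f[11L]
    if (cg$left > 0L || cg$right > 0L) {
      seq <- substr(seq, cg$left + 1L, nchar(seq) - cg$right)
      qual <- substr(qual, cg$left + 1L, nchar(qual) - cg$right)
    }
    if (nchar(seq) != cg$alen)
      stop("malformed SAM line ", ln_no, ": SEQ length disagrees with CIGAR")
    nm <- NA_integer_
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(nm_tag)) nm <- as.integer(sub("^NM:i:", "", nm_tag[1L]))
    recs[[i]] <- data.frame(
      qname = f[1L],
      mate = if (bitwAnd(flag, 128L) > 0L) 2L else 1L,
      start = pos,
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      seq = seq, qual = qual, nm = nm,
      mapq = suppressWarnings(as.integer(f[5L])))
  }
  df <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(df))
    df <- data.frame(qname = character(0), mate = integer(0),
                     start = integer(0), strand = character(0),
                     seq = character(0), qual = character(0),
                     nm = integer(0), mapq = integer(0))
  if (skipped > 0L)
    warning(skipped, " SAM record(s) skipped (unmapped or unsupported CIGAR)")
  df$frag <- match(df$qname, unique(df$qname))
  if (any(df$start + nchar(df$seq) - 1L > reference$length))
    stop("SAM record exceeds reference bounds")
  out <- new_alignments(df[, c("qname", "frag", "mate", "start", "strand",
                               "seq", "qual", "nm", "mapq")], reference)
  attr(out, "skipped") <- skipped
  out
}

#' Competitive assignment of a mixed pool between two references
#'
#' Maps every read against both references and keeps, for each target, the
#' fragments whose summed mismatch count is strictly better there than on the
#' competitor (unmapped counts as infinitely bad) — the in-silico analogue of
#' discarding reads that map better to the co-infecting genome.
#'
#' @param reads A `read_set` (e.g. from [simulate_coinfection_pool()]).
#' @param ref_a,ref_b The two [reference_genome()]s.
#' @param ... Passed to [align_read_set()].
#' @return list of two `alignments` objects, named by reference id.
#' @export
align_competitive <- function(reads, ref_a, ref_b, ...) {
  aln_a <- align_read_set(reads, ref_a, ...)
  aln_b <- align_read_set(reads, ref_b, ...)
  score <- function(aln, n) {
    s <- rep(Inf, n)
    agg <- tapply(aln$nm, aln$frag, sum)
    cnt <- tapply(aln$nm, aln$frag, length)
    idx <- as.integer(names(agg))
    # a fragment with only one mapped mate scores its mate as unmapped
    s[idx] <- as.numeric(agg) + ifelse(cnt == 2L, 0, Inf)
    s
  }
  n <- length(reads$id)
  sa <- score(aln_a, n)
  sb <- score(aln_b, n)
  keep_a <- which(sa < sb)
  keep_b <- which(sb < sa)
  list_a <- aln_a[aln_a$frag %in% keep_a, , drop = FALSE]
  list_b <- aln_b[aln_b$frag %in% keep_b, , drop = FALSE]
  out <- list(new_alignments(list_a, ref_a), new_alignments(list_b, ref_b))
  names(out) <- c(ref_a$id, ref_b$id)
  out
}
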