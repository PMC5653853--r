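# Shared fixture builders; everything is generated in code at test time.

toy_ref <- function(len = 1500, seed = 99, id = "toy") {
  random_genome(len, id = id, seed = seed)
}

qstr <- function(len, q = 35L) {
  vapply(len, function(l) strrep(intToUtf8(q + 33L), l), character(1))
}

# Hand-built alignments: reads are given reference-oriented, mates share a
# frag id.
mk_aln <- function(reference, start, seq, qual = NULL, strand = NULL,
                   frag = NULL, mate = NULL) {
  n <- length(start)
  if (is.null(qual)) qual <- qstr(nchar(seq))
  if (is.null(strand)) strand <- rep("+", n)
  if (is.null(frag)) frag <- seq_len(n)
  if (is.null(mate)) mate <- stats::ave(seq_len(n), frag, FUN = seq_along)
  quasipop:::new_alignments(data.frame(
    qname = paste0("r", frag), frag = frag, mate = mate,
    start = as.integer(start), strand = strand, seq = seq, qual = qual,
    nm = 0L, mapq = 60L), reference)
}

ref_window <- function(ref, start, len) {
  substring(ref$sequence, start, start + len - 1L)
}

mutate_at <- function(seq, offset, base) {
  substr(seq, offset, offset) <- base
  seq
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]

# Annotation emulating a ~43 kb phage genome: a non-structural early region,
# the structural module at 25,000-40,000 with the tail fibre (adsorption
# complex) at 36,000-39,000, and an other/unknown gene.
module_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gp01", "gpS1", "tail_fibre", "gpS2", "gpX"),
    start = c(500L, 25000L, 36000L, 39001L, 40500L),
    end = c(24000L, 35999L, 39000L, 40000L, 42500L),
    strand = "+",
    category = c("non_structural", "structural", "adsorption", "structural",
                 "other_unknown")), genome_length = 43000L)
}

fifteen_sites <- c(1200L, 4800L, 9100L, 14300L, 26050L, 27400L, 30200L,
                   33900L, 36100L, 36550L, 37000L, 37420L, 37910L, 38300L,
                   38760L)

# Exhaustive-placement mapping oracle: scores every start on both strands via
# Biostrings::neditStartingAt and applies the (mismatches, start, + before -)
# ordering. Returns NULL when no placement passes the mismatch budget.
oracle_map <- function(read, refseq, max_mm_frac = 0.1) {
  m <- nchar(read)
  L <- nchar(refseq)
  subject <- Biostrings::DNAString(refseq)
  starts <- seq_len(L - m + 1L)
  fwd <- Biostrings::neditStartingAt(Biostrings::DNAString(read), subject,
                                     starting.at = starts,
                                     with.indels = FALSE)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(read))
  rev <- Biostrings::neditStartingAt(rc, subject, starting.at = starts,
                                     with.indels = FALSE)
  cand <- data.frame(start = c(starts, starts),
                     strand = rep(c("+", "-"), each = length(starts)),
                     mm = c(fwd, rev))
  cand <- cand[order(cand$mm, cand$start, cand$strand), ]
  best <- cand[1L, ]
  if (best$mm <= floor(max_mm_frac * m)) best else NULL
}

# Brute-force pairwise co-occurrence expectation by enumerating haplotypes.
oracle_cooc <- function(pop, i, j) {
  carries_i <- pop$carriers[i, ]
  carries_j <- pop$carriers[j, ]
  p_both <- sum(pop$weights[carries_i & carries_j])
  p_any <- sum(pop$weights[carries_i | carries_j])
  if (p_any > 0) 100 * p_both / p_any else NA_real_
}
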