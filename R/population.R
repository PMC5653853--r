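# substring() rejects zero-length indices on R < 4.4, hence the guard
base_at <- function(ref, pos) {
  if (length(pos) == 0L) return(character(0))
  substring(ref$sequence, pos, pos)
}

#' Construct a planted-variant table
#'
#' Draws single-nucleotide variant sites on a reference with target population
#' frequencies. Positions are sampled without replacement (one alternative
#' allele per site); with `spectrum = "at_gc"` sites are biased toward A/T
#' reference bases with the transition alternative (A->G, T->C), emulating the
#' AT->GC transition excess typical of error-prone phage DNA polymerase
#' activity.
#'
#' @param reference A [reference_genome()].
#' @param freqs Numeric vector of target frequencies in (0, 1).
#' @param positions Optional explicit 1-based positions (length of `freqs`).
#' @param spectrum `"uniform"` (random alt allele) or `"at_gc"`.
#' @param min_spacing Minimum distance between sampled sites, in bases.
#' @return data.frame with columns `pos`, `ref`, `alt`, `freq` (class
#'   `planted_variants`), sorted by position.
#' @export
make_planted_variants <- function(reference, freqs, positions = NULL,
                                  spectrum = c("uniform", "at_gc"),
                                  min_spacing = 10L) {
  spectrum <- match.arg(spectrum)
  n <- length(freqs)
  stopifnot(all(freqs > 0), all(freqs < 1))
  if (n == 0L) {
    v <- data.frame(pos = integer(0), ref = character(0),
                    alt = character(0), freq = numeric(0))
    class(v) <- c("planted_variants", "data.frame")
    return(v)
  }
  if (is.null(positions)) {
    if (spectrum == "at_gc") {
      cand <- which(strsplit(reference$sequence, "")[[1L]] %in% c("A", "T"))
    } else {
      cand <- seq_len(reference$length)
    }
    positions <- integer(0)
    cand <- sample(cand)
    for (p in cand) {
      if (length(positions) == n) break
      if (all(abs(positions - p) >= min_spacing)) positions <- c(positions, p)
    }
    if (length(positions) < n)
      stop("could not place ", n, " sites with spacing ", min_spacing)
  }
  stopifnot(length(positions) == n, !anyDuplicated(positions),
            all(positions >= 1), all(positions <= reference$length))
  refb <- base_at(reference, positions)
  alt <- character(n)
  for (i in seq_len(n)) {
    if (spectrum == "at_gc" && refb[i] %in% c("A", "T")) {
      alt[i] <- if (refb[i] == "A") "G" else "C"
    } else {
      alt[i] <- sample(setdiff(DNA_BASES, refb[i]), 1L)
    }
  }
  v <- data.frame(pos = as.integer(positions), ref = refb, alt = alt,
                  freq = as.numeric(freqs))
  v <- v[order(v$pos), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("planted_variants", "data.frame")
  v
}

validate_variants <- function(variants, reference) {
  need <- c("pos", "ref", "alt", "freq")
  if (!all(need %in% names(variants)))
    stop("variants need columns: ", paste(need, collapse = ", "))
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(variants$pos < 1L) || any(variants$pos > reference$length))
    stop("variant position out of reference range")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (!all(variants$ref %in% DNA_BASES) || !all(variants$alt %in% DNA_BASES))
    stop("alleles must be A/C/G/T")
  if (any(base_at(reference, variants$pos) != variants$ref))
    stop("ref allele disagrees with reference sequence")
  per_pos <- table(variants$pos)
  if (any(per_pos > 3L)) stop("at most 3 alternative alleles per position")
  if (anyDuplicated(variants[, c("pos", "alt")]))
    stop("duplicate (pos, alt) variant")
  invisible(variants)
}

#' Build a haplotype population with known truth
#'
#' A population is a weighted set of genome haplotypes, each carrying a subset
#' of the planted variants — the quasispecies-like ground truth against which
#' every downstream stage is testable. Marginal per-site alternative-allele
#' frequencies and pairwise co-occurrence fractions follow in closed form from
#' the haplotype weights and are stored as truth.
#'
#' @param reference A [reference_genome()].
#' @param variants A planted-variant table (see [make_planted_variants()]);
#'   may have zero rows.
#' @param haplotypes List of `list(variants = <integer indices into the
#'   variant table>, weight = <fraction>)`. Weights must be positive and sum
#'   to 1 (tolerance 1e-9). A haplotype must not carry two alleles of one
#'   position.
#' @return A `haplotype_population`: reference, variant table with realised
#'   `freq`, haplotype weights, carrier matrix, and `truth` (frequency table
#'   and closed-form co-occurrence table, see [truth_cooccurrence()]).
#' @examples
#' ref <- random_genome(2000, seed = 1)
#' v <- make_planted_variants(ref, c(0.0831, 0.0144), positions = c(500, 900))
#' pop <- build_population(ref, v, list(
#'   list(variants = 1L, weight = 0.0831),
#'   list(variants = 2L, weight = 0.0144),
#'   list(variants = integer(0), weight = 0.9025)))
#' pop$truth$frequencies
#' @export
build_population <- function(reference, variants, haplotypes) {
  stopifnot(inherits(reference, "reference_genome"))
  validate_variants(variants, reference)
  w <- vapply(haplotypes, function(h) as.numeric(h$weight), numeric(1))
  if (any(w <= 0)) stop("haplotype weights must be positive")
  if (abs(sum(w) - 1) > 1e-9) stop("haplotype weights must sum to 1")
  nv <- nrow(variants)
  K <- length(haplotypes)
  carriers <- matrix(FALSE, nrow = nv, ncol = K)
  for (k in seq_len(K)) {
    idx <- as.integer(haplotypes[[k]]$variants)
    if (length(idx) &&
        (any(idx < 1L) || any(idx > nv)))
      stop("haplotype ", k, " references an unknown variant")
    if (anyDuplicated(variants$pos[idx]))
      stop("haplotype ", k, " carries two alleles of one position")
    carriers[idx, k] <- TRUE
  }
  pop <- structure(list(reference = reference,
                        variants = as.data.frame(variants),
                        weights = w, carriers = carriers),
                   class = "haplotype_population")
  pop$variants$freq <- population_frequencies(pop)
  pop$truth <- list(
    frequencies = cbind(pop$variants,
                        target_freq = variants$freq)[
                          , c("pos", "ref", "alt", "freq", "target_freq")],
    cooccurrence = truth_cooccurrence(pop))
  pop
}

#' Build a population by independent random assignment
#'
#' Realises arbitrary marginal frequencies on a finite pool of `n_haplotypes`
#' equally weighted genomes: each variant is assigned to
#' `round(freq * n_haplotypes)` genomes drawn at random (alleles of one
#' position get disjoint carrier sets). Marginals are exact to
#' `1/n_haplotypes`; pairs are approximately independent, and the realised
#' co-occurrence is recorded as truth.
#'
#' @inheritParams build_population
#' @param n_haplotypes Size of the genome pool (default 10000 gives 0.01\%
#'   frequency resolution).
#' @return A `haplotype_population`.
#' @export
build_population_independent <- function(reference, variants,
                                         n_haplotypes = 10000L) {
  stopifnot(inherits(reference, "reference_genome"))
  validate_variants(variants, reference)
  K <- as.integer(n_haplotypes)
  nv <- nrow(variants)
  carriers <- matrix(FALSE, nrow = nv, ncol = K)
  for (p in unique(variants$pos)) {
    rows <- which(variants$pos == p)
    avail <- seq_len(K)
    for (i in rows) {
      m <- round(variants$freq[i] * K)
      if (m < 1L || m > length(avail))
        stop("frequency ", variants$freq[i],
             " not realisable on ", K, " haplotypes")
      pick <- sample(avail, m)
      carriers[i, pick] <- TRUE
      avail <- setdiff(avail, pick)
    }
  }
  pop <- structure(list(reference = reference,
                        variants = as.data.frame(variants),
                        weights = rep(1 / K, K), carriers = carriers),
                   class = "haplotype_population")
  pop$variants$freq <- population_frequencies(pop)
  pop$truth <- list(
    frequencies = cbind(pop$variants,
                        target_freq = variants$freq)[
                          , c("pos", "ref", "alt", "freq", "target_freq")],
    cooccurrence = truth_cooccurrence(pop))
  pop
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat(sprintf("<haplotype_population> %s: %d haplotypes, %d variant sites\n",
              x$reference$id, length(x$weights), nrow(x$variants)))
  invisible(x)
}

#' Closed-form truth marginals and pairwise co-occurrence
#'
#' `population_frequencies()` returns per-variant alternative-allele
#' frequencies (sum of weights of carrying haplotypes).
#' `truth_cooccurrence()` returns, for every variant pair, the probability a
#' genome carries both alleles and the co-occurrence percentage
#' `100 * P(both) / (P(both) + P(only i) + P(only j))` — the genome-level
#' analogue of the read-backed statistic computed by [cooccurrence()].
#'
#' @param pop A `haplotype_population`.
#' @return `population_frequencies()`: numeric vector. `truth_cooccurrence()`:
#'   data.frame `i`, `j` (variant row indices), `pos_i`, `pos_j`, `p_both`,
#'   `cooccurrence_pct` (NA when no genome carries either allele).
#' @export
population_frequencies <- function(pop) {
  if (nrow(pop$variants) == 0L) return(numeric(0))
  as.numeric(pop$carriers %*% pop$weights)
}

#' @rdname population_frequencies
#' @export
truth_cooccurrence <- function(pop) {
  nv <- nrow(pop$variants)
  if (nv < 2L)
    return(data.frame(i = integer(0), j = integer(0), pos_i = integer(0),
                      pos_j = integer(0), p_both = numeric(0),
                      cooccurrence_pct = numeric(0)))
  f <- population_frequencies(pop)
  P <- pop$carriers %*% (t(pop$carriers) * pop$weights)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  p_both <- P[idx]
  denom <- f[idx[, 1L]] + f[idx[, 2L]] - p_both
  data.frame(i = idx[, 1L], j = idx[, 2L],
             pos_i = pop$variants$pos[idx[, 1L]],
             pos_j = pop$variants$pos[idx[, 2L]],
             p_both = p_both,
             cooccurrence_pct = ifelse(denom > 0, 100 * p_both / denom,
                                       NA_real_))
}

#' Write population truth tables as TSV
#'
#' Emits `truth_variants.tsv` (pos, ref, alt, freq), `truth_haplotypes.tsv`
#' (id, weight, comma-separated variant indices) and `truth_cooccurrence.tsv`.
#'
#' @param pop A `haplotype_population`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_population_truth <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, "truth_variants.tsv")
  data.table::fwrite(pop$truth$frequencies, pv, sep = "\t")
  hap <- data.frame(
    id = seq_along(pop$weights), weight = pop$weights,
    variants = vapply(seq_along(pop$weights), function(k)
      paste(which(pop$carriers[, k]), collapse = ","), character(1)))
  ph <- file.path(dir, "truth_haplotypes.tsv")
  data.table::fwrite(hap, ph, sep = "\t")
  pc <- file.path(dir, "truth_cooccurrence.tsv")
  data.table::fwrite(pop$truth$cooccurrence, pc, sep = "\t")
  invisible(c(pv, ph, pc))
}

# Apply the variants carried by haplotype `hap` of `pop` to fragment windows.
# `frag` is a character vector of substrings of the reference starting at
# `start` (1-based) with lengths nchar(frag); `hap` gives each fragment's
# haplotype index. Used by the simulator; sparse in variants so the loop is
# over sites, not fragments.
apply_haplotype_variants <- function(frag, start, hap, pop) {
  v <- pop$variants
  if (nrow(v) == 0L) return(frag)
  end <- start + nchar(frag) - 1L
  for (i in seq_len(nrow(v))) {
    rows <- which(start <= v$pos[i] & end >= v$pos[i] & pop$carriers[i, hap])
    if (length(rows)) {
      off <- v$pos[i] - start[rows] + 1L
      y <- frag[rows]
      substr(y, off, off) <- v$alt[i]
      frag[rows] <- y
    }
  }
  frag
}
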