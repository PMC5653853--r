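# Resolved base codes (0..3, -1 uncovered/low-quality) per fragment at the
# given sites, reusing the pileup's mate-overlap rule. unit = "read" treats
# every read as its own fragment.
fragment_base_codes <- function(aln, sites, min_base_q = 20L,
                                unit = c("fragment", "read")) {
  unit <- match.arg(unit)
  frag <- if (unit == "fragment") aln$frag else seq_len(nrow(aln))
  cpp_fragment_bases(aln$start, aln$seq, aln$qual, aln$strand,
                     as.integer(frag), as.integer(sites),
                     as.integer(min_base_q))
}

#' Classify one fragment's allele at a variant site
#'
#' The fragment's base at the site (mate overlaps resolved exactly as in
#' [build_pileup()]: higher-quality base wins) classified against the call's
#' reference/alternative alleles.
#'
#' @param aln An `alignments` object holding the fragment's read(s).
#' @param frag Fragment id within `aln`.
#' @param pos Site position (1-based).
#' @param ref,alt The site's reference and alternative alleles.
#' @param min_base_q Minimum base quality; below it the site counts as
#'   uncovered.
#' @return One of `"ref"`, `"alt"`, `"other"`, `"uncovered"`.
#' @export
fragment_alleles <- function(aln, frag, pos, ref, alt, min_base_q = 20L) {
  sub <- aln[aln$frag == frag, , drop = FALSE]
  if (nrow(sub) == 0L) return("uncovered")
  res <- cpp_fragment_bases(sub$start, sub$seq, sub$qual, sub$strand,
                            sub$frag, as.integer(pos),
                            as.integer(min_base_q))
  code <- res$codes[1L, 1L]
  if (code < 0L) return("uncovered")
  base <- DNA_BASES[code + 1L]
  if (base == alt) "alt" else if (base == ref) "ref" else "other"
}

cooc_from_codes <- function(ci, cj, ref_i, alt_i, ref_j, alt_j) {
  # NA-index lookup keeps vector length (codes of -1 mean uncovered)
  bi <- DNA_BASES[ifelse(ci < 0L, NA_integer_, ci + 1L)]
  bj <- DNA_BASES[ifelse(cj < 0L, NA_integer_, cj + 1L)]
  both_cov <- !is.na(bi) & !is.na(bj)
  class_i <- ifelse(bi == alt_i, "alt", ifelse(bi == ref_i, "ref", "other"))
  class_j <- ifelse(bj == alt_j, "alt", ifelse(bj == ref_j, "ref", "other"))
  usable <- both_cov & class_i != "other" & class_j != "other"
  n_other <- sum(both_cov & !usable)
  n_both <- sum(usable & class_i == "alt" & class_j == "alt")
  n_only_i <- sum(usable & class_i == "alt" & class_j == "ref")
  n_only_j <- sum(usable & class_i == "ref" & class_j == "alt")
  n_neither <- sum(usable & class_i == "ref" & class_j == "ref")
  denom <- n_both + n_only_i + n_only_j
  list(n_both = n_both, n_only_i = n_only_i, n_only_j = n_only_j,
       n_neither = n_neither, n_other = n_other,
       informative = n_both + n_only_i + n_only_j + n_neither,
       cooccurrence_pct = if (denom > 0) 100 * n_both / denom else NA_real_)
}

#' Read-backed co-occurrence of two variant sites
#'
#' Counts sequenced fragments covering *both* sites with classifiable bases:
#' `n_both` carry both alternative alleles, `n_only_i`/`n_only_j` exactly
#' one, `n_neither` neither; fragments showing a third allele at either site
#' are excluded from those four counts and tallied as `n_other`. The headline
#' statistic is the percentage of variant-bearing fragments carrying both:
#' `100 * n_both / (n_both + n_only_i + n_only_j)` (NA when no fragment
#' carries either variant). Raw counts are always returned so alternative
#' ratios can be recomputed. Symmetric in the two sites.
#'
#' @param aln An `alignments` object.
#' @param site_i,site_j Lists (or single-row data.frames) with `pos`, `ref`,
#'   `alt`; positions must differ.
#' @param min_base_q Minimum base quality, as in [build_pileup()].
#' @param unit `"fragment"` (mates merged, default — maximises span for
#'   overlapping paired reads) or `"read"`.
#' @return A `pair_cooccurrence` list: site annotations, the five counts,
#'   `informative` and `cooccurrence_pct`.
#' @export
cooccurrence <- function(aln, site_i, site_j, min_base_q = 20L,
                         unit = c("fragment", "read")) {
  if (site_i$pos == site_j$pos) stop("sites must have distinct positions")
  res <- fragment_base_codes(aln, c(site_i$pos, site_j$pos), min_base_q,
                             unit)
  cc <- cooc_from_codes(res$codes[, 1L], res$codes[, 2L],
                        site_i$ref, site_i$alt, site_j$ref, site_j$alt)
  structure(c(list(pos_i = site_i$pos, alt_i = site_i$alt,
                   pos_j = site_j$pos, alt_j = site_j$alt), cc),
            class = "pair_cooccurrence")
}

#' @export
print.pair_cooccurrence <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence> %d%s / %d%s: both=%d only_i=%d only_j=%d neither=%d -> %s\n",
    x$pos_i, x$alt_i, x$pos_j, x$alt_j, x$n_both, x$n_only_i, x$n_only_j,
    x$n_neither,
    if (is.na(x$cooccurrence_pct)) "NA"
    else sprintf("%.1f%%", x$cooccurrence_pct)))
  invisible(x)
}

#' Pairwise co-occurrence over all eligible call pairs
#'
#' One row per unordered pair of calls. Pairs farther apart than `max_span`
#' (beyond any fragment's reach) and pairs with fewer than `min_informative`
#' classifiable fragments keep their counts but report `cooccurrence_pct`
#' as NA.
#'
#' @param aln An `alignments` object.
#' @param calls A call table (`pos`, `ref`, `alt`), e.g. PASS rows of
#'   [run_multi_config()].
#' @param max_span Maximum site separation to evaluate, bases (default 900,
#'   matching a 2 x 300 bp library with ~600 bp inserts).
#' @param min_informative Minimum classifiable fragments for a percentage.
#' @param min_base_q,unit See [cooccurrence()].
#' @return data.frame: `pos_i`, `alt_i`, `pos_j`, `alt_j`, `n_both`,
#'   `n_only_i`, `n_only_j`, `n_neither`, `n_other`, `informative`,
#'   `cooccurrence_pct`.
#' @export
cooccurrence_matrix <- function(aln, calls, max_span = 900L,
                                min_informative = 20L, min_base_q = 20L,
                                unit = c("fragment", "read")) {
  unit <- match.arg(unit)
  n <- nrow(calls)
  empty <- data.frame(pos_i = integer(0), alt_i = character(0),
                      pos_j = integer(0), alt_j = character(0),
                      n_both = integer(0), n_only_i = integer(0),
                      n_only_j = integer(0), n_neither = integer(0),
                      n_other = integer(0), informative = integer(0),
                      cooccurrence_pct = numeric(0))
  if (n < 2L) return(empty)
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  codes <- fragment_base_codes(aln, calls$pos, min_base_q, unit)$codes
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    if (calls$pos[i] == calls$pos[j]) {
      # two alt alleles of one position: mutually exclusive by construction
      cc <- list(n_both = 0L, n_only_i = NA_integer_, n_only_j = NA_integer_,
                 n_neither = NA_integer_, n_other = NA_integer_,
                 informative = NA_integer_, cooccurrence_pct = NA_real_)
    } else if (abs(calls$pos[i] - calls$pos[j]) > max_span) {
      cc <- list(n_both = 0L, n_only_i = 0L, n_only_j = 0L, n_neither = 0L,
                 n_other = 0L, informative = 0L,
                 cooccurrence_pct = NA_real_)
    } else {
      cc <- cooc_from_codes(codes[, i], codes[, j], calls$ref[i],
                            calls$alt[i], calls$ref[j], calls$alt[j])
      if (cc$informative < min_informative) cc$cooccurrence_pct <- NA_real_
    }
    data.frame(pos_i = calls$pos[i], alt_i = calls$alt[i],
               pos_j = calls$pos[j], alt_j = calls$alt[j],
               n_both = cc$n_both, n_only_i = cc$n_only_i,
               n_only_j = cc$n_only_j, n_neither = cc$n_neither,
               n_other = cc$n_other, informative = cc$informative,
               cooccurrence_pct = cc$cooccurrence_pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
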