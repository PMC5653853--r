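VARIANT_CATEGORIES <- c(GENE_CATEGORIES, "non_coding")

#' Assign genome categories to variant calls
#'
#' Position-in-interval lookup of each call against a non-overlapping gene
#' annotation (1-based inclusive). Calls outside every gene are `non_coding`.
#' Genes tagged `adsorption` report category `adsorption`; they belong to the
#' structural module and are additionally counted under structural totals
#' where requested (see [summarise_categories()]).
#'
#' @param calls data.frame with at least `pos` (e.g. [run_multi_config()]
#'   output).
#' @param annotation A [gene_annotation()].
#' @return The calls with `gene_id` (NA when intergenic) and `category`
#'   columns appended.
#' @export
assign_category <- function(calls, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  gl <- attr(annotation, "genome_length")
  if (any(calls$pos < 1L | calls$pos > gl))
    stop("call position beyond genome bounds")
  hit <- IRanges::findOverlaps(
    IRanges::IRanges(calls$pos, calls$pos),
    IRanges::IRanges(annotation$start, annotation$end), select = "first")
  calls$gene_id <- ifelse(is.na(hit), NA_character_,
                          annotation$gene_id[hit])
  calls$category <- ifelse(is.na(hit), "non_coding",
                           annotation$category[hit])
  calls
}

#' Per-category SNP counts and gene tallies
#'
#' For each category: the number of calls (`snp_count`), the number of genes
#' annotated in that category (`genes_total`) and the number of distinct
#' genes carrying at least one call (`genes_with_snp`). With
#' `roll_up_structural = TRUE` an extra `structural_module` row aggregates
#' `structural` + `adsorption`, the usual definition of the phage structural
#' module.
#'
#' @param annotated Calls annotated by [assign_category()].
#' @param annotation The same [gene_annotation()].
#' @param roll_up_structural Append the aggregated structural-module row.
#' @return data.frame: `category`, `snp_count`, `genes_total`,
#'   `genes_with_snp`.
#' @export
summarise_categories <- function(annotated, annotation,
                                 roll_up_structural = FALSE) {
  stopifnot(inherits(annotation, "gene_annotation"))
  out <- data.frame(category = VARIANT_CATEGORIES,
                    snp_count = 0L, genes_total = 0L, genes_with_snp = 0L)
  gt <- table(annotation$category)
  out$genes_total <- as.integer(gt[out$category])
  out$genes_total[is.na(out$genes_total)] <- 0L
  out$genes_total[out$category == "non_coding"] <- NA_integer_
  if (nrow(annotated) > 0L) {
    sc <- table(annotated$category)
    out$snp_count <- as.integer(sc[out$category])
    out$snp_count[is.na(out$snp_count)] <- 0L
    gw <- tapply(annotated$gene_id[!is.na(annotated$gene_id)],
                 annotated$category[!is.na(annotated$gene_id)],
                 function(g) length(unique(g)))
    idx <- match(names(gw), out$category)
    out$genes_with_snp[idx] <- as.integer(gw)
  }
  if (roll_up_structural) {
    sel <- out$category %in% c("structural", "adsorption")
    out <- rbind(out, data.frame(
      category = "structural_module",
      snp_count = sum(out$snp_count[sel]),
      genes_total = sum(out$genes_total[sel]),
      genes_with_snp = sum(out$genes_with_snp[sel])))
  }
  out
}

#' Codon-level consequence of a single-nucleotide variant
#'
#' Translates the reference and mutated codon under the standard genetic code.
#' Codon N covers gene-relative bases 3N-2..3N on the coding strand; for `-`
#' strand genes the coding sequence is the reverse complement of the genomic
#' interval, so genomic position `pos` maps to coding offset
#' `end - pos + 1` and the substituted base is complemented.
#'
#' @param pos Genomic position of the variant (1-based).
#' @param alt Alternative allele (genomic / plus-strand base).
#' @param gene One row of a [gene_annotation()] (list or single-row
#'   data.frame with `start`, `end`, `strand`).
#' @param reference The [reference_genome()].
#' @return list: `codon_number`, `codon_ref`, `codon_alt`, `aa_ref`,
#'   `aa_alt`, `label` (`"<refAA><codon><altAA>"`, e.g. `"E123K"`, or
#'   `"synonymous"`).
#' @export
codon_consequence <- function(pos, alt, gene, reference) {
  if (pos < gene$start || pos > gene$end)
    stop("variant position lies outside the gene")
  glen <- gene$end - gene$start + 1L
  if (glen %% 3L != 0L)
    stop("gene length is not divisible by 3")
  cds <- substring(reference$sequence, gene$start, gene$end)
  if (gene$strand == "-") {
    cds <- revcomp(cds)
    off <- gene$end - pos + 1L
    alt_coding <- chartr("ACGT", "TGCA", alt)
  } else {
    off <- pos - gene$start + 1L
    alt_coding <- alt
  }
  codon_number <- (off - 1L) %/% 3L + 1L
  within <- (off - 1L) %% 3L + 1L
  codon_ref <- substring(cds, 3L * codon_number - 2L, 3L * codon_number)
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_coding
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
  aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
  list(codon_number = codon_number, codon_ref = codon_ref,
       codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt,
       label = if (aa_ref == aa_alt) "synonymous"
       else sprintf("%s%d%s", aa_ref, codon_number, aa_alt))
}

#' Annotate calls with categories, codon numbers and residue changes
#'
#' Combines [assign_category()] with per-call [codon_consequence()] and the
#' substitution class of [classify_substitution()]. Codon fields are NA for
#' non-coding calls and for genes whose length is not divisible by 3 (counted
#' with a warning).
#'
#' @param calls A call table (`pos`, `ref`, `alt`).
#' @param annotation A [gene_annotation()].
#' @param reference The [reference_genome()].
#' @return data.frame of class `annotated_variants`: calls plus `gene_id`,
#'   `category`, `codon_number`, `codon_change`, `aa_change`, `sub_type`,
#'   `sub_spectrum`.
#' @export
annotate_variants <- function(calls, annotation, reference) {
  out <- assign_category(as.data.frame(calls), annotation)
  n <- nrow(out)
  out$codon_number <- rep(NA_integer_, n)
  out$codon_change <- rep(NA_character_, n)
  out$aa_change <- rep(NA_character_, n)
  bad_len <- 0L
  for (i in seq_len(n)) {
    if (is.na(out$gene_id[i])) next
    g <- annotation[annotation$gene_id == out$gene_id[i], ]
    if ((g$end - g$start + 1L) %% 3L != 0L) {
      bad_len <- bad_len + 1L
      next
    }
    cc <- codon_consequence(out$pos[i], out$alt[i], g, reference)
    out$codon_number[i] <- cc$codon_number
    out$codon_change[i] <- paste0(cc$codon_ref, ">", cc$codon_alt)
    out$aa_change[i] <- cc$label
  }
  if (bad_len > 0L)
    warning(bad_len, " call(s) in genes with length not divisible by 3; ",
            "codon fields left NA")
  if (n > 0L) {
    cls <- classify_substitution(out$ref, out$alt)
    out$sub_type <- cls$type
    out$sub_spectrum <- cls$spectrum
  } else {
    out$sub_type <- character(0)
    out$sub_spectrum <- character(0)
  }
  class(out) <- c("annotated_variants", "data.frame")
  out
}

#' Codons carrying two or more variant calls
#'
#' Groups annotated calls by (gene, codon number) and returns the groups of
#' size two or more — codons displaying multiple amino-acid variants within
#' one population.
#'
#' @param annotated An [annotate_variants()] result.
#' @return data.frame: `gene_id`, `codon_number`, `n_variants`, `labels`
#'   (comma-separated residue-change labels).
#' @export
multi_snp_codons <- function(annotated) {
  ok <- !is.na(annotated$codon_number)
  d <- annotated[ok, , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(gene_id = character(0), codon_number = integer(0),
                      n_variants = integer(0), labels = character(0)))
  key <- paste(d$gene_id, d$codon_number, sep = "#")
  grp <- split(seq_len(nrow(d)), key)
  grp <- grp[vapply(grp, length, integer(1)) >= 2L]
  if (!length(grp))
    return(data.frame(gene_id = character(0), codon_number = integer(0),
                      n_variants = integer(0), labels = character(0)))
  out <- do.call(rbind, lapply(grp, function(idx) data.frame(
    gene_id = d$gene_id[idx[1L]],
    codon_number = d$codon_number[idx[1L]],
    n_variants = length(idx),
    labels = paste(d$aa_change[idx], collapse = ","))))
  out <- out[order(out$gene_id, out$codon_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
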