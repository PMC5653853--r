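#' Reference genome container
#'
#' A validated single-sequence reference: uppercase A/C/G/T, at least 1 kb
#' (the shortest genome this pipeline is meant for; phage genomes run tens of
#' kilobases). The genome is modelled as linear — simulated fragments never
#' wrap the origin.
#'
#' @param sequence Character scalar over A/C/G/T (case-insensitive).
#' @param id Sequence identifier used in FASTA/SAM/GFF output.
#' @return An object of class `reference_genome` with fields `id`, `sequence`
#'   and `length`.
#' @examples
#' ref <- random_genome(2000, id = "toy", seed = 1)
#' ref$length
#' @export
reference_genome <- function(sequence, id = "ref") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence may contain only A/C/G/T")
  if (nchar(sequence) < 1000L)
    stop("reference genome must be at least 1000 bp")
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d bp\n", x$id, x$length))
  invisible(x)
}

#' Generate a random reference genome
#'
#' @param length Genome length in bases (>= 1000).
#' @param id Sequence identifier.
#' @param gc GC content as a fraction.
#' @param seed Optional integer seed; when `NULL` the current RNG state is used.
#' @return A [reference_genome()].
#' @export
random_genome <- function(length = 43000L, id = "phage_sim", gc = 0.5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  reference_genome(seq, id = id)
}

#' Read/write a reference genome as FASTA
#'
#' Thin wrappers over Biostrings; `read_reference()` takes the first record.
#'
#' @param ref A [reference_genome()].
#' @param path FASTA file path.
#' @return `read_reference()` returns a [reference_genome()];
#'   `write_reference()` returns `path` invisibly.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) < 1L) stop("no sequences in ", path)
  reference_genome(as.character(x[[1L]]), id = sub("\\s.*$", "", names(x)[1L]))
}

#' Gene annotation with functional categories
#'
#' Genes carry one of four functional categories used for module-localisation
#' summaries: `non_structural` (replication/transcription machinery),
#' `structural` (virion components), `adsorption` (structural genes of the
#' tail-fibre/adsorption complex; counted within the structural module when a
#' total-structural tally is requested), and `other_unknown`. Positions not
#' covered by any gene are implicitly non-coding. Genes must not overlap;
#' operon-style phage genomes with minor overlaps must be pre-trimmed.
#'
#' @param genes data.frame with columns `gene_id`, `start`, `end` (1-based
#'   inclusive), `strand` (`+`/`-`), `category`.
#' @param genome_length Length of the annotated genome.
#' @return A `gene_annotation`: the validated data.frame with a
#'   `genome_length` attribute.
#' @examples
#' ann <- gene_annotation(data.frame(
#'   gene_id = c("gp01", "gp39"), start = c(100, 1200), end = c(1099, 1799),
#'   strand = "+", category = c("non_structural", "adsorption")),
#'   genome_length = 2000)
#' @export
gene_annotation <- function(genes, genome_length) {
  need <- c("gene_id", "start", "end", "strand", "category")
  if (!all(need %in% names(genes)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  genes <- as.data.frame(genes)[, need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start < 1L) || any(genes$end > genome_length) ||
      any(genes$start > genes$end))
    stop("gene coordinates must satisfy 1 <= start <= end <= genome length")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(genes$category %in% GENE_CATEGORIES))
    stop("category must be one of: ", paste(GENE_CATEGORIES, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) > 1L &&
      any(genes$start[-1L] <= genes$end[-nrow(genes)]))
    stop("genes must not overlap")
  structure(genes, genome_length = as.integer(genome_length),
            class = c("gene_annotation", "data.frame"))
}

#' Read/write gene annotation as GFF3
#'
#' The functional category travels in a `category=` attribute of each `gene`
#' feature.
#'
#' @param annotation A [gene_annotation()].
#' @param ref The annotated [reference_genome()] (provides seqid and length).
#' @param path GFF3 file path.
#' @return `read_annotation()` returns a [gene_annotation()].
#' @export
write_annotation <- function(annotation, ref, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ref$id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$category <- annotation$category
  GenomeInfoDb::seqlengths(gr) <- setNames(ref$length, ref$id)
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer omits the sequence-region directive; add it for round-trips
  lines <- readLines(path)
  writeLines(append(lines, sprintf("##sequence-region %s 1 %d", ref$id,
                                   ref$length), after = 1L), path)
  invisible(path)
}

#' @rdname write_annotation
#' @param genome_length Genome length; when `NULL`, taken from the GFF3
#'   `##sequence-region` directive.
#' @export
read_annotation <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (is.null(genome_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) >= 1L && !is.na(sl[1L])) {
      genome_length <- sl[1L]
    } else {
      # fall back to the ##sequence-region directive
      sr <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (!length(sr))
        stop("genome_length not given and absent from GFF3 header")
      genome_length <- as.integer(strsplit(sr[1L], "\\s+")[[1L]][4L])
    }
  }
  if (is.null(gr$category)) stop("GFF3 lacks the category attribute")
  gene_annotation(data.frame(
    gene_id = as.character(gr$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = as.character(gr$category)), genome_length)
}
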