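#' Build a gene table
#'
#' Validates and normalizes a data frame of gene annotations into the layout
#' used throughout the package: one row per feature, 1-based inclusive
#' coordinates on the heavy-strand reference, `+`/`-` strand symbols, and
#' feature kinds `PCG`, `tRNA`, `rRNA` or `CR`. A feature whose `stop` is
#' smaller than its `start` wraps across the origin of a circular genome.
#'
#' @param df Data frame with columns `gene`, `kind`, `start`, `stop`,
#'   `strand` and optionally `anticodon`.
#' @param genome_length Genome length used for coordinate checks and wrap
#'   arithmetic; defaults to `max(df$stop)`.
#' @param circular Logical; wrap-around features are only legal when `TRUE`.
#' @return The validated data frame (sorted by `start`, with a computed
#'   `size` column) of class `gene_table`.
#' @export
gene_table <- function(df, genome_length = NULL, circular = TRUE) {
  need <- c("gene", "kind", "start", "stop", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"anticodon" %in% names(df)) df$anticodon <- NA_character_
  df$gene <- as.character(df$gene)
  df$kind <- as.character(df$kind)
  df$strand <- as.character(df$strand)
  df$strand[df$strand %in% c("−", "L", "l")] <- "-"
  df$strand[df$strand %in% c("H", "h")] <- "+"
  df$anticodon <- toupper(as.character(df$anticodon))
  df$anticodon[df$anticodon %in% c("", ".", "NA")] <- NA_character_
  if (is.character(df$start)) df$start <- gsub(",", "", df$start)
  if (is.character(df$stop))  df$stop  <- gsub(",", "", df$stop)
  start_n <- suppressWarnings(as.numeric(df$start))
  stop_n <- suppressWarnings(as.numeric(df$stop))
  if (anyNA(start_n) || anyNA(stop_n) ||
      any(start_n != round(start_n)) || any(stop_n != round(stop_n))) {
    stop("non-integer gene coordinates")
  }
  df$start <- as.integer(start_n)
  df$stop <- as.integer(stop_n)
  if (is.null(genome_length)) genome_length <- max(df$stop)
  genome_length <- as.integer(genome_length)
  if (any(df$start < 1L | df$start > genome_length |
          df$stop < 1L | df$stop > genome_length)) {
    stop("gene coordinates outside 1..", genome_length)
  }
  if (!all(df$kind %in% c("PCG", "tRNA", "rRNA", "CR"))) {
    stop("gene kind must be one of PCG, tRNA, rRNA, CR")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene name(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  }
  if (sum(df$kind == "CR") > 1L) stop("more than one control-region record")
  wraps <- df$stop < df$start
  if (any(wraps) && !circular) {
    stop("wrap-around feature(s) on a linear genome: ",
         paste(df$gene[wraps], collapse = ", "))
  }
  if (is.unsorted(df$start)) {
    warning("gene table not sorted by start; sorting")
    df <- df[order(df$start), , drop = FALSE]
  }
  df$size <- ifelse(df$stop >= df$start,
                    df$stop - df$start + 1L,
                    genome_length - df$start + 1L + df$stop)
  rownames(df) <- NULL
  attr(df, "genome_length") <- genome_length
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Assemble an annotated mitogenome
#'
#' The central container every analysis stage consumes: an (optional)
#' circular heavy-strand sequence plus an ordered gene table. Table-only
#' mode (no sequence) supports layout arithmetic on published annotation
#' tables without the underlying sequence.
#'
#' @param genes A [gene_table()] or coercible data frame.
#' @param sequence Optional character scalar heavy-strand sequence.
#' @param taxon,accession Free-text metadata.
#' @param circular Logical, default `TRUE`.
#' @param genome_length Required check/fallback length in table-only mode.
#' @return Object of class `mitogenome`.
#' @examples
#' g <- mitogenome(
#'   data.frame(gene = c("ND1", "tRNA-Ile"), kind = c("PCG", "tRNA"),
#'              start = c(1, 10), stop = c(9, 14), strand = "+"),
#'   sequence = "ATGAAATAAGGGGG")
#' genome_length(g)
#' @export
mitogenome <- function(genes, sequence = NULL, taxon = "", accession = "",
                       circular = TRUE, genome_length = NULL) {
  if (!is.null(sequence)) {
    sequence <- .check_seq(sequence)
    if (!is.null(genome_length) && genome_length != nchar(sequence)) {
      stop("declared genome_length differs from sequence length")
    }
    genome_length <- nchar(sequence)
  }
  genes <- gene_table(genes, genome_length = genome_length, circular = circular)
  structure(
    list(
      sequence = sequence,
      genes = genes,
      taxon = taxon,
      accession = accession,
      circular = circular,
      genome_length = attr(genes, "genome_length")
    ),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf(
    "<mitogenome> %s%s: %d bp (%s, %s), %d features (%d PCG, %d tRNA, %d rRNA, %d CR)\n",
    if (nzchar(x$taxon)) x$taxon else "unnamed",
    if (nzchar(x$accession)) paste0(" [", x$accession, "]") else "",
    x$genome_length,
    if (x$circular) "circular" else "linear",
    if (is.null(x$sequence)) "table-only" else "sequence present",
    nrow(x$genes),
    sum(x$genes$kind == "PCG"), sum(x$genes$kind == "tRNA"),
    sum(x$genes$kind == "rRNA"), sum(x$genes$kind == "CR")
  ))
  invisible(x)
}

#' Genome length of an annotated mitogenome
#' @param genome A [mitogenome()].
#' @return Integer length in bp.
#' @export
genome_length <- function(genome) genome$genome_length

# find a gene record by name (or pass through a one-row subset)
.resolve_gene <- function(genome, gene) {
  if (is.data.frame(gene)) {
    if (nrow(gene) != 1L) stop("expected a single gene record")
    return(as.list(gene))
  }
  if (is.list(gene)) return(gene)
  i <- match(gene, genome$genes$gene)
  if (is.na(i)) stop("gene not found in table: ", gene)
  as.list(genome$genes[i, , drop = FALSE])
}

#' Extract the coding-strand sequence of a gene
#'
#' Slices `[start..stop]` from the heavy-strand reference (wrapping across
#' the origin when `stop < start` on a circular genome) and
#' reverse-complements the slice for light-strand genes, so the result reads
#' 5'→3' on the coding strand.
#'
#' @param genome A [mitogenome()] with sequence present.
#' @param gene Gene name or a single gene-table row.
#' @return Character scalar of length equal to the gene size.
#' @export
extract_gene_sequence <- function(genome, gene) {
  if (is.null(genome$sequence)) {
    stop("genome is table-only: no sequence to extract from")
  }
  rec <- .resolve_gene(genome, gene)
  L <- genome$genome_length
  if (rec$start < 1L || rec$start > L || rec$stop < 1L || rec$stop > L) {
    stop("gene coordinates outside genome")
  }
  if (rec$stop >= rec$start) {
    s <- substr(genome$sequence, rec$start, rec$stop)
  } else {
    if (!genome$circular) stop("wrap-around gene on a linear genome")
    s <- paste0(substr(genome$sequence, rec$start, L),
                substr(genome$sequence, 1L, rec$stop))
  }
  if (identical(rec$strand, "-")) s <- revcomp(s)
  s
}

# write a coding-strand string back into the heavy-strand sequence at the
# genome positions of `rec` offset `at` (1-based within the gene, coding
# orientation); used by the simulator
.gene_positions <- function(rec, L) {
  pos <- if (rec$stop >= rec$start) rec$start:rec$stop
         else c(rec$start:L, 1:rec$stop)
  if (identical(rec$strand, "-")) rev(pos) else pos
}
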