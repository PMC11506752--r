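#' Canonical mitochondrial protein-coding gene order
#'
#' The gene order used for concatenation, following the canonical
#' vertebrate mitochondrial gene arrangement.
#'
#' @return Character vector of the 13 PCG symbols.
#' @export
pcg_order <- function() {
  c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
    "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")
}

#' Build a concatenated supermatrix from per-gene alignments
#'
#' Concatenates per-gene aligned CDS into one matrix with per-gene charset
#' ranges. Genes are taken in [pcg_order()] (genes not in that list follow
#' alphabetically); taxa are matched by exact name across genes, and a
#' taxon missing from a gene is gap-filled for that gene's columns.
#'
#' @param gene_alignments Named list (gene -> named character vector of
#'   equal-length aligned sequences).
#' @return Object of class `supermatrix`: list with `taxa`, `matrix` (named
#'   character vector of concatenated rows), `charsets` (data frame `gene`,
#'   `start`, `end`), `missing_fraction` (per taxon), `length`.
#' @export
build_supermatrix <- function(gene_alignments) {
  if (!length(gene_alignments) || is.null(names(gene_alignments))) {
    stop("need a named list of per-gene alignments")
  }
  keep <- vapply(gene_alignments, length, integer(1)) > 0L
  if (any(!keep)) {
    warning("dropping empty gene(s): ",
            paste(names(gene_alignments)[!keep], collapse = ", "))
    gene_alignments <- gene_alignments[keep]
  }
  genes <- names(gene_alignments)
  ord <- c(intersect(pcg_order(), genes), sort(setdiff(genes, pcg_order())))
  gene_alignments <- gene_alignments[ord]
  for (g in ord) {
    aln <- gene_alignments[[g]]
    if (is.null(names(aln)) || any(!nzchar(names(aln)))) {
      stop("unnamed sequence(s) in gene ", g)
    }
    if (anyDuplicated(names(aln))) stop("duplicate taxon in gene ", g)
    if (length(unique(nchar(aln))) != 1L) stop("ragged alignment in gene ", g)
  }
  taxa <- sort(unique(unlist(lapply(gene_alignments, names))))
  lens <- vapply(gene_alignments, function(a) unique(nchar(a)), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  gap_count <- stats::setNames(numeric(length(taxa)), taxa)
  for (i in seq_along(ord)) {
    aln <- gene_alignments[[i]]
    block <- vapply(taxa, function(tx) {
      if (tx %in% names(aln)) toupper(aln[[tx]])
      else strrep("-", lens[i])
    }, character(1))
    gap_count <- gap_count + ifelse(taxa %in% names(aln), 0, lens[i])
    rows <- paste0(rows, block)
  }
  names(rows) <- taxa
  structure(
    list(taxa = taxa, matrix = rows,
         charsets = data.frame(gene = ord, start = unname(starts),
                               end = unname(ends), stringsAsFactors = FALSE),
         missing_fraction = gap_count / sum(lens),
         length = sum(lens)),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites, %d gene partitions\n",
              length(x$taxa), x$length, nrow(x$charsets)))
  invisible(x)
}

# whitespace-free taxon labels; returns mapping when anything changed
.sanitize_taxa <- function(taxa) {
  clean <- gsub("[^A-Za-z0-9_.-]+", "_", taxa)
  clean <- make.unique(clean, sep = "_")
  data.frame(original = taxa, sanitized = clean, stringsAsFactors = FALSE)
}

#' Export a supermatrix for downstream tree inference
#'
#' Writes the inputs that Bayesian/ML tree programs consume: relaxed
#' PHYLIP, NEXUS with a charset block, and a RAxML-style partition file
#' (`DNA, ND1 = 1-975` lines). Output is byte-stable for identical input.
#' Taxon names containing whitespace or other unsafe characters are
#' sanitized; the mapping is returned.
#'
#' @param sm A [build_supermatrix()] result.
#' @param basename Output path prefix; writes `<basename>.phy`,
#'   `<basename>.nex`, `<basename>.partitions.txt`.
#' @param formats Subset of `c("phylip", "nexus", "partitions")`.
#' @return Invisibly, a list with `files` and the taxon `name_map`.
#' @export
export_supermatrix <- function(sm, basename,
                               formats = c("phylip", "nexus", "partitions")) {
  formats <- match.arg(formats, several.ok = TRUE)
  map <- .sanitize_taxa(sm$taxa)
  rows <- sm$matrix
  names(rows) <- map$sanitized[match(names(rows), map$original)]
  files <- character(0)
  if ("phylip" %in% formats) {
    f <- paste0(basename, ".phy")
    con <- file(f, "wb")
    writeLines(sprintf("%d %d", length(rows), sm$length), con)
    writeLines(sprintf("%s  %s", names(rows), unname(rows)), con)
    close(con)
    files <- c(files, f)
  }
  if ("nexus" %in% formats) {
    f <- paste0(basename, ".nex")
    con <- file(f, "wb")
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(rows), sm$length),
      "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
      "  MATRIX"
    ), con)
    writeLines(sprintf("    %s  %s", names(rows), unname(rows)), con)
    writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
    writeLines(sprintf("  CHARSET %s = %d-%d;", sm$charsets$gene,
                       sm$charsets$start, sm$charsets$end), con)
    writeLines("END;", con)
    close(con)
    files <- c(files, f)
  }
  if ("partitions" %in% formats) {
    f <- paste0(basename, ".partitions.txt")
    con <- file(f, "wb")
    writeLines(sprintf("DNA, %s = %d-%d", sm$charsets$gene,
                       sm$charsets$start, sm$charsets$end), con)
    close(con)
    files <- c(files, f)
  }
  invisible(list(files = files, name_map = map))
}

#' Read a relaxed PHYLIP matrix
#'
#' Counterpart of the PHYLIP writer in [export_supermatrix()].
#'
#' @param path File path.
#' @return Named character vector of aligned sequences.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                         vapply(parts, `[`, character(1), 1L))
  if (length(out) != hdr[1] || any(nchar(out) != hdr[2])) {
    stop("PHYLIP header does not match matrix")
  }
  out
}

#' Neighbor-joining smoke tree
#'
#' Distance-based neighbor joining (via ape) as a quick sanity check of a
#' supermatrix before handing it to full Bayesian/ML inference. Negative
#' branch lengths are clamped to zero (flagged via the `clamped`
#' attribute); taxa are pre-sorted by name so ties resolve
#' deterministically.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal
#'   (matrix or `dist`), taxa as dimnames.
#' @return Newick string (character scalar) with attribute `clamped`.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  if (!isTRUE(all.equal(m, t(m))) || any(m < 0) || any(diag(m) != 0)) {
    stop("need a symmetric nonnegative distance matrix with zero diagonal")
  }
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  if (nrow(m) < 3L) {
    nwk <- if (nrow(m) == 2L) {
      sprintf("(%s:%g,%s:%g);", rownames(m)[1], m[1, 2] / 2,
              rownames(m)[2], m[1, 2] / 2)
    } else sprintf("(%s:0);", rownames(m)[1])
    return(structure(nwk, clamped = FALSE))
  }
  tr <- ape::nj(stats::as.dist(m))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(ape::write.tree(tr), clamped = clamped)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' Convenience bridge from [k2p_saturation()] records to the square
#' distance matrix [nj_tree()] consumes.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(alignment) {
  rec <- k2p_saturation(alignment)
  taxa <- unique(c(rec$seq1, rec$seq2))
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(nrow(rec))) {
    m[rec$seq1[i], rec$seq2[i]] <- rec$k2p[i]
    m[rec$seq2[i], rec$seq1[i]] <- rec$k2p[i]
  }
  m
}
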