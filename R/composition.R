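#' Base composition of a sequence
#'
#' Counts A, C, G, T and ambiguity symbols and converts to percentages of
#' total length. Ambiguity codes contribute to the length (denominator) but
#' have no percentage of their own beyond `other`.
#'
#' @param seq Character scalar nucleotide sequence.
#' @return List with `length`, `counts` (named A,C,G,T,other) and `percent`
#'   (named A,C,G,T,AT,GC), percentages on 0-100.
#' @examples
#' base_composition("AATC")$percent[["A"]]  # 50
#' @export
base_composition <- function(seq) {
  seq <- .check_seq(seq, allow_gap = TRUE)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cnt <- c(A = sum(ch == "A"), C = sum(ch == "C"),
           G = sum(ch == "G"), T = sum(ch == "T"))
  other <- n - sum(cnt)
  pct <- 100 * cnt / n
  list(
    length = n,
    counts = c(cnt, other = other),
    percent = c(pct,
                AT = unname(pct[["A"]] + pct[["T"]]),
                GC = unname(pct[["G"]] + pct[["C"]]))
  )
}

#' AT and GC strand skew
#'
#' `AT-skew = (A - T) / (A + T)` and `GC-skew = (G - C) / (G + C)` on raw
#' counts. A zero denominator yields `NA` (undefined skew), not an error.
#'
#' @param seq Character scalar nucleotide sequence.
#' @return Named numeric vector `c(at_skew, gc_skew)`.
#' @examples
#' at_gc_skew("AATC")  # 0.333..., -1
#' @export
at_gc_skew <- function(seq) {
  cnt <- base_composition(seq)$counts
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  c(at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_)
}

#' Default report partitions
#'
#' The partitioning used in mitogenome characterization tables: the complete
#' genome plus the pooled protein-coding genes, tRNAs, rRNAs and control
#' region.
#'
#' @param genome A [mitogenome()].
#' @return Named list of gene-name character vectors (`complete` is `NULL`,
#'   meaning the whole sequence).
#' @export
default_partitions <- function(genome) {
  g <- genome$genes
  list(
    complete = NULL,
    PCGs = g$gene[g$kind == "PCG"],
    tRNAs = g$gene[g$kind == "tRNA"],
    rRNAs = g$gene[g$kind == "rRNA"],
    CR = g$gene[g$kind == "CR"]
  )
}

#' Partitioned composition profile
#'
#' Composition, A+T content and skews per named partition. Each partition's
#' sequence is the concatenation of its member genes in table order, each
#' taken on its coding strand (light-strand genes reverse-complemented);
#' `reference_strand = TRUE` instead uses the heavy-strand slice for every
#' gene. In table-only mode the composition columns are `NA` but lengths and
#' genome percentages are still computed.
#'
#' @param genome A [mitogenome()].
#' @param partitions Named list of gene-name vectors (a `NULL` element means
#'   the complete sequence); default [default_partitions()].
#' @param reference_strand Logical; see above.
#' @return Data frame with columns `partition`, `length_bp`, `pct_A`,
#'   `pct_T`, `pct_G`, `pct_C`, `pct_AT`, `at_skew`, `gc_skew`,
#'   `pct_of_genome`. Raw (unrounded) values.
#' @export
partition_profile <- function(genome, partitions = default_partitions(genome),
                              reference_strand = FALSE) {
  L <- genome$genome_length
  rows <- lapply(names(partitions), function(nm) {
    members <- partitions[[nm]]
    if (is.null(members)) {
      len <- L
      seq <- genome$sequence
    } else {
      if (!length(members)) {
        warning("empty partition skipped: ", nm)
        return(NULL)
      }
      idx <- match(members, genome$genes$gene)
      if (anyNA(idx)) stop("unknown gene(s) in partition ", nm, ": ",
                           paste(members[is.na(idx)], collapse = ", "))
      idx <- sort(idx)
      len <- sum(genome$genes$size[idx])
      seq <- if (is.null(genome$sequence)) NULL else {
        paste(vapply(idx, function(i) {
          r <- genome$genes[i, ]
          if (reference_strand) r$strand <- "+"
          extract_gene_sequence(genome, r)
        }, character(1)), collapse = "")
      }
    }
    if (is.null(seq)) {
      data.frame(partition = nm, length_bp = len, pct_A = NA_real_,
                 pct_T = NA_real_, pct_G = NA_real_, pct_C = NA_real_,
                 pct_AT = NA_real_, at_skew = NA_real_, gc_skew = NA_real_,
                 pct_of_genome = 100 * len / L, stringsAsFactors = FALSE)
    } else {
      bc <- base_composition(seq)
      sk <- at_gc_skew(seq)
      data.frame(partition = nm, length_bp = len,
                 pct_A = bc$percent[["A"]], pct_T = bc$percent[["T"]],
                 pct_G = bc$percent[["G"]], pct_C = bc$percent[["C"]],
                 pct_AT = bc$percent[["AT"]],
                 at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
                 pct_of_genome = 100 * len / L, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Intergenic layout: spacers and overlaps
#'
#' Recomputes the intergenic-nucleotide (IN) column of an annotation table:
#' `IN(gene_i) = start(gene_{i+1}) - stop(gene_i) - 1` in table order, with
#' the last feature's IN closing the circle back to the first feature.
#' Negative values are overlaps with the next feature.
#'
#' @param genome A [mitogenome()] (sequence not required).
#' @return List with `layout` (data frame `gene`, `next_gene`, `in_bp`) and
#'   `summary` (list: `overlap_count`, `overlap_total_bp`,
#'   `longest_overlap_bp`, `longest_overlap_pair`, `longest_spacer_bp`,
#'   `longest_spacer_gene`).
#' @export
intergenic_layout <- function(genome) {
  g <- genome$genes
  if (nrow(g) < 2L) stop("need at least two features for layout arithmetic")
  L <- genome$genome_length
  nxt <- c(seq_len(nrow(g))[-1L], 1L)
  in_bp <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    j <- nxt[i]
    gap <- g$start[j] - g$stop[i] - 1L
    if (i == nrow(g) && genome$circular) gap <- gap + L
    in_bp[i] <- gap
  }
  layout <- data.frame(gene = g$gene, next_gene = g$gene[nxt], in_bp = in_bp,
                       stringsAsFactors = FALSE)
  if (!genome$circular) layout <- layout[-nrow(layout), , drop = FALSE]
  ov <- layout[layout$in_bp < 0L, , drop = FALSE]
  sp <- layout[layout$in_bp > 0L, , drop = FALSE]
  iov <- if (nrow(ov)) which.min(ov$in_bp) else NA_integer_
  isp <- if (nrow(sp)) which.max(sp$in_bp) else NA_integer_
  list(
    layout = layout,
    summary = list(
      overlap_count = nrow(ov),
      overlap_total_bp = sum(abs(ov$in_bp)),
      longest_overlap_bp = if (nrow(ov)) max(abs(ov$in_bp)) else 0L,
      longest_overlap_pair = if (nrow(ov)) c(ov$gene[iov], ov$next_gene[iov]) else character(0),
      longest_spacer_bp = if (nrow(sp)) max(sp$in_bp) else 0L,
      longest_spacer_gene = if (nrow(sp)) sp$gene[isp] else character(0)
    )
  )
}

#' Start and stop codon classification per protein-coding gene
#'
#' Reads each PCG on its coding strand and classifies its endpoints. Stop
#' classification follows gene size modulo 3: `0` means a complete terminal
#' triplet (flagged when it is not a legal stop), `2` means the incomplete
#' stop `"TA-"` when the trailing dinucleotide is TA, and `1` means `"T--"`
#' when the trailing nucleotide is T; incomplete stops are completed to TAA
#' by polyadenylation of the mature transcript. Anything else is flagged
#' anomalous.
#'
#' @param genome A [mitogenome()] with sequence.
#' @param code A [mito_genetic_code()].
#' @return Data frame: `gene`, `size`, `start_codon`, `start_ok`,
#'   `stop_codon` (triplet, `"TA-"` or `"T--"`), `stop_complete`,
#'   `anomalous`.
#' @export
codon_endpoints <- function(genome, code = mito_genetic_code()) {
  if (is.null(genome$sequence)) stop("codon_endpoints() needs the sequence")
  pcg <- genome$genes[genome$genes$kind == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    r <- pcg[i, ]
    cds <- extract_gene_sequence(genome, r)
    if (nchar(cds) < 6L) stop("PCG shorter than 6 nt: ", r$gene)
    start_codon <- substr(cds, 1L, 3L)
    m <- nchar(cds) %% 3L
    anomalous <- FALSE
    if (m == 0L) {
      stop_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
      complete <- TRUE
      if (!stop_codon %in% code$stop_codons) anomalous <- TRUE
    } else if (m == 2L) {
      tail2 <- substr(cds, nchar(cds) - 1L, nchar(cds))
      stop_codon <- "TA-"; complete <- FALSE
      if (tail2 != "TA") { anomalous <- TRUE; stop_codon <- paste0(tail2, "-") }
    } else {
      tail1 <- substr(cds, nchar(cds), nchar(cds))
      stop_codon <- "T--"; complete <- FALSE
      if (tail1 != "T") { anomalous <- TRUE; stop_codon <- paste0(tail1, "--") }
    }
    data.frame(gene = r$gene, size = r$size, start_codon = start_codon,
               start_ok = start_codon %in% code$start_codons,
               stop_codon = stop_codon, stop_complete = complete,
               anomalous = anomalous, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify incomplete termination codons from printed sizes alone
#'
#' Size modulo 3 of a protein-coding gene identifies genes that cannot end
#' in a complete triplet; these are the genes completed to TAA by
#' polyadenylation.
#'
#' @param genome A [mitogenome()] (table-only is fine).
#' @return Character vector of PCG names whose size is not a multiple of 3.
#' @export
incomplete_stop_genes <- function(genome) {
  pcg <- genome$genes[genome$genes$kind == "PCG", , drop = FALSE]
  sort(pcg$gene[pcg$size %% 3L != 0L])
}
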