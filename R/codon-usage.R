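#' Codon counts over a set of coding sequences
#'
#' Counts complete in-frame codons read from position 1 of each coding
#' sequence. By default stop codons (terminal or internal) are excluded
#' from the table and the total, and incomplete trailing codons are always
#' dropped.
#'
#' @param cds_list Character vector (or list) of coding-strand CDS.
#' @param code A [mito_genetic_code()].
#' @param include_stops Logical; count stop codons too.
#' @return Object of class `codon_usage`: list with `per_codon` (named
#'   64-entry integer vector), `per_aa` (named counts by amino acid),
#'   `total_codons`, and the `code` used.
#' @examples
#' cu <- codon_counts("ATGAAATAA")
#' cu$per_codon[c("ATG", "AAA")]
#' cu$total_codons  # 2
#' @export
codon_counts <- function(cds_list, code = mito_genetic_code(),
                         include_stops = FALSE) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  if (!length(cds_list)) stop("empty CDS list")
  per_codon <- stats::setNames(integer(64L), names(code$codons))
  for (cds in cds_list) {
    cds <- .check_seq(cds)
    n_codon <- nchar(cds) %/% 3L
    if (n_codon == 0L) next
    codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    codons <- codons[codons %in% names(per_codon)]  # skip ambiguous codons
    tab <- table(codons)
    per_codon[names(tab)] <- per_codon[names(tab)] + as.integer(tab)
  }
  if (!include_stops) per_codon[code$codons == "*"] <- 0L
  aa <- code$codons
  per_aa <- tapply(per_codon, aa, sum)
  per_aa <- per_aa[names(per_aa) != "*" | include_stops]
  structure(
    list(per_codon = per_codon,
         per_aa = per_aa[order(names(per_aa))],
         total_codons = sum(per_codon[code$codons != "*"]),
         include_stops = include_stops,
         code = code),
    class = "codon_usage"
  )
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = k * n_c / sum(n_c' over the family)` where `k` is the number
#' of synonymous codons encoding the amino acid under the vertebrate
#' mitochondrial code (families follow the amino acid, not the codon block:
#' leucine is TTR + CTN, serine is TCN + AGY, six codons each). Families
#' with zero counts get `NA`.
#'
#' @param usage A [codon_counts()] result.
#' @return Data frame: `codon`, `aa`, `count`, `family_size`, `rscu`.
#' @export
rscu <- function(usage) {
  code <- usage$code
  sense <- names(code$codons)[code$codons != "*"]
  aa <- code$codons[sense]
  fam_size <- table(aa)
  fam_total <- tapply(usage$per_codon[sense], aa, sum)
  out <- data.frame(
    codon = sense,
    aa = unname(aa),
    count = unname(usage$per_codon[sense]),
    family_size = as.integer(fam_size[aa]),
    stringsAsFactors = FALSE
  )
  tot <- as.numeric(fam_total[out$aa])
  out$rscu <- ifelse(tot > 0, out$family_size * out$count / tot, NA_real_)
  rownames(out) <- NULL
  out
}

#' Amino-acid usage frequencies
#'
#' Relative frequency of each amino acid among all counted sense codons,
#' ranked most-abundant first.
#'
#' @param usage A [codon_counts()] result.
#' @return Data frame: `aa`, `count`, `frequency`, `rank`.
#' @export
aa_frequencies <- function(usage) {
  code <- usage$code
  sense <- names(code$codons)[code$codons != "*"]
  fam_total <- tapply(usage$per_codon[sense], code$codons[sense], sum)
  out <- data.frame(
    aa = names(fam_total),
    count = as.integer(fam_total),
    frequency = as.numeric(fam_total) / max(1L, usage$total_codons),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$aa), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
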