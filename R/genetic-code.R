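#' Vertebrate mitochondrial genetic code
#'
#' Returns the genetic code used throughout the package. The default is NCBI
#' translation table 2 (vertebrate mitochondrial), whose departures from the
#' standard code matter for every downstream statistic: `ATA` encodes Met,
#' `TGA` encodes Trp, and `AGA`/`AGG` are stop codons, so leucine and serine
#' each keep six-codon families while arginine drops to four.
#'
#' @param id Integer translation-table id. Only table 2 is shipped; the
#'   argument exists so callers can assert which code they are using.
#' @return An object of class `genetic_code`: a list with elements
#'   `id`, `codons` (named character vector of 64 amino-acid letters, `"*"`
#'   for stop), `start_codons` (default `ATG`, `GTG`) and `stop_codons`
#'   (`TAA`, `TAG`, `AGA`, `AGG`).
#' @examples
#' code <- mito_genetic_code()
#' code$codons[c("ATA", "TGA", "AGA")]
#' @export
mito_genetic_code <- function(id = 2L) {
  if (!identical(as.integer(id), 2L)) {
    stop("only the vertebrate mitochondrial code (table 2) is shipped")
  }
  structure(
    list(
      id = 2L,
      codons = .code2_table(),
      start_codons = c("ATG", "GTG"),
      stop_codons = c("TAA", "TAG", "AGA", "AGG")
    ),
    class = "genetic_code"
  )
}

# NCBI table 2 in the conventional TCAG codon order
.code2_table <- function() {
  aas <- strsplit(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
    ""
  )[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
  stats::setNames(aas, codons)
}

#' Translate an in-frame coding sequence
#'
#' Translates complete codons from position 1. A trailing 1-2 nt remainder
#' (the hallmark of mitochondrial genes with incomplete termination codons)
#' is ignored and flagged via the `incomplete_tail` attribute.
#'
#' @param cds Character scalar, coding-strand nucleotide sequence.
#' @param code A [mito_genetic_code()] object.
#' @return Character scalar protein sequence; stop codons render as `"*"`,
#'   codons containing non-ACGT symbols as `"X"` (with a warning). Attribute
#'   `incomplete_tail` gives the number of trailing nucleotides dropped.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' translate_cds("ATATGA")     # "MW" under the vertebrate mito code
#' @export
translate_cds <- function(cds, code = mito_genetic_code()) {
  cds <- .check_seq(cds)
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  n_codon <- nchar(cds) %/% 3L
  tail_nt <- nchar(cds) %% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(code$codons[codons])
  if (anyNA(aa)) {
    warning("ambiguous codon(s) translated as 'X'")
    aa[is.na(aa)] <- "X"
  }
  structure(paste(aa, collapse = ""), incomplete_tail = tail_nt)
}

#' Validate the reading frame of a protein-coding gene
#'
#' Checks what an ORF finder would check: that the gene starts with a legal
#' initiation codon, contains no internal in-frame stop codons, and reports
#' its length modulo 3 (non-zero values are expected for genes with
#' incomplete termination codons completed by polyadenylation).
#'
#' @param genome An [mitogenome()] with sequence present.
#' @param gene Gene name (character) or a single-row gene-table subset; must
#'   be of kind `"PCG"`.
#' @param code A [mito_genetic_code()] object.
#' @return List with elements `gene`, `start_codon`, `start_ok`,
#'   `internal_stop_codons` (integer codon indices, excluding the terminal
#'   codon), `length_mod3`, and `terminal_codon` (last complete codon).
#' @export
validate_orf <- function(genome, gene, code = mito_genetic_code()) {
  rec <- .resolve_gene(genome, gene)
  if (rec$kind != "PCG") {
    stop("validate_orf() applies to protein-coding genes only, got kind ",
         rec$kind)
  }
  cds <- extract_gene_sequence(genome, rec)
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(code$codons[codons])
  internal <- which(!is.na(aa) & aa == "*")
  internal <- internal[internal < n_codon]
  list(
    gene = rec$gene,
    start_codon = codons[1L],
    start_ok = codons[1L] %in% code$start_codons,
    internal_stop_codons = internal,
    length_mod3 = nchar(cds) %% 3L,
    terminal_codon = codons[n_codon]
  )
}
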