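IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

# uppercase + validate a nucleotide string
.check_seq <- function(x, allow_gap = FALSE) {
  if (length(x) != 1L || !is.character(x)) stop("sequence must be a single string")
  x <- toupper(x)
  if (nchar(x) == 0L) stop("empty sequence")
  allowed <- if (allow_gap) IUPAC_NT else setdiff(IUPAC_NT, "-")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), allowed)
  if (length(bad)) {
    stop("non-IUPAC nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC-aware reverse complement (gaps preserved).
#'
#' @param x Character scalar nucleotide sequence.
#' @return Character scalar.
#' @examples
#' revcomp("ATGC")  # "GCAT"
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# expansion of IUPAC symbols into base sets (used by the motif scanner and
# the simulator)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
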