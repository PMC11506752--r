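# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (enumeration, direct loops) rather
# than calling the implementation paths they check.

# all permutations of a small vector
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Nei-Gojobori by exhaustive pathway enumeration; independent of ng86_pair.
# Returns list(S, N, Sd, Nd).
oracle_ng86 <- function(cds1, cds2, code = mito_genetic_code()) {
  aa_of <- function(codon) code$codons[[codon]]
  n <- nchar(cds1) / 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    c1 <- substr(cds1, 3 * i - 2, 3 * i)
    c2 <- substr(cds2, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (aa_of(c1) == "*" || aa_of(c2) == "*") next
    for (codon in c(c1, c2)) {
      for (pos in 1:3) {
        alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
        keep <- vapply(alts, function(b) {
          alt <- codon; substr(alt, pos, pos) <- b
          aa_of(alt) != "*"
        }, logical(1))
        if (any(keep)) {
          syn <- vapply(alts[keep], function(b) {
            alt <- codon; substr(alt, pos, pos) <- b
            aa_of(alt) == aa_of(codon)
          }, logical(1))
          S <- S + mean(syn) / 2
          N <- N + (1 - mean(syn)) / 2
        }
      }
    }
    dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dpos)) next
    path_syn <- c(); path_ok <- c()
    for (ord in perms_of(dpos)) {
      cur <- c1; syn <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (aa_of(nxt) == "*" && nxt != c2) ok <- FALSE
        if (aa_of(cur) == aa_of(nxt)) syn <- syn + 1
        cur <- nxt
      }
      path_syn <- c(path_syn, syn); path_ok <- c(path_ok, ok)
    }
    use <- if (any(path_ok)) path_syn[path_ok] else path_syn
    Sd <- Sd + mean(use)
    Nd <- Nd + length(dpos) - mean(use)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# character-by-character IUPAC motif scan
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_motif_scan <- function(seq, motif, max_mismatch) {
  qs <- strsplit(seq, "")[[1]]
  mo <- strsplit(motif, "")[[1]]
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  for (s in seq_len(length(qs) - length(mo) + 1)) {
    mm <- 0
    for (p in seq_along(mo)) {
      if (!qs[s + p - 1] %in% IUPAC_ORACLE[[mo[p]]]) mm <- mm + 1
    }
    if (mm <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
    }
  }
  hits
}

# mean pairwise p-distance with complete deletion of non-ACGT columns
oracle_mean_pdist <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); tot <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(m[i, ] != m[j, ]); k <- k + 1
  }
  tot / k
}

# random stop-free in-frame CDS under the vertebrate mito code
random_cds <- function(n_codon, seed) {
  code <- mito_genetic_code()
  sense <- names(code$codons)[code$codons != "*"]
  set.seed(seed)
  paste(sample(sense, n_codon, replace = TRUE), collapse = "")
}

table1 <- function() selene_table1()
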