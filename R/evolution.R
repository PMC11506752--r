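#' Synonymous and nonsynonymous site counts of one codon
#'
#' Nei-Gojobori (1986) site counting under an arbitrary genetic code. For
#' each codon position the three possible single-nucleotide changes are
#' classified; changes that create a stop codon are excluded from both
#' numerator and denominator, so each position contributes the fraction of
#' its non-stop changes that are synonymous (a position whose every change
#' creates a stop contributes nothing, i.e. site loss).
#'
#' @param codon Character scalar, 3 nt over ACGT, not a stop codon.
#' @param code A [mito_genetic_code()].
#' @param include_stop_changes Logical; count stop-creating changes as
#'   nonsynonymous instead of excluding them (the alternative convention).
#' @return Named numeric vector `c(s, n)` with `s + n <= 3`.
#' @examples
#' ng86_sites("GGT")  # glycine: third position fully synonymous
#' @export
ng86_sites <- function(codon, code = mito_genetic_code(),
                       include_stop_changes = FALSE) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be 3 nt over ACGT")
  }
  aa <- code$codons[[codon]]
  if (aa == "*") stop("stop codon has no site decomposition: ", codon)
  bases <- c("A", "C", "G", "T")
  s <- 0; n <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0L; tot <- 0L
    for (b in setdiff(bases, ref)) {
      alt <- codon
      substr(alt, pos, pos) <- b
      alt_aa <- code$codons[[alt]]
      if (alt_aa == "*") {
        if (include_stop_changes) { tot <- tot + 1L }
        next
      }
      tot <- tot + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (tot > 0L) {
      s <- s + syn / tot
      n <- n + 1 - syn / tot
    }
  }
  c(s = s, n = n)
}

# pathway-averaged (syn, nonsyn) difference counts between two codons,
# excluding (by default) mutational pathways that traverse a stop codon
.ng86_codon_diff <- function(c1, c2, code, include_stop_paths = FALSE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0, fallback = 0))
  perms <- switch(d,
                  list(pos),
                  list(pos, rev(pos)),
                  {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  score_path <- function(ord) {
    cur <- c1
    syn <- 0L
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- code$codons[[cur]]; a2 <- code$codons[[nxt]]
      if (a2 == "*" && !identical(nxt, c2)) return(NULL)  # stop intermediate
      if (a1 == a2) syn <- syn + 1L
      cur <- nxt
    }
    syn
  }
  syns <- unlist(lapply(perms, score_path))
  fallback <- 0
  if (!length(syns) && !include_stop_paths) {
    # every pathway hits a stop: fall back to averaging over all pathways
    fallback <- 1
    syns <- vapply(perms, function(ord) {
      cur <- c1; syn <- 0L
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code$codons[[cur]] == code$codons[[nxt]]) syn <- syn + 1L
        cur <- nxt
      }
      syn
    }, integer(1))
  } else if (include_stop_paths) {
    syns <- vapply(perms, function(ord) {
      cur <- c1; syn <- 0L
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code$codons[[cur]] == code$codons[[nxt]]) syn <- syn + 1L
        cur <- nxt
      }
      syn
    }, integer(1))
  }
  sd <- mean(syns)
  c(sd = sd, nd = d - sd, fallback = fallback)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) pathway method
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and pathway-averaged synonymous/nonsynonymous differences between two
#' in-frame aligned coding sequences, then applies the Jukes-Cantor
#' correction `d = -3/4 * log(1 - 4p/3)` to the proportions. Codon pairs
#' containing gaps, ambiguity symbols or stop codons are dropped pairwise.
#'
#' @param cds1,cds2 Equal-length in-frame aligned CDS strings.
#' @param code A [mito_genetic_code()].
#' @param include_stop_paths Logical; include stop-traversing mutational
#'   pathways (and count stop-creating changes as nonsynonymous sites).
#' @param gene Optional label carried into the result.
#' @return Object of class `pairwise_selection`: list with `gene`,
#'   `codons_compared`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`,
#'   `ka_ks` (`NA` when `Ks` is 0 or a proportion is saturated), and
#'   `pathway_fallbacks` (codon pairs where every pathway hit a stop).
#' @examples
#' ng86_pair("ATGAAA", "ATGAAG")$Sd  # one synonymous difference
#' @export
ng86_pair <- function(cds1, cds2, code = mito_genetic_code(),
                      include_stop_paths = FALSE, gene = NA_character_) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2)) stop("sequences differ in length")
  if (nchar(cds1) %% 3L != 0L) stop("alignment length not a multiple of 3")
  n_codon <- nchar(cds1) %/% 3L
  if (n_codon == 0L) stop("empty alignment")
  idx <- 3L * seq_len(n_codon)
  co1 <- substring(cds1, idx - 2L, idx)
  co2 <- substring(cds2, idx - 2L, idx)
  clean <- !grepl("[^ACGT]", co1) & !grepl("[^ACGT]", co2)
  stops <- rep(FALSE, n_codon)
  stops[clean] <- code$codons[co1[clean]] == "*" | code$codons[co2[clean]] == "*"
  use <- clean & !stops
  if (!any(use)) stop("no comparable codon pairs")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; fallbacks <- 0L
  for (i in which(use)) {
    s1 <- ng86_sites(co1[i], code, include_stop_changes = include_stop_paths)
    s2 <- ng86_sites(co2[i], code, include_stop_changes = include_stop_paths)
    S <- S + (s1[["s"]] + s2[["s"]]) / 2
    N <- N + (s1[["n"]] + s2[["n"]]) / 2
    d <- .ng86_codon_diff(co1[i], co2[i], code, include_stop_paths)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    fallbacks <- fallbacks + as.integer(d[["fallback"]] > 0)
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)  # saturation marker
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(
    list(gene = gene, codons_compared = sum(use), S = S, N = N,
         Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka,
         ka_ks = ratio, pathway_fallbacks = fallbacks),
    class = "pairwise_selection"
  )
}

#' @export
print.pairwise_selection <- function(x, ...) {
  cat(sprintf(
    "<Ka/Ks (NG86)> %s: %d codons | S %.2f N %.2f | Sd %.2f Nd %.2f | Ks %s Ka %s | Ka/Ks %s\n",
    ifelse(is.na(x$gene), "(unnamed)", x$gene), x$codons_compared,
    x$S, x$N, x$Sd, x$Nd,
    ifelse(is.na(x$Ks), "NA", sprintf("%.4f", x$Ks)),
    ifelse(is.na(x$Ka), "NA", sprintf("%.4f", x$Ka)),
    ifelse(is.na(x$ka_ks),
           sprintf("undef (Ka=%s)", ifelse(is.na(x$Ka), "NA", sprintf("%.4f", x$Ka))),
           sprintf("%.4f", x$ka_ks))
  ))
  invisible(x)
}

# alignment as a character matrix (rows = sequences)
.aln_matrix <- function(alignment) {
  if (is.list(alignment)) alignment <- unlist(alignment)
  if (length(alignment) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(alignment))) != 1L) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Nucleotide diversity (pi)
#'
#' Average over all sequence pairs of the per-site difference proportion.
#' Under complete deletion (the default) every column containing a gap or
#' ambiguity symbol in any sequence is excluded before comparison; under
#' pairwise deletion each pair uses its own clean columns.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAATT"))  # 0.2
#' @export
nucleotide_diversity <- function(alignment,
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .aln_matrix(alignment)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  if (deletion == "complete") {
    keep <- apply(ok, 2L, all)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  tot <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      sites <- sum(use)
      tot <- tot + if (sites > 0) sum(m[i, use] != m[j, use]) / sites else 0
      npair <- npair + 1L
    }
  }
  tot / npair
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at 1, 1+step, ... while the full window fits inside the
#' alignment; each window's pi comes from [nucleotide_diversity()] on the
#' slice. Defaults mirror the conventional DnaSP setting of a 200 bp window
#' sliding by 25 bp.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param window,step Window and step sizes in bp.
#' @param deletion Passed to [nucleotide_diversity()].
#' @return List of class `diversity_result`: `pi` (global), `windows`
#'   (data frame `start`, `end`, `midpoint`, `pi`), `window`, `step`,
#'   `truncated` (TRUE when the window exceeded the alignment and a single
#'   truncated window was used).
#' @export
sliding_window_pi <- function(alignment, window = 200L, step = 25L,
                              deletion = "complete") {
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  m_len <- unique(nchar(unlist(alignment)))
  if (length(m_len) != 1L) stop("ragged alignment")
  truncated <- FALSE
  if (window > m_len) {
    truncated <- TRUE
    starts <- 1L
    window_eff <- m_len
  } else {
    starts <- seq.int(1L, m_len - window + 1L, by = step)
    window_eff <- window
  }
  seqs <- unlist(alignment)
  rows <- lapply(starts, function(s) {
    e <- s + window_eff - 1L
    data.frame(start = s, end = e, midpoint = (s + e) / 2,
               pi = nucleotide_diversity(substr(seqs, s, e), deletion))
  })
  structure(
    list(pi = nucleotide_diversity(seqs, deletion),
         windows = do.call(rbind, rows),
         window = window, step = step, truncated = truncated),
    class = "diversity_result"
  )
}

#' Transition/transversion saturation against K2P distance
#'
#' For every sequence pair: the transition proportion `p` (A<->G, C<->T),
#' the transversion proportion `q`, and the Kimura 2-parameter distance
#' `d = -1/2 log(1 - 2p - q) - 1/4 log(1 - 2q)` over the pair's ungapped
#' unambiguous sites. Plotting p and q against d is the standard visual
#' check for substitution saturation.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Data frame: `seq1`, `seq2`, `sites`, `p`, `q`, `k2p` (`Inf` when
#'   the log domain is violated, i.e. distances beyond the model).
#' @export
k2p_saturation <- function(alignment) {
  m <- .aln_matrix(alignment)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  purine <- function(x) x %in% c("A", "G")
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      sites <- sum(use)
      a <- m[i, use]; b <- m[j, use]
      diff <- a != b
      ts <- sum(diff & (purine(a) == purine(b)))
      tv <- sum(diff) - ts
      p <- ts / sites; q <- tv / sites
      k2p <- if (1 - 2 * p - q > 0 && 1 - 2 * q > 0) {
        -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
      } else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        seq1 = rownames(m)[i] %||% as.character(i),
        seq2 = rownames(m)[j] %||% as.character(j),
        sites = sites, p = p, q = q, k2p = k2p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
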