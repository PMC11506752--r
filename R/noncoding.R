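#' IUPAC-aware motif scan with mismatches
#'
#' Slides the motif along the query and reports every position where the
#' number of Hamming mismatches is at most `max_mismatch`. A motif symbol
#' matches a query base when the IUPAC set of the motif symbol contains the
#' base (so `Y` matches `T` or `C`, but a plain base never matches an
#' ambiguous query base). Overlapping hits are allowed.
#'
#' @param seq Query sequence (character scalar).
#' @param motif IUPAC pattern (character scalar), no longer than the query.
#' @param max_mismatch Maximum mismatches allowed (default 0).
#' @return Data frame of hits: `start`, `end`, `mismatches`, `match` (the
#'   matched subsequence). Zero rows when nothing matches.
#' @examples
#' motif_search("GGTATGG", "TAY", max_mismatch = 0)
#' @export
motif_search <- function(seq, motif, max_mismatch = 0L) {
  seq <- .check_seq(seq, allow_gap = FALSE)
  motif <- toupper(motif)
  mo <- strsplit(motif, "")[[1]]
  if (any(!mo %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC symbol in motif: ",
         paste(setdiff(mo, names(IUPAC_SETS)), collapse = ", "))
  }
  k <- length(mo)
  qs <- strsplit(seq, "")[[1]]
  n <- length(qs)
  if (k > n) stop("motif longer than sequence")
  # per motif position, which query bases match
  match_tbl <- lapply(mo, function(sym) IUPAC_SETS[[sym]])
  hits <- list()
  for (s in seq_len(n - k + 1L)) {
    mm <- 0L
    for (p in seq_len(k)) {
      if (!(qs[s + p - 1L] %in% match_tbl[[p]])) {
        mm <- mm + 1L
        if (mm > max_mismatch) break
      }
    }
    if (mm <= max_mismatch) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = s + k - 1L, mismatches = mm,
        match = substr(seq, s, s + k - 1L), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Default conserved-sequence-block motif set
#'
#' Placeholder IUPAC consensus motifs for the four conserved domains of the
#' teleost mitochondrial control region, at the lengths characteristic of
#' Selene control regions: CSB-D 18 bp, CSB-1 22 bp, CSB-2 17 bp, CSB-3
#' 19 bp. These are configuration data, not biology: published CSB
#' consensus figures are not machine-readable, so real analyses should
#' override this set with study-specific motifs (see [read_motifs()]).
#'
#' @return Named character vector of IUPAC motifs, in the expected
#'   5' to 3' order CSB-D, CSB-1, CSB-2, CSB-3.
#' @export
csb_motifs <- function() {
  c(
    `CSB-D` = "TACATRYATCTATTATCA",
    `CSB-1` = "ATTACATAAAAACCCCCCTACC",
    `CSB-2` = "CAAACCCCCCTACCCCC",
    `CSB-3` = "TGTCAAACCCCGAAACCAG"
  )
}

#' Read a motif configuration file
#'
#' Simple `name<TAB>pattern` text format (lines starting with `#` ignored).
#'
#' @param path Path to the motif file.
#' @return Named character vector of IUPAC motifs.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  stats::setNames(toupper(vapply(parts, `[`, character(1), 2L)),
                  vapply(parts, `[`, character(1), 1L))
}

#' Locate conserved sequence blocks in a control region
#'
#' Scans the control-region sequence for each motif, keeps the best hit per
#' motif (fewest mismatches, then leftmost), and checks that the found
#' blocks appear in the canonical CSB-D < CSB-1 < CSB-2 < CSB-3 order.
#'
#' @param cr_seq Control-region sequence.
#' @param motifs Named IUPAC motif vector, default [csb_motifs()].
#' @param max_mismatch Single value or per-motif vector of allowed
#'   mismatches.
#' @return List with `hits` (data frame `motif`, `found`, `start`, `end`,
#'   `length`, `mismatches`, `match`) and `order_ok` (logical; `NA` when
#'   fewer than two motifs were found).
#' @export
find_csb <- function(cr_seq, motifs = csb_motifs(), max_mismatch = 2L) {
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    stop("motifs must be named")
  }
  max_mismatch <- rep_len(max_mismatch, length(motifs))
  rows <- lapply(seq_along(motifs), function(i) {
    h <- motif_search(cr_seq, motifs[[i]], max_mismatch[i])
    if (!nrow(h)) {
      data.frame(motif = names(motifs)[i], found = FALSE, start = NA_integer_,
                 end = NA_integer_, length = nchar(motifs[[i]]),
                 mismatches = NA_integer_, match = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      h <- h[order(h$mismatches, h$start), , drop = FALSE][1L, ]
      data.frame(motif = names(motifs)[i], found = TRUE, start = h$start,
                 end = h$end, length = nchar(motifs[[i]]),
                 mismatches = h$mismatches, match = h$match,
                 stringsAsFactors = FALSE)
    }
  })
  hits <- do.call(rbind, rows)
  found <- hits[hits$found, , drop = FALSE]
  order_ok <- if (nrow(found) < 2L) NA else !is.unsorted(found$start, strictly = TRUE)
  list(hits = hits, order_ok = order_ok)
}

# ---- tRNA cloverleaf heuristic -----------------------------------------

# Watson-Crick + GU wobble pairing
.pairs_ok <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# fraction of paired positions when stem1 (5'->3') pairs antiparallel with
# stem2 (5'->3')
.stem_fraction <- function(x, s1, l1, s2, l2) {
  a <- x[s1:(s1 + l1 - 1L)]
  b <- x[(s2 + l2 - 1L):s2]
  mean(.pairs_ok(a, b))
}

#' Heuristic cloverleaf folding of a tRNA gene
#'
#' Transparent arm-by-arm heuristic (not a covariance model): the acceptor
#' stem is the best antiparallel pairing of the 5' 7-mer against a 3' 7-mer
#' (Watson-Crick plus GU wobble, present at >= 5/7 paired); the anticodon
#' arm is the best 5 bp stem + 7 nt loop hairpin in the middle third of the
#' sequence, its loop's central triplet being the anticodon; the DHU arm is
#' a >= 3 bp perfectly paired hairpin between the acceptor stem and the
#' anticodon arm; the T-arm a >= 4 bp hairpin between the anticodon arm and
#' the 3' acceptor side. A trailing CCA (added post-transcriptionally in
#' mature tRNAs) is detected and ignored.
#'
#' @param seq tRNA gene sequence, 55-95 nt.
#' @param expected_anticodon Optional triplet; when given, a mismatch with
#'   the recovered anticodon is reported in `anticodon_matches`.
#' @return List of class `cloverleaf_report` with elements `acceptor`,
#'   `dhu`, `anticodon_arm`, `tpsic` (each a list `present`, `stem_length`,
#'   `paired_fraction`), plus `anticodon`, `anticodon_matches`,
#'   `cca_trimmed`.
#' @export
fold_trna <- function(seq, expected_anticodon = NULL) {
  seq <- .check_seq(seq)
  cca <- FALSE
  if (nchar(seq) >= 58L && endsWith(seq, "CCA")) {
    # fold the gene body; the mature 3' CCA is unpaired
    body <- substr(seq, 1L, nchar(seq) - 3L)
    if (nchar(body) >= 55L) { seq <- body; cca <- TRUE }
  }
  n <- nchar(seq)
  if (n < 55L || n > 95L) stop("sequence length ", n, " outside 55-95 nt")
  x <- strsplit(seq, "")[[1]]

  # acceptor stem: 5' positions 1..7 against the last 7 nt (allowing a
  # 0-4 nt discriminator/overhang before the 3' end)
  acc_best <- 0; acc_off <- 0L
  for (off in 0:4) {
    s2 <- n - 6L - off
    if (s2 <= 7L) next
    f <- .stem_fraction(x, 1L, 7L, s2, 7L)
    if (f > acc_best) { acc_best <- f; acc_off <- off }
  }
  acceptor <- list(present = acc_best >= 5 / 7, stem_length = 7L,
                   paired_fraction = acc_best)

  # anticodon arm: 5 bp stem + 7 nt loop + 5 bp stem, searched in the
  # middle third
  third <- floor(n / 3)
  ac_best <- -1; ac_start <- NA_integer_
  for (s in seq.int(max(8L, third - 10L), min(n - 16L, 2L * third))) {
    f <- .stem_fraction(x, s, 5L, s + 12L, 5L)
    if (f > ac_best) { ac_best <- f; ac_start <- s }
  }
  anticodon <- NA_character_
  if (!is.na(ac_start)) {
    loop <- x[(ac_start + 5L):(ac_start + 11L)]
    anticodon <- paste(loop[3:5], collapse = "")
  }
  anticodon_arm <- list(present = !is.na(ac_start) && ac_best >= 4 / 5,
                        stem_length = 5L, paired_fraction = max(ac_best, 0))

  # DHU arm: >= 3 bp perfect hairpin strictly between acceptor 5' stem and
  # the anticodon arm
  dhu_region <- c(8L, if (!is.na(ac_start)) ac_start - 1L else third)
  dhu <- .find_hairpin(x, dhu_region[1], dhu_region[2], min_stem = 3L)

  # T-arm: >= 4 bp hairpin between anticodon arm and 3' acceptor side
  t_from <- if (!is.na(ac_start)) ac_start + 17L else 2L * third
  tpsic <- .find_hairpin(x, t_from, n - 7L - acc_off, min_stem = 4L)

  res <- list(
    acceptor = acceptor, dhu = dhu, anticodon_arm = anticodon_arm,
    tpsic = tpsic, anticodon = anticodon,
    anticodon_matches = if (is.null(expected_anticodon)) NA
                        else identical(anticodon, toupper(expected_anticodon)),
    cca_trimmed = cca
  )
  class(res) <- "cloverleaf_report"
  res
}

# best perfect hairpin (stem_len >= min_stem, loop 3-10 nt) inside
# x[from..to]; returns arm descriptor
.find_hairpin <- function(x, from, to, min_stem) {
  best <- list(present = FALSE, stem_length = 0L, paired_fraction = 0)
  if (is.na(from) || is.na(to) || to - from + 1L < 2L * min_stem + 3L) {
    return(best)
  }
  for (stem in seq.int(min_stem, min_stem + 2L)) {
    for (loop in 3:10) {
      span <- 2L * stem + loop
      if (span > to - from + 1L) next
      for (s in seq.int(from, to - span + 1L)) {
        f <- .stem_fraction(x, s, stem, s + stem + loop, stem)
        score_cur <- best$stem_length * best$paired_fraction
        if (f == 1 && stem * f > score_cur) {
          best <- list(present = TRUE, stem_length = stem, paired_fraction = f)
        } else if (!best$present && f > best$paired_fraction) {
          best$paired_fraction <- f
          best$stem_length <- stem
        }
      }
    }
  }
  best
}

#' Construct an idealized cloverleaf tRNA sequence
#'
#' Builds a perfectly paired cloverleaf (used by the simulator's folded-tRNA
#' mode and as a positive control for [fold_trna()]): 7 bp acceptor stem,
#' 4 bp DHU arm, 5 bp anticodon stem with the anticodon at the loop centre,
#' 5 bp T-arm, with standard single-nucleotide spacers.
#'
#' @param anticodon Triplet placed at the centre of the anticodon loop.
#' @param dhu Logical; omit the DHU stem-loop (as in mitochondrial
#'   tRNA-Ser(S1)) when `FALSE`.
#' @param extra Number of additional unpaired spacer nucleotides inserted
#'   between the anticodon and T arms (variable-region padding, used to hit
#'   an exact gene length).
#' @return Character scalar (57 + extra nt without the DHU arm, 65 + extra
#'   with it).
#' @export
cloverleaf_sequence <- function(anticodon = "GAA", dhu = TRUE, extra = 0L) {
  anticodon <- toupper(anticodon)
  stopifnot(nchar(anticodon) == 3L, extra >= 0L)
  rc <- function(s) revcomp(s)
  acc5 <- "GCGGATT"                      # acceptor 5'
  dhu_arm <- if (dhu) paste0("GCTC", "AGTTG", rc("GCTC")) else "TTAAA"
  ac_stem5 <- "CTGGC"
  ac_loop <- paste0("TT", anticodon, "AA")
  t_stem5 <- "GGTTC"
  t_loop <- "GAATCCC"
  paste0(
    acc5, "TA",
    dhu_arm, "A",
    ac_stem5, ac_loop, rc(ac_stem5), "G", strrep("A", extra),
    t_stem5, t_loop, rc(t_stem5),
    rc(acc5)
  )
}
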