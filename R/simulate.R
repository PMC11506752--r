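# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification for a synthetic mitogenome
#'
#' Bundles the dials of the generator. Defaults reproduce the study
#' conditions of a carangid mitogenome: the packaged 38-feature annotation
#' layout on a 16,541 bp circle, 53.13% A+T, AT-skew 0.034 and GC-skew
#' -0.288 (the whole-genome composition of the African moonfish).
#'
#' @param layout A [mitogenome()] (table-only is fine) providing the gene
#'   layout template; default [selene_table1()].
#' @param target_at Target A+T fraction (0-1).
#' @param at_skew,gc_skew Target strand skews in `[-1, 1]`.
#' @param codon_bias Optional named numeric vector of per-codon sampling
#'   weights for protein-coding genes (sense codons; unlisted codons get
#'   weight 0). When supplied, PCG interiors are drawn codon-wise from this
#'   distribution instead of the background base distribution.
#' @param seed Integer seed; the same spec and seed always produce the
#'   identical genome.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(layout = selene_table1(), target_at = 0.5313,
                            at_skew = 0.034, gc_skew = -0.288,
                            codon_bias = NULL, seed = 1L) {
  stopifnot(target_at > 0, target_at < 1,
            abs(at_skew) <= 1, abs(gc_skew) <= 1)
  if (!is.null(codon_bias)) {
    if (is.null(names(codon_bias)) || any(codon_bias < 0) ||
        sum(codon_bias) <= 0) {
      stop("codon_bias must be a named nonnegative weight vector")
    }
    names(codon_bias) <- toupper(names(codon_bias))
  }
  structure(
    list(layout = layout, target_at = target_at, at_skew = at_skew,
         gc_skew = gc_skew, codon_bias = codon_bias, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# base sampling distribution implied by (AT fraction, skews)
.base_probs <- function(target_at, at_skew, gc_skew) {
  gc <- 1 - target_at
  c(A = target_at * (1 + at_skew) / 2,
    C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2,
    T = target_at * (1 - at_skew) / 2)
}

#' Generate a synthetic annotated mitogenome
#'
#' Samples a circular genome over the template layout: background bases are
#' drawn i.i.d. from the distribution implied by the composition targets;
#' each protein-coding gene then gets (on its coding strand, where no
#' earlier gene has claimed the positions) a legal start codon (`ATG`, or
#' `GTG` for COI), the terminal codon its size modulo 3 dictates (`TAA`,
#' `TA` or `T`), and internal in-frame stop codons removed by resampling
#' third positions. In overlap zones the earlier template gene wins and the
#' conflict is logged. The control region optionally receives the four CSB
#' motifs planted in canonical order, and tRNA genes can be filled with
#' idealized cloverleaf sequences.
#'
#' @param spec A [simulation_spec()].
#' @param plant_csb Plant instantiated [csb_motifs()] in the control region.
#' @param fold_trnas Fill tRNA genes with [cloverleaf_sequence()] structures
#'   carrying the template anticodons (tRNA-Ser(S1) is built without a DHU
#'   arm). Default `FALSE`: tRNA regions stay background-sampled.
#' @param taxon,accession Metadata for the result.
#' @return A [mitogenome()] with sequence; attribute `conflicts` lists
#'   constraint writes skipped because of overlap locking.
#' @examples
#' g <- generate_mitogenome(simulation_spec(seed = 7))
#' genome_length(g)  # 16541
#' @export
generate_mitogenome <- function(spec, plant_csb = TRUE, fold_trnas = FALSE,
                                taxon = "synthetic moonfish",
                                accession = "SYN000001") {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- spec$layout$genes
  L <- spec$layout$genome_length
  probs <- .base_probs(spec$target_at, spec$at_skew, spec$gc_skew)
  bases <- names(probs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  code <- mito_genetic_code()
  .with_seed(spec$seed, {
    x <- sample(bases, L, replace = TRUE, prob = probs)
    locked <- logical(L)
    conflicts <- character(0)
    # constrained overwrites recorded as (old, new) genome-strand base
    # pairs, later compensated elsewhere so global composition stays on
    # target
    delta_old <- character(0)
    delta_new <- character(0)

    # coding-order genome positions of a record
    posn <- function(r) .gene_positions(as.list(r), L)
    # write coding-strand bases b at coding offsets k of record r,
    # honouring locks; returns TRUE if all written
    write_coding <- function(r, k, b) {
      p <- posn(r)[k]
      if (any(locked[p])) return(FALSE)
      newb <- if (r$strand == "-") unname(comp[b]) else b
      changed <- x[p] != newb
      delta_old <<- c(delta_old, x[p][changed])
      delta_new <<- c(delta_new, newb[changed])
      x[p] <<- newb
      TRUE
    }
    read_coding <- function(r) {
      p <- posn(r)
      s <- x[p]
      if (r$strand == "-") s <- unname(comp[s])
      paste(s, collapse = "")
    }
    sample_base <- function(allowed) {
      if (length(allowed) == 1L) return(allowed)
      sample(allowed, 1L, prob = probs[allowed] / sum(probs[allowed]))
    }

    stops <- code$stop_codons
    pcg_rows <- which(genes$kind == "PCG")
    for (i in pcg_rows) {
      r <- genes[i, ]
      size <- r$size
      start_codon <- if (r$gene == "COI") "GTG" else "ATG"
      if (!write_coding(r, 1:3, strsplit(start_codon, "")[[1]])) {
        conflicts <- c(conflicts, paste0(r$gene, ":start"))
      }
      m <- size %% 3L
      term <- switch(as.character(m),
                     `0` = c("T", "A", "A"), `2` = c("T", "A"), `1` = "T")
      if (!write_coding(r, (size - length(term) + 1L):size, term)) {
        conflicts <- c(conflicts, paste0(r$gene, ":stop"))
      }
      n_codon <- size %/% 3L
      n_full <- if (m == 0L) n_codon - 1L else n_codon  # exclude terminal TAA
      if (!is.null(spec$codon_bias) && n_full >= 2L) {
        bias <- spec$codon_bias[!names(spec$codon_bias) %in% stops]
        for (k in seq.int(2L, n_full)) {
          cdn <- sample(names(bias), 1L, prob = bias)
          if (!write_coding(r, (3L * k - 2L):(3L * k), strsplit(cdn, "")[[1]])) {
            conflicts <- c(conflicts, paste0(r$gene, ":codon", k))
          }
        }
      }
      # remove internal in-frame stops (codons 2..n_full) by resampling a
      # position that breaks the stop
      cds <- strsplit(read_coding(r), "")[[1]]
      for (k in if (n_full >= 2L) seq.int(2L, n_full) else integer(0)) {
        cdn <- paste(cds[(3L * k - 2L):(3L * k)], collapse = "")
        if (cdn %in% stops) {
          fixed <- FALSE
          for (p_in_codon in c(3L, 2L, 1L)) {
            pos_coding <- 3L * (k - 1L) + p_in_codon
            allowed <- bases[vapply(bases, function(b) {
              alt <- cdn
              substr(alt, p_in_codon, p_in_codon) <- b
              !(alt %in% stops)
            }, logical(1))]
            if (!length(allowed)) next
            b <- sample_base(allowed)
            if (write_coding(r, pos_coding, b)) {
              cds[pos_coding] <- b
              fixed <- TRUE
              break
            }
          }
          if (!fixed) conflicts <- c(conflicts, paste0(r$gene, ":stop@", k))
        }
      }
      locked[posn(r)] <- TRUE
    }

    if (fold_trnas) {
      trna_rows <- which(genes$kind == "tRNA")
      for (i in trna_rows) {
        r <- genes[i, ]
        anticodon <- if (is.na(r$anticodon)) "GAA" else r$anticodon
        dhu <- !grepl("Ser\\(S1\\)", r$gene)
        base_len <- if (dhu) 65L else 57L
        if (r$size < base_len) next  # too short for the idealized fold
        leaf <- cloverleaf_sequence(anticodon, dhu = dhu,
                                    extra = r$size - base_len)
        if (!write_coding(r, seq_len(r$size), strsplit(leaf, "")[[1]])) {
          conflicts <- c(conflicts, paste0(r$gene, ":cloverleaf"))
        } else {
          locked[posn(r)] <- TRUE
        }
      }
    }

    if (plant_csb) {
      cr_row <- which(genes$kind == "CR")
      if (length(cr_row) == 1L) {
        r <- genes[cr_row, ]
        motifs <- csb_motifs()
        # concrete instantiation of each IUPAC symbol, background-weighted
        inst <- vapply(motifs, function(m) {
          paste(vapply(strsplit(m, "")[[1]], function(sym) {
            sample_base(IUPAC_SETS[[sym]])
          }, character(1)), collapse = "")
        }, character(1))
        offs <- floor(r$size * c(0.22, 0.42, 0.62, 0.80))
        for (j in seq_along(inst)) {
          k <- offs[j]:(offs[j] + nchar(inst[j]) - 1L)
          if (max(k) > r$size ||
              !write_coding(r, k, strsplit(inst[j], "")[[1]])) {
            conflicts <- c(conflicts, paste0("CR:", names(motifs)[j]))
          } else {
            locked[posn(r)[k]] <- TRUE
          }
        }
      }
    }

    # composition repair: every constrained overwrite shifted the global
    # base counts by (-old, +new); undo each shift at a random unlocked
    # position so the realized composition tracks the sampling targets
    swap <- delta_old != delta_new
    for (j in which(swap)) {
      cand <- which(!locked & x == delta_new[j])
      if (!length(cand)) next
      x[cand[sample.int(length(cand), 1L)]] <- delta_old[j]
    }

    g <- mitogenome(genes[, c("gene", "kind", "start", "stop", "strand",
                              "anticodon")],
                    sequence = paste(x, collapse = ""),
                    taxon = taxon, accession = accession, circular = TRUE)
    attr(g, "conflicts") <- conflicts
    g
  })
}

#' Apply a fixed number of synonymous and nonsynonymous substitutions
#'
#' Introduces exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous
#' single-nucleotide substitutions, each in a distinct codon, never creating
#' a stop codon. Because changes land in distinct codons, a pathway counter
#' on the (original, mutant) pair recovers the counts exactly.
#'
#' @param cds In-frame, stop-free coding sequence.
#' @param n_syn,n_nonsyn Numbers of substitutions to apply.
#' @param code A [mito_genetic_code()].
#' @param seed Integer seed.
#' @return Mutated CDS string.
#' @export
mutate_cds <- function(cds, n_syn, n_nonsyn, code = mito_genetic_code(),
                       seed = 1L) {
  cds <- .check_seq(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  n_codon <- nchar(cds) %/% 3L
  idx <- 3L * seq_len(n_codon)
  codons <- substring(cds, idx - 2L, idx)
  if (any(code$codons[codons] == "*")) stop("CDS contains stop codon(s)")
  bases <- c("A", "C", "G", "T")
  options_for <- function(cdn, synonymous) {
    out <- list()
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cdn, p, p))) {
        alt <- cdn
        substr(alt, p, p) <- b
        if (code$codons[[alt]] == "*") next
        is_syn <- code$codons[[alt]] == code$codons[[cdn]]
        if (is_syn == synonymous) out[[length(out) + 1L]] <- c(p, b)
      }
    }
    out
  }
  .with_seed(seed, {
    can_syn <- which(vapply(codons, function(c) length(options_for(c, TRUE)) > 0,
                            logical(1)))
    can_non <- which(vapply(codons, function(c) length(options_for(c, FALSE)) > 0,
                            logical(1)))
    if (length(can_syn) < n_syn) stop("not enough codons with synonymous options")
    syn_at <- if (n_syn > 0) can_syn[sample.int(length(can_syn), n_syn)]
              else integer(0)
    can_non <- setdiff(can_non, syn_at)
    if (length(can_non) < n_nonsyn) {
      stop("not enough codons with nonsynonymous options")
    }
    non_at <- if (n_nonsyn > 0) can_non[sample.int(length(can_non), n_nonsyn)]
              else integer(0)
    for (k in syn_at) {
      opt <- options_for(codons[k], TRUE)
      ch <- opt[[sample.int(length(opt), 1L)]]
      substr(codons[k], as.integer(ch[1]), as.integer(ch[1])) <- ch[2]
    }
    for (k in non_at) {
      opt <- options_for(codons[k], FALSE)
      ch <- opt[[sample.int(length(opt), 1L)]]
      substr(codons[k], as.integer(ch[1]), as.integer(ch[1])) <- ch[2]
    }
    paste(codons, collapse = "")
  })
}

#' Simulate a divergent alignment
#'
#' Star-tree evolution of a random uniform root: every taxon independently
#' substitutes each site with a probability calibrated so the expected
#' pairwise p-distance equals `mean_divergence` (a single-hit model with a
#' closed-form collision correction, not a full Markov chain). Substitution
#' targets are transition-biased: a transition with probability
#' `ti_tv / (ti_tv + 2)`, otherwise either transversion equally.
#'
#' @param n_taxa Number of sequences.
#' @param length Alignment length in bp.
#' @param mean_divergence Expected pairwise p-distance, in `[0, 0.6)`.
#' @param ti_tv Transition/transversion target ratio parameter (kappa-like
#'   weight; large values give transition-only evolution).
#' @param seed Integer seed.
#' @return Named character vector (`t1`, `t2`, ...) of equal length.
#' @export
simulate_alignment <- function(n_taxa, length, mean_divergence, ti_tv = 2,
                               seed = 1L) {
  stopifnot(n_taxa >= 2L, length >= 1L, mean_divergence >= 0,
            mean_divergence < 0.75, ti_tv > 0)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  w_ts <- ti_tv / (ti_tv + 2)
  # two independent hits at one site coincide with probability `match`
  match <- w_ts^2 + 2 * ((1 - w_ts) / 2)^2
  disc <- 1 - (1 + match) * mean_divergence
  if (disc < 0) {
    stop("mean_divergence ", mean_divergence,
         " not reachable under the single-hit model (max ",
         round(1 / (1 + match), 3), ")")
  }
  m <- (1 - sqrt(disc)) / (1 + match)
  .with_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    out <- vapply(seq_len(n_taxa), function(i) {
      tip <- root
      hit <- stats::runif(length) < m
      if (any(hit)) {
        ts <- stats::runif(sum(hit)) < w_ts
        origin <- tip[hit]
        repl <- character(sum(hit))
        repl[ts] <- transition[origin[ts]]
        if (any(!ts)) {
          repl[!ts] <- vapply(origin[!ts], function(b) {
            sample(transversions[[b]], 1L)
          }, character(1))
        }
        tip[hit] <- repl
      }
      paste(tip, collapse = "")
    }, character(1))
    stats::setNames(out, paste0("t", seq_len(n_taxa)))
  })
}
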