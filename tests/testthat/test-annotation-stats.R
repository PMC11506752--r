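test_that("base composition and skews follow their definitions", {
  bc <- base_composition("AATC")
  expect_equal(unname(bc$percent[c("A", "T", "C", "G")]), c(50, 25, 25, 0))
  expect_equal(unname(base_composition("ACGT")$percent[1:4]), rep(25, 4))
  sk <- at_gc_skew("AATC")
  expect_equal(sk[["at_skew"]], 1 / 3)
  expect_equal(sk[["gc_skew"]], -1)
  expect_equal(unname(at_gc_skew("AATTGGCC")), c(0, 0))
  expect_true(is.na(at_gc_skew("GGCC")[["at_skew"]]))
})

test_that("skew is bounded and antisymmetric under reverse complement", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = runif(4) + 0.1), collapse = "")
    sk <- at_gc_skew(s)
    expect_true(all(abs(sk) <= 1))
    expect_equal(unname(at_gc_skew(revcomp(s))), unname(-sk))
  }
})

test_that("partition lengths and genome fractions match the published layout", {
  pp <- partition_profile(table1())
  expect_identical(pp$length_bp,
                   c(16541L, 11427L, 1576L, 2670L, 847L))
  expect_equal(pp$pct_of_genome[pp$partition == "PCGs"], 100 * 11427 / 16541,
               tolerance = 1e-12)
  expect_equal(pp$pct_of_genome[pp$partition == "CR"], 5.12, tolerance = 0.005)
  expect_true(all(is.na(pp$pct_A)))  # table-only: no composition
})

test_that("partition composition concatenates coding-strand gene sequences", {
  g <- generate_mitogenome(simulation_spec(seed = 3))
  pp <- partition_profile(g)
  # complete partition is just the whole-sequence profile
  whole <- base_composition(g$sequence)
  expect_equal(pp$pct_A[pp$partition == "complete"], whole$percent[["A"]])
  # manual concatenation oracle for the rRNA partition
  rr <- paste(vapply(g$genes$gene[g$genes$kind == "rRNA"], function(nm)
    extract_gene_sequence(g, nm), character(1)), collapse = "")
  expect_equal(pp$pct_G[pp$partition == "rRNAs"],
               base_composition(rr)$percent[["G"]])
  # reference-strand switch changes light-strand-containing partitions
  pp_ref <- partition_profile(g, reference_strand = TRUE)
  expect_false(isTRUE(all.equal(pp_ref$pct_A[pp_ref$partition == "tRNAs"],
                                pp$pct_A[pp$partition == "tRNAs"])))
})

test_that("intergenic layout reproduces the printed IN column", {
  lay <- intergenic_layout(table1())
  in_of <- function(g) lay$layout$in_bp[lay$layout$gene == g]
  expect_identical(in_of("ND1"), 4L)
  expect_identical(in_of("ATP8"), -10L)
  expect_identical(in_of("tRNA-Asn"), 37L)
  expect_identical(in_of("tRNA-Phe"), -1L)
  expect_identical(in_of("tRNA-Thr"), -2L)
  # full column as printed (closing CR->tRNA-Phe gap is 0)
  printed <- c(-1L, -1L, 0L, -1L, 0L, 4L, -2L, -2L, 0L, -1L, 0L, 0L, 37L,
               -1L, 1L, -1L, 2L, 7L, -1L, 1L, -10L, 0L, -1L, 0L, -1L, 1L,
               -7L, -1L, -1L, 5L, 0L, -4L, -1L, 3L, -1L, -2L, 0L, 0L)
  expect_identical(lay$layout$in_bp, printed)
  s <- lay$summary
  expect_identical(s$overlap_count, 19L)
  expect_identical(s$overlap_total_bp, 40L)
  expect_identical(s$longest_overlap_bp, 10L)
  expect_setequal(s$longest_overlap_pair, c("ATP8", "ATP6"))
  expect_identical(s$longest_spacer_bp, 37L)
  expect_identical(s$longest_spacer_gene, "tRNA-Asn")
})

test_that("IN sums tile the circle up to gaps and overlaps", {
  g <- table1()
  lay <- intergenic_layout(g)
  expect_identical(sum(lay$layout$in_bp),
                   genome_length(g) - sum(g$genes$size))
  sim <- generate_mitogenome(simulation_spec(seed = 8))
  lay2 <- intergenic_layout(sim)
  expect_identical(lay2$layout$in_bp, lay$layout$in_bp)
})

test_that("adjacent and zero-gap toy layouts get the right IN", {
  g <- mitogenome(data.frame(gene = c("a", "b"), kind = "tRNA",
                             start = c(1, 6), stop = c(5, 10), strand = "+"),
                  genome_length = 12)
  lay <- intergenic_layout(g)
  expect_identical(lay$layout$in_bp[1], 0L)   # b starts right after a
  expect_identical(lay$layout$in_bp[2], 2L)   # circle closes with 2 spare nt
})

test_that("stop-codon classification recovers incomplete terminators", {
  mk <- function(cds) mitogenome(
    data.frame(gene = "g", kind = "PCG", start = 1, stop = nchar(cds),
               strand = "+"), sequence = cds)
  ce <- codon_endpoints(mk("ATGAAATAA"))
  expect_identical(ce$start_codon, "ATG")
  expect_identical(ce$stop_codon, "TAA")
  expect_true(ce$stop_complete && !ce$anomalous)
  ce2 <- codon_endpoints(mk("ATGAAAAAT"))   # mod3 = 0, 'AAT' is no stop
  expect_true(ce2$anomalous)
  ce3 <- codon_endpoints(mk("ATGAAATA"))    # mod3 = 2, trailing TA
  expect_identical(ce3$stop_codon, "TA-")
  ce4 <- codon_endpoints(mk("ATGAAAT"))     # mod3 = 1, trailing T
  expect_identical(ce4$stop_codon, "T--")
  ce5 <- codon_endpoints(mk("ATGAAAGA"))    # mod3 = 2 but tail GA
  expect_true(ce5$anomalous)
})

test_that("size-mod-3 alone identifies the polyadenylation-completed genes", {
  expect_identical(
    incomplete_stop_genes(table1()),
    sort(c("ND2", "ND3", "ND4", "COII", "COIII", "ATP6", "CYTB")))
})
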