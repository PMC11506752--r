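test_that("NG86 site decomposition matches exhaustive enumeration", {
  # GGT (Gly): only the third position is synonymous, fully so
  expect_equal(unname(ng86_sites("GGT")), c(1, 2))
  # ATG (Met): third position 1/3 synonymous (ATA = Met under code 2);
  # the AGG change at position 2 creates a stop and leaves the denominator
  expect_equal(unname(ng86_sites("ATG")), c(1 / 3, 8 / 3))
  expect_error(ng86_sites("TAA"), "stop")
  set.seed(5)
  code <- mito_genetic_code()
  sense <- names(code$codons)[code$codons != "*"]
  for (codon in sample(sense, 12)) {
    s <- ng86_sites(codon)
    expect_lte(s[["s"]] + s[["n"]], 3 + 1e-12)
    expect_gte(min(s), 0)
  }
})

test_that("identical and constructed pairs give the expected Ka/Ks signs", {
  cds <- random_cds(60, 10)
  same <- ng86_pair(cds, cds)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ka_ks))  # Ks = 0 -> undefined ratio, not 0 or Inf
  syn_only <- mutate_cds(cds, n_syn = 5, n_nonsyn = 0, seed = 2)
  res <- ng86_pair(cds, syn_only)
  expect_equal(res$Ka, 0)
  expect_gt(res$Ks, 0)
  non_only <- mutate_cds(cds, n_syn = 0, n_nonsyn = 5, seed = 2)
  res2 <- ng86_pair(cds, non_only)
  expect_equal(res2$Ks, 0)
  expect_gt(res2$Ka, 0)
  expect_error(ng86_pair("ATGAAA", "ATGAA"), "length")
})

test_that("pathway counting agrees with the brute-force oracle", {
  for (seed in 1:40) {
    a <- random_cds(30, seed)
    b <- mutate_cds(a, n_syn = seed %% 4, n_nonsyn = seed %% 3,
                    seed = seed + 100)
    # extra multi-hit codons: splice codons of another random CDS
    if (seed %% 2 == 0) {
      c2 <- random_cds(30, seed + 500)
      keep <- seq(1, 90, by = 9)
      for (k in keep) substr(b, k, k + 2) <- substr(c2, k, k + 2)
    }
    got <- ng86_pair(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$N, want$N, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    # symmetry and difference bookkeeping
    rev <- ng86_pair(b, a)
    expect_equal(rev$Sd, got$Sd, tolerance = 1e-10)
    expect_equal(rev$Ka, got$Ka, tolerance = 1e-10)
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(got$Sd + got$Nd, ndiff, tolerance = 1e-10)
  }
})

test_that("nucleotide diversity equals mean pairwise p-distance", {
  expect_equal(nucleotide_diversity(c("AAAAAAAAAA", "AAAAAAAATT")), 0.2)
  expect_equal(nucleotide_diversity(c(a = "ACGT", b = "ACGT", c = "ACGT")), 0)
  aln4 <- c("ACGTACGTAC", "ACGTACGTAA", "ACGAACGTAC", "TCGTACGTAC")
  expect_equal(nucleotide_diversity(aln4), oracle_mean_pdist(aln4))
  # complete deletion drops the gapped column for every pair
  gapped <- c("A-GT", "AAGT", "ACGT")
  expect_equal(nucleotide_diversity(gapped), oracle_mean_pdist(gapped))
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
  for (seed in 1:5) {
    aln <- simulate_alignment(4, 300, 0.15, seed = seed)
    expect_equal(nucleotide_diversity(aln), oracle_mean_pdist(aln))
  }
})

test_that("sliding windows tile the alignment as specified", {
  aln <- simulate_alignment(3, 250, 0.1, seed = 4)
  sw <- sliding_window_pi(aln)
  expect_identical(sw$windows$start, c(1L, 26L, 51L))
  expect_identical(sw$windows$end, c(200L, 225L, 250L))
  one <- sliding_window_pi(aln, window = 250)
  expect_equal(one$windows$pi, one$pi)
  short <- sliding_window_pi(aln, window = 400)
  expect_true(short$truncated)
  expect_identical(nrow(short$windows), 1L)
  # diversity confined to one block is found by the window maximum
  base <- strrep("A", 300)
  hot <- base
  substr(hot, 141, 160) <- strrep("T", 20)
  sw2 <- sliding_window_pi(c(base, hot), window = 50, step = 10)
  best <- sw2$windows[which.max(sw2$windows$pi), ]
  expect_true(best$start <= 160 && best$end >= 141)
})

test_that("K2P distances match the closed form and the ape reference", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  rec <- k2p_saturation(aln)
  expect_equal(unname(unlist(rec[, c("p", "q", "k2p")])), c(0, 0, 0))
  # p = 0.1, q = 0.05 evaluates to 0.17018 at 5 dp
  expect_equal(-0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               0.17018, tolerance = 1e-4)
  sim <- simulate_alignment(4, 500, 0.2, seed = 6)
  rec2 <- k2p_saturation(sim)
  ref <- ape::dist.dna(ape::as.DNAbin(strsplit(sim, "")), model = "K80")
  expect_equal(rec2$k2p, as.numeric(ref), tolerance = 1e-10)
  expect_true(all(rec2$p + rec2$q <= 1))
})

test_that("mean K2P grows with simulated divergence", {
  means <- vapply(c(0.02, 0.1, 0.2, 0.35), function(d) {
    mean(k2p_saturation(simulate_alignment(4, 2000, d, seed = 9))$k2p)
  }, numeric(1))
  expect_false(is.unsorted(means))
})

test_that("transition-only evolution yields q = 0 and the reduced K2P form", {
  aln <- simulate_alignment(2, 5000, 0.1, ti_tv = 1e9, seed = 12)
  rec <- k2p_saturation(aln)
  expect_equal(rec$q, 0)
  expect_equal(rec$k2p, -0.5 * log(1 - 2 * rec$p), tolerance = 1e-12)
})
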