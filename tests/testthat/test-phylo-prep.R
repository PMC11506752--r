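test_that("supermatrix concatenation tracks charsets and gap fill", {
  alns <- list(
    ND1 = c(a = "ATGATG", b = "ATGTTG", c = "ATGCTG"),
    ND2 = c(a = "ATGAAATTT", b = "ATGAAATTC", c = "ATGAAATTA")
  )
  sm <- build_supermatrix(alns)
  expect_identical(sm$length, 15L)
  expect_identical(sm$charsets$start, c(1L, 7L))
  expect_identical(sm$charsets$end, c(6L, 15L))
  expect_equal(unname(sm$missing_fraction), c(0, 0, 0))
  # dropping a taxon from one gene gap-fills its charset
  alns$ND2 <- alns$ND2[c("a", "b")]
  sm2 <- build_supermatrix(alns)
  expect_identical(substr(sm2$matrix[["c"]], 7, 15), strrep("-", 9))
  expect_equal(sm2$missing_fraction[["c"]], 9 / 15)
  expect_error(build_supermatrix(list(ND1 = c(a = "AAA", a = "AAT"))),
               "duplicate")
  expect_warning(build_supermatrix(c(alns, list(ND3 = character(0)))),
                 "empty")
})

test_that("genes concatenate in canonical mitochondrial order", {
  g <- generate_mitogenome(simulation_spec(seed = 19))
  alns <- lapply(setNames(pcg_order(), pcg_order()), function(nm)
    setNames(extract_gene_sequence(g, nm), "sim"))
  sm <- build_supermatrix(rev(alns))  # input order must not matter
  expect_identical(sm$charsets$gene, pcg_order())
  expect_identical(sm$length, 11427L)
  expect_identical(sm$charsets$end[1], 975L)  # ND1 first
  # charsets tile 1..length without overlap
  expect_identical(sm$charsets$start[-1], sm$charsets$end[-13] + 1L)
})

test_that("supermatrix exports are valid and byte-stable", {
  alns <- list(ND1 = c(`taxon A` = "ATGATG", b = "ATGTTG"),
               COI = c(`taxon A` = "ATGAAATTT", b = "ATGAAATTC"))
  sm <- build_supermatrix(alns)
  b1 <- file.path(tempdir(), "sm1")
  b2 <- file.path(tempdir(), "sm2")
  ex <- export_supermatrix(sm, b1)
  export_supermatrix(sm, b2)
  for (s in c(".phy", ".nex", ".partitions.txt")) {
    expect_identical(readBin(paste0(b1, s), "raw", 1e5),
                     readBin(paste0(b2, s), "raw", 1e5))
  }
  nex <- readLines(paste0(b1, ".nex"))
  expect_true(any(grepl("NTAX=2 NCHAR=15", nex)))
  expect_identical(sum(grepl("CHARSET", nex)), 2L)
  parts <- readLines(paste0(b1, ".partitions.txt"))
  expect_identical(length(parts), 2L)
  expect_identical(parts[1], "DNA, ND1 = 1-6")
  # whitespace in taxon names is sanitized with a mapping
  expect_identical(ex$name_map$sanitized[ex$name_map$original == "taxon A"],
                   "taxon_A")
  rt <- read_phylip(paste0(b1, ".phy"))
  expect_identical(unname(rt), unname(sm$matrix))
})

test_that("neighbor joining recovers an additive 4-taxon topology", {
  # distances generated on ((a,b),(c,d)) with internal branch 3
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- ape::read.tree(text = nj_tree(d))
  # the split {a,b} | {c,d} must be present
  ab <- ape::getMRCA(ape::unroot(tr), c("a", "b"))
  part <- ape::prop.part(ape::unroot(tr))
  splits <- lapply(part, function(p) sort(attr(part, "labels")[p]))
  expect_true(list(c("a", "b")) %in% splits || list(c("c", "d")) %in% splits)
  # 3 taxa give the unique unrooted topology
  d3 <- d[1:3, 1:3]
  tr3 <- ape::read.tree(text = nj_tree(d3))
  expect_identical(sort(tr3$tip.label), c("a", "b", "c"))
  # degenerate all-equal distances do not crash and clamp to >= 0 lengths
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  treq <- ape::read.tree(text = nj_tree(deq))
  expect_true(all(treq$edge.length >= 0))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ on K2P distances separates two simulated clades", {
  base <- simulate_alignment(4, 1500, 0.02, seed = 101)
  names(base) <- c("x1", "x2", "y1", "y2")
  # separate the clades: shared transitions at every 5th site of the y pair
  base[c("y1", "y2")] <- vapply(base[c("y1", "y2")], function(s) {
    v <- strsplit(s, "")[[1]]
    i <- seq(1, length(v), by = 5)
    v[i] <- chartr("ACGT", "GTAC", v[i])
    paste(v, collapse = "")
  }, character(1))
  aln <- base
  tr <- ape::read.tree(text = nj_tree(k2p_matrix(aln)))
  part <- ape::prop.part(ape::unroot(tr))
  splits <- lapply(part, function(p) sort(attr(part, "labels")[p]))
  expect_true(list(c("x1", "x2")) %in% splits || list(c("y1", "y2")) %in% splits)
})
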