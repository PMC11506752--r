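test_that("the packaged annotation table reproduces every printed size", {
  g <- table1()
  expect_identical(nrow(g$genes), 38L)
  expect_identical(genome_length(g), 16541L)
  sizes <- setNames(g$genes$size, g$genes$gene)
  expect_identical(sizes[["ND1"]], 975L)
  expect_identical(sizes[["ND5"]], 1839L)
  expect_identical(sizes[["ATP8"]], 168L)
  expect_identical(sizes[["CR"]], 847L)
  expect_identical(sizes[["tRNA-Lys"]], 76L)
  # partition totals follow from the sizes
  expect_identical(sum(sizes[g$genes$kind == "PCG"]), 11427L)
  expect_identical(sum(sizes[g$genes$kind == "tRNA"]), 1576L)
  expect_identical(sum(sizes[g$genes$kind == "rRNA"]), 2670L)
  expect_identical(sum(g$genes$kind == "PCG"), 13L)
  expect_identical(sum(g$genes$kind == "tRNA"), 22L)
})

test_that("gene-table TSV parsing enforces the dialect", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tkind\tstart\tstop\tstrand",
               "ND1\tPCG\t1\t9\t+", "tRNA-Ile\ttRNA\t12\t20\t-"), f)
  g <- read_gene_table(f)
  expect_identical(nrow(g$genes), 2L)
  expect_identical(genome_length(g), 20L)
  writeLines(c("gene\tkind\tstart\tstop\tstrand\tcolour",
               "ND1\tPCG\t1\t9\t+\tred"), f)
  expect_warning(read_gene_table(f), "unknown column")
  writeLines(c("gene\tkind\tstart\tstop\tstrand", "ND1\tPCG\t1\tnine\t+"), f)
  expect_error(read_gene_table(f), "non-integer")
  writeLines(c("gene\tkind\tstart\tstop\tstrand", "ND1\tPCG\t1\t90\t+"), f)
  expect_error(read_gene_table(f, genome_length = 50), "outside")
})

test_that("gene tables round-trip through TSV", {
  g <- table1()
  f <- tempfile(fileext = ".tsv")
  write_gene_table(g, f)
  g2 <- read_gene_table(f)
  expect_identical(g2$genes[, c("gene", "kind", "start", "stop", "strand",
                                "anticodon", "size")],
                   g$genes[, c("gene", "kind", "start", "stop", "strand",
                               "anticodon", "size")])
})

test_that("the packaged toy GenBank parses and round-trips", {
  f <- system.file("extdata", "toy_mitogenome_synthetic.gb",
                   package = "mitoprofile")
  g <- read_genbank(f)
  expect_identical(nrow(g$genes), 9L)
  expect_identical(genome_length(g), 1500L)
  expect_true(g$circular)
  # a light-strand and an origin-wrapping feature survive parsing
  expect_identical(g$genes$strand[g$genes$gene == "tRNA-Gln"], "-")
  wrap <- g$genes[g$genes$gene == "tRNA-Thr", ]
  expect_lt(wrap$stop, wrap$start)
  expect_identical(wrap$size, 1500L - wrap$start + 1L + wrap$stop)
  # GenBank -> model -> TSV -> model preserves every record field
  tsv <- tempfile(fileext = ".tsv")
  write_gene_table(g, tsv)
  # wrap-around coordinates make the genome length non-inferable from the
  # table alone, so it is declared explicitly
  g2 <- read_gene_table(tsv, genome_length = 1500)
  expect_identical(g2$genes, g$genes)
  # model -> GenBank -> model preserves sequence and table
  gb2 <- tempfile(fileext = ".gb")
  write_genbank(g, gb2)
  g3 <- read_genbank(gb2)
  expect_identical(g3$sequence, g$sequence)
  expect_identical(g3$genes, g$genes)
})

test_that("malformed GenBank records are rejected", {
  f <- system.file("extdata", "toy_mitogenome_synthetic.gb",
                   package = "mitoprofile")
  lines <- readLines(f)
  bad <- tempfile(fileext = ".gb")
  writeLines(lines[!startsWith(lines, "ORIGIN") &
                     !grepl("^\\s+\\d", lines)], bad)
  expect_error(read_genbank(bad), "ORIGIN")
  lines2 <- sub("^(     CDS             )301\\.\\.600$", "\\1600..301", lines)
  lines2 <- sub("circular", "linear  ", lines2)
  writeLines(lines2, bad)
  expect_error(read_genbank(bad), "reversed|join")
})

test_that("gene-name normalization maps GenBank spellings to canon", {
  expect_identical(
    normalize_gene_name(c("COX1", "cob", "NAD4L", "rrnS",
                          "12S ribosomal RNA", "tRNA-Phe", "trnF")),
    c("COI", "CYTB", "ND4L", "12S-rRNA", "12S-rRNA", "tRNA-Phe", "tRNA-Phe"))
  expect_identical(normalize_gene_name("tRNA-Ser (S1)"), "tRNA-Ser(S1)")
  expect_warning(out <- normalize_gene_name("mystery7"), "unrecognized")
  expect_identical(out, "mystery7")
})

test_that("FASTA io round-trips and the alignment reader rejects ragged input", {
  seqs <- c(a = "ATGCATGCAT", b = "TTGCATGCAA")
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  expect_identical(read_alignment(f), seqs)
  write_fasta(c(a = "ATGCATGCAT", b = "TTGCATGCA"), f)
  expect_error(read_alignment(f), "ragged")
})
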