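test_that("genetic code table 2 carries the vertebrate mitochondrial reassignments", {
  code <- genetic_code(2L)
  expect_length(code$codon_to_aa, 64L)
  expect_identical(code$codon_to_aa[["AGA"]], "*")
  expect_identical(code$codon_to_aa[["AGG"]], "*")
  expect_identical(code$codon_to_aa[["ATA"]], "M")
  expect_identical(code$codon_to_aa[["TGA"]], "W")
})

test_that("coding-sense extraction handles strands and the origin wrap", {
  g <- mito_genome("t", "AAACCC",
                   gene_features(c("a", "b"), "PCG", c(1L, 4L), c(3L, 6L),
                                 c("H", "L")))
  expect_identical(extract_gene_sequence(g, "a"), "AAA")
  expect_identical(extract_gene_sequence(g, "b"), "GGG")

  gw <- mito_genome("w", "TTAAGG",
                    gene_features("wrap", "PCG", 5L, 2L, "H"),
                    circular = TRUE)
  expect_identical(extract_gene_sequence(gw, "wrap"), "GGTT")
  expect_identical(feature_lengths(5L, 2L, 6L), 4L)

  expect_error(
    mito_genome("lin", "TTAAGG", gene_features("x", "PCG", 5L, 2L, "H"),
                circular = FALSE),
    "origin-spanning")
})

test_that("reverse complement is an involution and skew-compatible", {
  for (seed in 1:5) {
    s <- random_seq(80L, seed)
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_identical(revcomp("ACGTN"), "NACGT")
})

test_that("strand dialects normalize onto H/L", {
  expect_identical(normalize_strand(c("+", "1", "H", "plus")),
                   rep("H", 4L))
  expect_identical(normalize_strand(c("-", "−", "-1", "L", "minus")),
                   rep("L", 5L))
  expect_error(normalize_strand("?"), "unrecognized")
})

test_that("GenBank write-then-read is the identity on synthetic genomes", {
  g <- fx_ch()$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
  expect_true(g2$circular)
  expect_identical(g2$id, g$id)
  # the 37-gene complement plus control region
  expect_identical(sum(g2$features$type == "PCG"), 13L)
  expect_identical(sum(g2$features$type == "tRNA"), 22L)
  expect_identical(sum(g2$features$type == "rRNA"), 2L)
  expect_identical(sum(g2$features$type == "control_region"), 1L)
})

test_that("GenBank reader handles complement locations and origin-spanning joins", {
  g <- tiny_genome()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$features, g$features)
  b <- g2$features[g2$features$name == "geneB", ]
  expect_identical(b$strand, "L")
  cw <- g2$features[g2$features$name == "geneC", ]
  expect_true(cw$end < cw$start)
})

test_that("FASTA + feature-table round trip preserves genome and annotations", {
  g <- fx_ch()$genome
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_with_table(g, fa, tsv)
  g2 <- read_fasta_with_table(fa, tsv)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features[, c("name", "type", "start", "end", "strand")],
                   g$features[, c("name", "type", "start", "end", "strand")])
})

test_that("FASTA/table reader enforces its contracts", {
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">s1", "ACGTACGTAC"), fa)
  writeLines(c("name\ttype\tstart\tend\tstrand",
               "geneX\tPCG\t1\t6\t−"), tsv)
  g <- read_fasta_with_table(fa, tsv)
  expect_identical(g$features$strand, "L")

  writeLines(c("name\ttype\tstart\tend\tstrand"), tsv)
  expect_warning(g0 <- read_fasta_with_table(fa, tsv), "empty")
  expect_identical(nrow(g0$features), 0L)

  writeLines(c(">s1", "ACGT", ">s2", "ACGT"), fa)
  expect_error(read_fasta_with_table(fa, tsv), "ambiguity")
})

test_that("ambiguity codes other than N are rejected with position", {
  expect_error(mito_genome("x", "ACGRT"), "position 4")
  expect_silent(mito_genome("x", "ACGNT"))
})
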