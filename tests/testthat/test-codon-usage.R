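test_that("codon counting reads frame 1 and excludes trailing partials", {
  k <- count_codons("ATGAAATAA")
  expect_identical(unname(k[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_identical(sum(k), 3L)

  k2 <- count_codons("ATGAAAT")
  expect_identical(sum(k2), 2L)
  expect_identical(attr(k2, "trailing_nt"), 1L)

  k3 <- count_codons(c("ATGANA", "CCC"))
  expect_identical(attr(k3, "skipped"), 1L)
  expect_identical(sum(k3), 2L)
})

test_that("count_codons recovers a planted codon multiset exactly", {
  code <- genetic_code(2L)
  cods <- rep(c("ATG", "GGC", "TTA", "CGA", "CGA"), times = c(4, 3, 2, 5, 0))
  set.seed(42)
  genes <- vapply(split(cods, rep(1:2, length.out = length(cods))),
                  paste, character(1L), collapse = "")
  k <- count_codons(genes)
  expect_identical(unname(k[c("ATG", "GGC", "TTA", "CGA")]),
                   c(4L, 3L, 2L, 5L))
  expect_identical(sum(k), 14L)
})

test_that("RSCU follows the family formula with split Leu/Ser families", {
  code <- genetic_code(2L)
  counts <- setNames(integer(64L), all_codons())
  counts[c("GTA", "GTC", "GTG", "GTT")] <- 5L       # Val family, uniform
  counts["ATG"] <- 10L; counts["ATA"] <- 30L        # Met two-codon family
  counts["TCA"] <- 6L                               # one Ser2 codon used
  r <- compute_rscu(counts, code)
  expect_equal(r$rscu[r$codon %in% c("GTA", "GTC", "GTG", "GTT")],
               rep(1, 4L))
  expect_equal(r$rscu[r$codon == "ATA"], 1.5)       # 30/40 x 2
  expect_equal(r$rscu[r$codon == "ATG"], 0.5)
  # unused codon in a used family -> 0; Ser2 is a 4-fold family
  expect_equal(r$rscu[r$codon == "TCC"], 0)
  expect_identical(r$family_size[r$codon == "TCA"], 4L)
  expect_equal(r$rscu[r$codon == "TCA"], 4)
  # Ser1 (AGY) is a separate 2-fold family under table 2
  expect_identical(r$family_size[r$codon == "AGC"], 2L)
  expect_false(r$family[r$codon == "AGC"] == r$family[r$codon == "TCA"])
  # Leu splits into UUR (2) and CUN (4)
  expect_identical(r$family_size[r$codon == "TTA"], 2L)
  expect_identical(r$family_size[r$codon == "CTA"], 4L)
})

test_that("RSCU family sums equal family sizes and scale invariance holds", {
  g <- fx_ch()$genome
  pcgs <- vapply(which(g$features$type == "PCG"),
                 function(i) extract_gene_sequence(g, i), character(1L))
  counts <- count_codons(pcgs)
  r <- compute_rscu(counts)
  sums <- tapply(r$rscu, r$family, sum)
  sizes <- tapply(r$family_size, r$family, max)
  used <- tapply(r$count, r$family, sum) > 0L
  expect_true(all(abs(sums[used] - sizes[used]) < 1e-9))
  expect_true(all(sums[!used] == 0))
  expect_true(all(r$rscu >= 0))

  r10 <- compute_rscu(counts * 10L)
  expect_equal(r10$rscu, r$rscu)
})

test_that("stop codons enter RSCU only on request", {
  counts <- setNames(integer(64L), all_codons())
  counts[c("TAA", "AGA")] <- 3L
  r0 <- compute_rscu(counts, include_stops = FALSE)
  expect_false(any(r0$aa == "*"))
  r1 <- compute_rscu(counts, include_stops = TRUE)
  expect_true(any(r1$aa == "*"))
})

test_that("amino-acid usage merges Ser families and accounts every codon", {
  g <- fx_ch()$genome
  pcgs <- vapply(which(g$features$type == "PCG"),
                 function(i) extract_gene_sequence(g, i), character(1L))
  counts <- count_codons(pcgs)
  u <- amino_acid_usage(counts)
  expect_identical(sum(u$aa_usage$count), sum(counts))
  ser_total <- u$aa_usage$count[u$aa_usage$aa == "S"]
  ser_fams <- sum(u$family_usage$count[u$family_usage$aa == "S"])
  expect_identical(ser_total, ser_fams)
  expect_identical(sum(u$family_usage$aa == "S"), 2L)
  expect_false(u$top_codon$tie)
})

test_that("top-codon ties break lexicographically and are flagged", {
  counts <- setNames(integer(64L), all_codons())
  counts[c("GGA", "AAA")] <- 7L
  u <- amino_acid_usage(counts)
  expect_identical(u$top_codon$codon, "AAA")
  expect_true(u$top_codon$tie)

  zero <- amino_acid_usage(setNames(integer(64L), all_codons()))
  expect_true(is.na(zero$top_codon$codon))
  expect_identical(zero$top_codon$count, 0L)
})
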