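test_that("site counts match hand enumeration for table-2 landmark codons", {
  code <- genetic_code(2L)
  # GTT (Val, 4-fold): third position fully synonymous, others not
  expect_equal(ng86_sites("GTT", code), c(s = 1, n = 2))
  # ATG: only ATG->ATA is synonymous under table 2 (ATA = Met)
  expect_equal(ng86_sites("ATG", code), c(s = 1 / 3, n = 8 / 3))
  # TGG: only TGG->TGA is synonymous under table 2 (TGA = Trp)
  expect_equal(ng86_sites("TGG", code), c(s = 1 / 3, n = 8 / 3))
  expect_error(ng86_sites("TAA", code), "stop")
})

test_that("site counts satisfy s + n = 3 for all 60 sense codons", {
  code <- genetic_code(2L)
  for (cd in all_codons()) {
    if (is_stop_codon(cd, code)) next
    x <- ng86_sites(cd, code)
    expect_equal(unname(x[["s"]] + x[["n"]]), 3)
    expect_gte(x[["s"]], 0)
  }
})

test_that("difference classification agrees with direct translation on every single-step pair", {
  code <- genetic_code(2L)
  codons <- all_codons()
  sense <- codons[!is_stop_codon(codons, code)]
  checked <- 0L
  for (c1 in sense) {
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(c1, pos, pos))) {
        c2 <- c1
        substr(c2, pos, pos) <- b
        if (is_stop_codon(c2, code)) next
        d <- ng86_differences(c1, c2, code)
        same_aa <- translate_codons(c1, code) == translate_codons(c2, code)
        expect_equal(unname(d), if (same_aa) c(1, 0) else c(0, 1))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 400L)
})

test_that("pathway averaging handles multi-step pairs and stop exclusion", {
  code <- genetic_code(2L)
  expect_equal(ng86_differences("GTT", "GTA", code), c(sd = 1, nd = 0))
  expect_equal(ng86_differences("TTT", "TTA", code), c(sd = 0, nd = 1))
  expect_equal(ng86_differences("AAA", "AAA", code), c(sd = 0, nd = 0))
  # TTT -> GTA: via GTT (nonsyn then syn) or TTA (nonsyn, nonsyn)
  expect_equal(ng86_differences("TTT", "GTA", code), c(sd = 0.5, nd = 1.5))
  # sd + nd equals the Hamming distance for any sense pair
  set.seed(9)
  sense <- all_codons()[!is_stop_codon(all_codons(), code)]
  for (i in 1:40) {
    c1 <- sample(sense, 1L); c2 <- sample(sense, 1L)
    d <- ng86_differences(c1, c2, code)
    hd <- sum(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
    expect_equal(unname(d[["sd"]] + d[["nd"]]), hd)
  }
})

test_that("Jukes-Cantor correction has the right fixed points and domain", {
  expect_equal(jc_correct(0), 0)
  expect_true(is.na(jc_correct(0.75)))
  expect_gt(jc_correct(0.5), 0.5)
})

test_that("identical sequences give Ka = Ks = 0 with an undefined ratio", {
  s <- paste(rep("ATGGCACGTATC", 30L), collapse = "")
  aln <- codon_alignment("x", s, s)
  r <- ng86_kaks(aln)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_match(r$flag, "Ks = 0")
})

test_that("ng86_kaks is symmetric and conserves sites", {
  trio <- fx_evolved()
  s1 <- extract_gene_sequence(trio$A, "ND2")
  s2 <- extract_gene_sequence(trio$B, "ND2")
  a12 <- align_codon_pair("ND2", s1, s2)
  a21 <- align_codon_pair("ND2", s2, s1)
  r12 <- ng86_kaks(a12)
  r21 <- ng86_kaks(a21)
  expect_equal(r12$Ka, r21$Ka)
  expect_equal(r12$Ks, r21$Ks)
  expect_equal(r12$S, r21$S)
  expect_equal(r12$S + r12$N, 3 * r12$n_codons)
})

test_that("too few codons and gap columns are handled per contract", {
  expect_error(ng86_kaks(codon_alignment("x", "ATGGCA", "ATGGCA")),
               "too few")
  s <- paste(rep("ATGGCACGTATC", 10L), collapse = "")
  gappy <- paste0("---", substr(s, 4L, nchar(s)))
  r <- ng86_kaks(codon_alignment("x", s, gappy))
  expect_identical(r$n_codons, nchar(s) %/% 3L - 1L)
})

test_that("synonymous-only evolution yields Ka = 0 and Ks near the planted rate", {
  anc <- fx_ch()
  div <- default_divergence()
  div$nonsyn_rate <- 0
  ev <- evolve_pair(anc$genome, div, seed = 77L,
                    protect = anc$truth$protected_positions, id = "SYN_only")
  for (gene in c("ND1", "COX1", "ATP6")) {
    aln <- align_codon_pair(gene, extract_gene_sequence(anc$genome, gene),
                            extract_gene_sequence(ev$genome, gene))
    r <- ng86_kaks(aln)
    expect_equal(r$Ka, 0)
    expect_gt(r$Ks, 0)
    expect_lt(abs(r$Ks - jc_correct(0.10)), 0.03)
  }
})

test_that("planted pn/ps is recovered over a long gene", {
  anc <- fx_ch()
  div <- default_divergence()
  ev <- evolve_pair(anc$genome, div, seed = 88L,
                    protect = anc$truth$protected_positions, id = "EV")
  aln <- align_codon_pair("ND5", extract_gene_sequence(anc$genome, "ND5"),
                          extract_gene_sequence(ev$genome, "ND5"))
  r <- ng86_kaks(aln)
  planted <- jc_correct(0.0056) / jc_correct(0.10)
  expect_lt(abs(r$ratio - planted) / planted, 0.45)  # ~10 events: coarse
  expect_lt(r$ratio, 1)
})

test_that("equal synonymous and nonsynonymous pressure drives Ka/Ks toward 1", {
  anc <- fx_ch()
  div <- default_divergence()
  div$syn_rate <- 0.06
  div$nonsyn_rate <- 0.06
  ev <- evolve_pair(anc$genome, div, seed = 99L,
                    protect = anc$truth$protected_positions, id = "NEUT")
  ratios <- vapply(c("ND5", "COX1", "ND4"), function(gene) {
    aln <- align_codon_pair(gene, extract_gene_sequence(anc$genome, gene),
                            extract_gene_sequence(ev$genome, gene))
    ng86_kaks(aln)$ratio
  }, numeric(1L))
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("planted rate ranks are recovered across the gene table", {
  kk <- pairwise_kaks_table(fx_evolved())
  expect_identical(nrow(kk$results), 39L)           # 13 genes x 3 pairs
  expect_true(all(kk$results$ratio < 1, na.rm = TRUE))
  s <- kk$summary
  top <- s$gene[which.max(s$median_ratio)]
  expect_identical(top, "ATP8")
  bottom2 <- s$gene[order(s$median_ratio)][1:2]
  expect_setequal(bottom2, c("COX1", "COX2"))
})

test_that("a gene missing from one genome is skipped with a warning", {
  trio <- fx_evolved()
  g3 <- trio$C
  g3$features <- g3$features[g3$features$name != "ND3", ]
  expect_warning(
    kk <- pairwise_kaks_table(list(A = trio$A, B = trio$B, C = g3),
                              genes = c("ND3", "ND4L")),
    "ND3 missing")
  expect_identical(unique(kk$results$gene), "ND4L")
})
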