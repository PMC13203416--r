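test_that("junction classification covers overlap, abutting and spacer cases", {
  g <- mito_genome("j", strrep("ACGT", 20L),
                   gene_features(c("a", "b"), "PCG", c(1L, 8L), c(10L, 20L),
                                 "H"))
  b <- boundary_table(g)
  ab <- b[b$upstream_gene == "a", ]
  expect_identical(ab$kind, "overlap")
  expect_identical(ab$length, 3L)      # positions 8, 9, 10 shared

  g2 <- mito_genome("j2", strrep("ACGT", 5L),
                    gene_features(c("a", "b"), "PCG", c(1L, 11L),
                                  c(10L, 20L), "H"))
  b2 <- boundary_table(g2)
  expect_identical(b2$kind, c("abutting", "abutting"))  # incl. wrap pair

  g3 <- mito_genome("j3", strrep("ACGT", 20L),
                    gene_features(c("a", "b"), "PCG", c(1L, 15L),
                                  c(10L, 20L), "H"))
  b3 <- boundary_table(g3)
  expect_identical(b3$kind[1L], "spacer")
  expect_identical(b3$length[1L], 4L)
})

test_that("every feature has exactly one downstream neighbor on the circle", {
  g <- fx_ch()$genome
  b <- boundary_table(g)
  expect_identical(nrow(b), nrow(g$features))
  expect_identical(sort(b$upstream_gene), sort(g$features$name))
})

test_that("boundary bookkeeping closes the circle exactly", {
  g <- fx_ch()$genome
  b <- boundary_table(g)
  lens <- feature_lengths(g$features$start, g$features$end, g$length)
  gaps <- ifelse(b$kind == "spacer", b$length,
                 ifelse(b$kind == "overlap", -b$length, 0L))
  expect_identical(sum(lens) + sum(gaps), g$length)
})

test_that("the planted junction structure is recovered exactly", {
  b <- boundary_table(fx_ch()$genome)
  s <- boundary_summary(b)
  expect_identical(s$n_overlap, 9L)
  expect_identical(s$total_overlap_bp, 78L)
  expect_identical(s$max_overlap_bp, 43L)
  expect_identical(s$n_spacer, 14L)
  expect_identical(s$total_spacer_bp, 72L)
  atp <- b[b$upstream_gene == "ATP8" & b$downstream_gene == "ATP6", ]
  expect_identical(atp$kind, "overlap")
  expect_identical(atp$length, 43L)
  ol <- b[b$upstream_gene == "tRNA-Asn" & b$downstream_gene == "tRNA-Cys", ]
  expect_identical(ol$kind, "spacer")
  expect_identical(ol$length, 43L)
})

test_that("nested features are flagged out of the chain, not merged", {
  g <- mito_genome("n", strrep("ACGT", 25L),
                   gene_features(c("outer", "inner", "after"),
                                 c("PCG", "tRNA", "PCG"),
                                 c(1L, 10L, 40L), c(30L, 20L, 90L), "H"))
  b <- boundary_table(g)
  expect_identical(attr(b, "nested"), "inner")
  expect_false("inner" %in% b$upstream_gene)
  expect_identical(nrow(b), 2L)
})

test_that("strand distribution reproduces the canonical vertebrate split", {
  g <- fx_ch()$genome
  d <- strand_distribution(g)
  expect_identical(unname(d$overall[["L"]]), 9L)   # ND6 + 8 tRNAs
  by <- d$by_type
  expect_identical(by$L[by$type == "PCG"], 1L)
  expect_identical(by$L[by$type == "tRNA"], 8L)
  # 28 genes on H (excluding the control region)
  genes_h <- sum(by$H[by$type != "control_region"])
  expect_identical(genes_h, 28L)

  empty <- mito_genome("e", "ACGTACGT")
  expect_identical(unname(strand_distribution(empty)$overall),
                   c(0L, 0L))
})

test_that("codon audit classifies complete and incomplete stops", {
  g <- fx_ch()$genome
  aud <- codon_boundary_audit(g)
  expect_identical(nrow(aud), 13L)
  expect_true(all(aud$note == ""))
  expect_identical(aud$stop_class[aud$gene == "ND4"], "incomplete_T")
  expect_identical(aud$stop_codon[aud$gene == "ND4"], "T")
  expect_identical(aud$stop_class[aud$gene == "COX3"], "incomplete_TA")
  expect_identical(aud$stop_codon[aud$gene == "COX3"], "TA")
  expect_identical(aud$stop_codon[aud$gene == "CYTB"], "AGA")
  expect_identical(aud$stop_class[aud$gene == "CYTB"], "complete")
  expect_identical(sort(aud$gene[aud$start_codon == "ATA"]),
                   c("ND2", "ND3", "ND5"))
  expect_true(all(aud$start_codon[!aud$gene %in% c("ND2", "ND3", "ND5")] ==
                    "ATG"))
})

test_that("audit is strand-invariant: L-strand genes audit on coding sense", {
  g <- fx_ch()$genome
  aud <- codon_boundary_audit(g)
  nd6 <- aud[aud$gene == "ND6", ]
  expect_identical(nd6$start_codon, "ATG")
  expect_identical(nd6$stop_codon, "TAA")
  # mirror construction: revcomp the H slice by hand
  f <- g$features[g$features$name == "ND6", ]
  s <- revcomp(substr(g$sequence, f$start, f$end))
  expect_identical(substr(s, 1L, 3L), "ATG")
})

test_that("audit rejects PCGs shorter than 6 nt", {
  g <- mito_genome("s", strrep("ACGT", 10L),
                   gene_features("stub", "PCG", 1L, 5L, "H"))
  expect_error(codon_boundary_audit(g), "shorter than 6")
})

test_that("PCG summary arithmetic matches the printed precision", {
  # direct arithmetic on the three deposited genome sizes
  mk <- function(total, L) {
    list(fraction = round(100 * total / L, 2), codons = round(total / 3))
  }
  expect_identical(mk(11421L, 17218L)$fraction, 66.33)
  expect_identical(mk(11421L, 17202L)$fraction, 66.39)
  expect_identical(mk(11424L, 17211L)$fraction, 66.38)
  expect_identical(mk(11421L, 17218L)$codons, 3807)
  expect_identical(mk(11424L, 17211L)$codons, 3808)

  s <- summarize_pcgs(fx_ch()$genome)
  expect_identical(s$total_pcg_bp, 11421L)
  expect_identical(s$fraction_pct, 66.33)
  expect_identical(s$codon_total, 3807L)

  small <- mito_genome("sm", strrep("ACGTAC", 100L),
                       gene_features("one", "PCG", 1L, 300L, "H"))
  expect_warning(ss <- summarize_pcgs(small), "missing canonical")
  expect_identical(ss$fraction_pct, 50)
  expect_identical(ss$codon_total, 100L)
})
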