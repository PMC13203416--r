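test_that("layout arithmetic reproduces the three deposited genome sizes", {
  for (v in c("CH", "CL", "CS")) {
    lay <- mito_gene_layout(v)
    expect_identical(nrow(lay), 38L)                    # 37 genes + D-loop
    expect_identical(sum(lay$type == "PCG"), 13L)
    expect_identical(sum(lay$type == "tRNA"), 22L)
    expect_identical(sum(lay$type == "rRNA"), 2L)
    pcg_total <- sum(lay$length[lay$type == "PCG"])
    expect_identical(pcg_total, if (v == "CS") 11424L else 11421L)
    spec <- synthetic_spec(v, seed = 1L)
    expect_identical(spec$genome_length,
                     c(CH = 17218L, CL = 17202L, CS = 17211L)[[v]])
  }
  # inconsistent junction arithmetic is a spec error before generation
  lay <- mito_gene_layout("CH")
  lay$gap_after[38L] <- -20000L
  expect_error(synthetic_spec("CH", layout = lay), "inconsistent")
})

test_that("generation is deterministic: same spec + seed, identical bytes", {
  a <- generate_genome(synthetic_spec("CL", seed = 5L))
  b <- generate_genome(synthetic_spec("CL", seed = 5L))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$genome$features, b$genome$features)
  expect_identical(a$truth$repeats, b$truth$repeats)
  c <- generate_genome(synthetic_spec("CL", seed = 6L))
  expect_false(identical(a$genome$sequence, c$genome$sequence))
})

test_that("generated genomes carry clean translatable PCGs", {
  res <- fx_ch()
  g <- res$genome
  code <- genetic_code(2L)
  for (i in which(g$features$type == "PCG")) {
    s <- extract_gene_sequence(g, i)
    ncod <- nchar(s) %/% 3L
    cods <- substring(s, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    interior <- cods[2:(ncod - (nchar(s) %% 3L == 0L))]
    expect_false(any(is_stop_codon(interior, code)),
                 info = g$features$name[i])
  }
})

test_that("planted junctions and repeats round-trip through the analyzers", {
  res <- generate_genome(synthetic_spec("CS", seed = 55L))
  s <- boundary_summary(boundary_table(res$genome))
  expect_identical(s$n_overlap, 9L)
  expect_identical(s$total_overlap_bp, 78L)
  expect_identical(s$n_spacer, 14L)
  expect_identical(s$total_spacer_bp, 70L)
  tr <- res$truth$repeats
  for (r in seq_len(nrow(tr))) {
    m <- find_repeats(res$genome$sequence, min_len = tr$length[r],
                      max_mismatch = tr$mismatches[r], classes = tr$klass[r])
    expect_true(any(m$start1 == tr$start1[r] & m$start2 == tr$start2[r] &
                      m$length == tr$length[r] &
                      m$mismatches == tr$mismatches[r]),
                info = sprintf("row %d", r))
  }
})

test_that("plant_repeats on an existing genome honors an explicit plan", {
  base <- generate_genome(synthetic_spec("CH", seed = 60L,
                                         repeat_plan = NULL))
  expect_identical(nrow(base$truth$repeats), 0L)
  plan <- data.frame(klass = c("F", "P"), length = c(25L, 24L),
                     mismatches = c(0L, 1L), stringsAsFactors = FALSE)
  planted <- plant_repeats(base$genome, plan, seed = 61L)
  expect_identical(nrow(planted$truth), 2L)
  for (r in 1:2) {
    tr <- planted$truth[r, ]
    m <- find_repeats(planted$genome$sequence, tr$length, tr$mismatches,
                      classes = tr$klass)
    expect_true(any(m$start1 == tr$start1 & m$start2 == tr$start2 &
                      m$length == tr$length & m$mismatches == tr$mismatches))
  }
  empty <- plant_repeats(base$genome, plan[0, ], seed = 61L)
  expect_identical(empty$genome$sequence, base$genome$sequence)
})

test_that("evolution plants the requested counts and never breaks frames", {
  anc <- fx_ch()
  div <- default_divergence()
  ev <- evolve_pair(anc$genome, div, seed = 70L,
                    protect = anc$truth$protected_positions, id = "EV")
  expect_identical(nrow(ev$events), 13L)
  expect_identical(ev$events$syn_planted,
                   as.integer(round(0.10 * ev$events$S)))
  # no new internal stops anywhere
  code <- genetic_code(2L)
  for (i in which(ev$genome$features$type == "PCG")) {
    s <- extract_gene_sequence(ev$genome, i)
    ncod <- nchar(s) %/% 3L
    cods <- substring(s, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    interior <- cods[2:(ncod - (nchar(s) %% 3L == 0L))]
    expect_false(any(is_stop_codon(interior, code)))
  }
  # zero rates leave the PCGs untouched
  div0 <- default_divergence()
  div0$syn_rate <- 0; div0$nonsyn_rate <- 0
  ev0 <- evolve_pair(anc$genome, div0, seed = 71L, noncoding_rate = 0,
                     protect = anc$truth$protected_positions, id = "E0")
  expect_identical(ev0$genome$sequence, anc$genome$sequence)
  # an impossible request refuses
  div9 <- default_divergence()
  div9$nonsyn_rate <- 2
  expect_error(evolve_pair(anc$genome, div9, seed = 72L, id = "E9"),
               "rate too high")
})

test_that("evolution leaves planted repeat loci intact", {
  anc <- fx_ch()
  ev <- evolve_pair(anc$genome, default_divergence(), seed = 73L,
                    protect = anc$truth$protected_positions, id = "EVP")
  tr <- anc$truth$repeats
  for (r in seq_len(nrow(tr))) {
    m <- find_repeats(ev$genome$sequence, min_len = tr$length[r],
                      max_mismatch = tr$mismatches[r], classes = tr$klass[r])
    expect_true(any(m$start1 == tr$start1[r] & m$start2 == tr$start2[r] &
                      m$length == tr$length[r] &
                      m$mismatches == tr$mismatches[r]))
  }
})
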