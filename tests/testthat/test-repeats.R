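# helper: plant an exact copy (optionally transformed) of a segment of s at
# position p2, returning the modified sequence
plant_copy <- function(s, from, len, p2, transform = identity) {
  seg <- transform(substr(s, from, from + len - 1L))
  paste0(substr(s, 1L, p2 - 1L), seg, substr(s, p2 + len, nchar(s)))
}

test_that("planted exact copies are found in their class", {
  s <- random_seq(300L, 7L)
  sF <- plant_copy(s, 20L, 25L, 200L)
  m <- find_repeats(sF, min_len = 20L, max_mismatch = 0L, classes = "F")
  expect_gte(nrow(m), 1L)
  hit <- m[m$start1 <= 20L & m$start1 + m$length >= 45L, ]
  expect_gte(nrow(hit), 1L)
  expect_gte(hit$length[1L], 25L)
  expect_identical(hit$mismatches[1L], 0L)

  sP <- plant_copy(s, 20L, 25L, 200L, transform = revcomp)
  mp <- find_repeats(sP, min_len = 20L, max_mismatch = 0L, classes = "P")
  expect_gte(nrow(mp[mp$start1 <= 20L & mp$length >= 25L, ]), 1L)
})

test_that("the oracle resolves tiny hand-checkable cases", {
  # period-4 repeat: forward match between the two ACGT blocks
  o <- oracle_find_repeats("ACGTACGT", min_len = 4L, max_mismatch = 0L,
                           classes = "F")
  expect_identical(o$start1, 1L)
  expect_identical(o$start2, 5L)
  expect_identical(o$length, 4L)
  expect_identical(o$mismatches, 0L)

  # a homopolymer collapses to the single maximal offset-1 self copy
  h <- strrep("A", 50L)
  oh <- oracle_find_repeats(h, min_len = 20L, max_mismatch = 0L,
                            classes = "F")
  expect_identical(nrow(oh), 1L)
  expect_identical(oh$start1, 1L)
  expect_identical(oh$start2, 2L)
  expect_identical(oh$length, 49L)

  # unstructured random sequence: typically empty at 20/0
  r <- oracle_find_repeats(random_seq(200L, 11L), 20L, 0L)
  expect_identical(nrow(r), 0L)
})

test_that("finder and oracle agree across a seeded parameter grid", {
  for (seed in 1:6) {
    s <- random_seq(150L + 90L * seed, seed * 13L)
    for (ml in c(8L, 12L, 20L)) {
      for (mm in c(0L, 1L, 3L)) {
        expect_identical(find_repeats(s, ml, mm),
                         oracle_find_repeats(s, ml, mm),
                         info = sprintf("seed=%d ml=%d mm=%d", seed, ml, mm))
      }
    }
  }
})

test_that("class F is reflection-stable under reverse complement", {
  s <- plant_copy(random_seq(400L, 21L), 30L, 24L, 300L)
  n <- nchar(s)
  f1 <- find_repeats(s, 20L, 1L, classes = "F")
  f2 <- find_repeats(revcomp(s), 20L, 1L, classes = "F")
  # reflect f2 back: a copy at [a, b] maps to [n-b+1, n-a+1]
  refl1 <- n - f2$end2 + 1L
  refl2 <- n - f2$end1 + 1L
  got <- data.frame(start1 = pmin(refl1, refl2), start2 = pmax(refl1, refl2),
                    length = f2$length, mismatches = f2$mismatches)
  got <- got[order(got$start1, got$start2), ]
  want <- f1[order(f1$start1, f1$start2),
             c("start1", "start2", "length", "mismatches")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("reported mismatch counts re-extract exactly", {
  res <- fx_ch()
  seq <- res$genome$sequence
  m <- find_repeats(seq, 20L, 3L)
  expect_gt(nrow(m), 0L)
  for (i in seq_len(nrow(m))) {
    expect_identical(verify_match_mismatches(seq, m[i, ]), m$mismatches[i])
  }
})

test_that("all planted repeats are recovered with exact parameters", {
  res <- fx_ch()
  tr <- res$truth$repeats
  expect_identical(sort(unique(tr$klass)), c("C", "F", "P", "R"))
  for (r in seq_len(nrow(tr))) {
    m <- find_repeats(res$genome$sequence, min_len = tr$length[r],
                      max_mismatch = tr$mismatches[r], classes = tr$klass[r])
    hit <- m$start1 == tr$start1[r] & m$start2 == tr$start2[r] &
      m$length == tr$length[r] & m$mismatches == tr$mismatches[r]
    expect_true(any(hit), info = sprintf("planted row %d (%s)", r,
                                         tr$klass[r]))
  }
})

test_that("length histogram aggregates by class and the planted mode is 20 bp", {
  m <- data.frame(klass = c("F", "F", "P"), start1 = 1L, start2 = 50L,
                  length = c(20L, 20L, 22L), mismatches = 0L,
                  end1 = 1L, end2 = 1L)
  h <- repeat_length_histogram(m)
  expect_identical(h$count[h$klass == "F" & h$length == 20L], 2L)
  expect_identical(h$count[h$klass == "P" & h$length == 22L], 1L)
  expect_identical(nrow(repeat_length_histogram(m[0, ])), 0L)

  tr <- fx_ch()$truth$repeats
  th <- repeat_length_histogram(tr)
  agg <- tapply(th$count, th$length, sum)
  expect_identical(names(which.max(agg)), "20")
})

test_that("guards behave: tiny min_len refused, long min_len warns", {
  s <- random_seq(100L, 3L)
  expect_error(find_repeats(s, min_len = 4L), ">= 8")
  expect_warning(m <- find_repeats(s, min_len = 200L), "exceeds")
  expect_identical(nrow(m), 0L)
  expect_error(oracle_find_repeats(random_seq(2001L, 4L), 20L, 0L), "2000")
})
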