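#!/usr/bin/env Rscript
# Dispersed repeats in four classes (forward, palindrome, complement,
# reverse) at minimum length 20 bp with up to 3 mismatches, plus the
# per-class length histogram and recovery of the generator's planted truth.
suppressPackageStartupMessages(library(mitochar))

dir.create("results/repeats", recursive = TRUE, showWarnings = FALSE)
for (v in c("CH", "CL", "CS")) {
  g <- read_genbank(file.path("results/simulated", paste0(v, ".gb")))
  m <- find_repeats(g$sequence, min_len = 20L, max_mismatch = 3L)
  write.table(m, file.path("results/repeats", paste0(v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  h <- repeat_length_histogram(m)
  write.table(h, file.path("results/repeats", paste0(v, "_histogram.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mode_len <- h$length[which.max(tapply(h$count, h$length, sum)[
    as.character(h$length)])]
  agg <- tapply(h$count, h$length, sum)
  message(sprintf("%s: %d repeat matches; modal length %s bp (n=%d)", v,
                  nrow(m), names(which.max(agg)), max(agg)))

  tru <- jsonlite::read_json(file.path("results/simulated",
                                       paste0(v, ".truth.json")),
                             simplifyVector = TRUE)$repeats
  found <- 0L
  for (r in seq_len(nrow(tru))) {
    mm <- find_repeats(g$sequence, tru$length[r], tru$mismatches[r],
                       classes = tru$klass[r])
    if (any(mm$start1 == tru$start1[r] & mm$start2 == tru$start2[r] &
              mm$length == tru$length[r] &
              mm$mismatches == tru$mismatches[r])) found <- found + 1L
  }
  message(sprintf("  planted truth recovered: %d/%d", found, nrow(tru)))
}
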