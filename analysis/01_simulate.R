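#!/usr/bin/env Rscript
# Generate the three-variant synthetic mitogenome trio (CH/CL/CS layouts)
# plus an evolved trio for selection-pressure analysis, and write the
# fixtures under results/: GenBank flat files, FASTA + feature tables, and
# the generator's ground truth as JSON.
suppressPackageStartupMessages(library(mitochar))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1L) as.integer(args[[1L]]) else 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating variant trio (seed ", seed, ") ...")
trio <- synthetic_trio(seed = seed)
for (v in names(trio)) {
  g <- trio[[v]]$genome
  write_genbank(g, file.path(out, paste0(v, ".gb")))
  write_fasta_with_table(g, file.path(out, paste0(v, ".fa")),
                         file.path(out, paste0(v, ".features.tsv")))
  tru <- trio[[v]]$truth
  jsonlite::write_json(
    list(seed = tru$seed, genome_length = tru$genome_length,
         n_overlaps = tru$n_overlaps, total_overlap_bp = tru$total_overlap_bp,
         n_spacers = tru$n_spacers, total_spacer_bp = tru$total_spacer_bp,
         repeats = tru$repeats),
    file.path(out, paste0(v, ".truth.json")), auto_unbox = TRUE, digits = NA)
  message(sprintf("  %s: %d bp, %d features", v, g$length,
                  nrow(g$features)))
}

message("Simulating evolved trio for Ka/Ks ...")
ev <- evolved_trio(seed = seed)
for (id in names(ev)) {
  write_genbank(ev[[id]], file.path(out, paste0("evolved_", id, ".gb")))
}
jsonlite::write_json(attr(ev, "events"),
                     file.path(out, "evolved_events.json"),
                     auto_unbox = TRUE, digits = NA)
message("Fixtures written under ", out)
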