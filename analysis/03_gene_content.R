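#!/usr/bin/env Rscript
# Gene content and architecture of the simulated trio: strand distribution,
# overlaps and intergenic spacers around the circle, start/stop codon audit
# (including incomplete stops), and the PCG length summary.
suppressPackageStartupMessages(library(mitochar))

dir.create("results/gene_content", recursive = TRUE, showWarnings = FALSE)
for (v in c("CH", "CL", "CS")) {
  g <- read_genbank(file.path("results/simulated", paste0(v, ".gb")))
  b <- boundary_table(g)
  write.table(b, file.path("results/gene_content",
                           paste0("boundaries_", v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- boundary_summary(b)
  aud <- codon_boundary_audit(g)
  write.table(aud, file.path("results/gene_content",
                             paste0("codon_audit_", v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pc <- summarize_pcgs(g)
  sd <- strand_distribution(g)
  message(sprintf(
    "%s: %d overlaps (%d bp, max %d), %d spacers (%d bp); L-strand %d; PCGs %d bp = %.2f%% (%d aa)",
    v, s$n_overlap, s$total_overlap_bp, s$max_overlap_bp, s$n_spacer,
    s$total_spacer_bp, sd$overall[["L"]], pc$total_pcg_bp, pc$fraction_pct,
    pc$codon_total))
  inc <- aud[aud$stop_class != "complete", ]
  message("  incomplete stops: ",
          paste(sprintf("%s (%s)", inc$gene, inc$stop_codon), collapse = ", "))
}
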