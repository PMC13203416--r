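#!/usr/bin/env Rscript
# Codon usage of the 13 concatenated PCGs per genome: counts, RSCU under
# the vertebrate mitochondrial code (Leu/Ser split into their codon-box
# families), and amino-acid usage with the top codon.
suppressPackageStartupMessages(library(mitochar))

dir.create("results/codon_usage", recursive = TRUE, showWarnings = FALSE)
code <- genetic_code(2L)
for (v in c("CH", "CL", "CS")) {
  g <- read_genbank(file.path("results/simulated", paste0(v, ".gb")))
  pcgs <- vapply(which(g$features$type == "PCG"),
                 function(i) extract_gene_sequence(g, i), character(1L))
  counts <- count_codons(pcgs)
  rscu <- compute_rscu(counts, code)
  write_rscu_tsv(rscu, file.path("results/codon_usage",
                                 paste0("rscu_", v, ".tsv")))
  u <- amino_acid_usage(counts, code)
  write.table(u$aa_usage, file.path("results/codon_usage",
                                    paste0("aa_usage_", v, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top_aa <- u$aa_usage$aa[u$aa_usage$aa != "*"][1L]
  message(sprintf("%s: %d codons counted; top amino acid %s; top codon %s (%s, n=%d)",
                  v, sum(counts), top_aa, u$top_codon$codon_rna,
                  u$top_codon$family, u$top_codon$count))
}
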