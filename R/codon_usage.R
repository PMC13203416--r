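#' Count in-frame codons across coding sequences
#'
#' Counts complete codons read from position 1 of each gene. Trailing 1-2 nt
#' partial codons (incomplete stops) are excluded from the 64-entry table
#' but tallied in the `trailing_nt` attribute; codons containing N are
#' skipped and counted in the `skipped` attribute.
#'
#' @param genes character vector of coding-sense nucleotide sequences.
#' @return named integer vector over the 64 codons, with attributes
#'   `skipped` (codons containing N) and `trailing_nt` (partial-codon bases
#'   excluded).
#' @export
count_codons <- function(genes) {
  counts <- setNames(integer(64L), all_codons())
  skipped <- 0L
  trailing <- 0L
  for (g in genes) {
    s <- validate_dna(g, context = "count_codons")
    n <- nchar(s)
    ncod <- n %/% 3L
    trailing <- trailing + (n - 3L * ncod)
    if (ncod == 0L) next
    cods <- substring(s, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
    has_n <- grepl("N", cods, fixed = TRUE)
    skipped <- skipped + sum(has_n)
    tab <- table(cods[!has_n])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  attr(counts, "skipped") <- skipped
  attr(counts, "trailing_nt") <- trailing
  counts
}

# Synonymous families of a code: codons grouped by amino acid and then by
# codon box (first two nucleotides) whenever a family spans several boxes.
# Under table 2 this reproduces the standard RSCU bookkeeping in which Leu
# and Ser each split into a 4-fold and a 2-fold family (Leu1/Leu2,
# Ser1/Ser2) while single-box families (incl. Met = ATA/ATG, Trp = TGA/TGG)
# stay whole.
codon_families <- function(code) {
  codons <- all_codons()
  aa <- translate_codons(codons, code)
  box <- substr(codons, 1L, 2L)
  fam <- paste0(aa, "_", box)
  # keep a single id for families confined to one box
  for (a in unique(aa)) {
    sel <- aa == a
    if (length(unique(box[sel])) == 1L) fam[sel] <- a
  }
  data.frame(codon = codons, aa = aa, family = fam,
             family_size = as.integer(ave(seq_along(fam), fam, FUN = length)),
             stringsAsFactors = FALSE)
}

#' Relative synonymous codon usage
#'
#' RSCU = (codon count / total count of its synonymous family) x family
#' size, computed within each synonymous family of the supplied code (Leu
#' and Ser split into their two codon-box families, sizes 4 and 2).
#' Families with zero total usage get RSCU 0 for every member. Stop codons
#' are excluded unless `include_stops` is set.
#'
#' @param counts 64-entry codon counts from [count_codons()].
#' @param code a [genetic_code()].
#' @param include_stops keep stop codons (as STOP families) in the table.
#' @return data.frame (codon, codon_rna, aa, family, family_size, count,
#'   rscu); within each used family the RSCU values sum to the family size.
#' @export
compute_rscu <- function(counts, code = genetic_code(2L),
                         include_stops = FALSE) {
  fams <- codon_families(code)
  fams$count <- as.integer(counts[fams$codon])
  if (!include_stops) fams <- fams[fams$aa != "*", , drop = FALSE]
  fam_tot <- tapply(fams$count, fams$family, sum)
  tot <- as.numeric(fam_tot[fams$family])
  fams$rscu <- ifelse(tot > 0, fams$count / tot * fams$family_size, 0)
  fams$codon_rna <- chartr("T", "U", fams$codon)
  rownames(fams) <- NULL
  fams[, c("codon", "codon_rna", "aa", "family", "family_size",
           "count", "rscu")]
}

#' Amino-acid usage from codon counts
#'
#' Aggregates codon counts by amino acid (the two Ser codon-box families
#' are merged for the amino-acid totals; stop codons are tallied under a
#' `"*"` pseudo-amino-acid) and reports the single most used codon overall.
#' Ties for the top codon are broken lexicographically and flagged.
#'
#' @param counts 64-entry codon counts from [count_codons()].
#' @param code a [genetic_code()].
#' @return list with `aa_usage` (aa, count; sums to total codon count),
#'   `family_usage` (per codon-box family, e.g. Ser1/Ser2 breakdown) and
#'   `top_codon` (codon, codon_rna, aa, family, count, tie).
#' @export
amino_acid_usage <- function(counts, code = genetic_code(2L)) {
  fams <- codon_families(code)
  fams$count <- as.integer(counts[fams$codon])
  aa_tab <- aggregate(count ~ aa, fams, sum)
  aa_tab <- aa_tab[order(-aa_tab$count, aa_tab$aa), , drop = FALSE]
  rownames(aa_tab) <- NULL
  fam_tab <- aggregate(count ~ family + aa, fams, sum)
  fam_tab <- fam_tab[order(-fam_tab$count, fam_tab$family),
                     c("family", "aa", "count")]
  rownames(fam_tab) <- NULL

  sense <- fams[fams$aa != "*", , drop = FALSE]
  if (sum(sense$count) == 0L) {
    top <- list(codon = NA_character_, codon_rna = NA_character_,
                aa = NA_character_, family = NA_character_,
                count = 0L, tie = FALSE)
  } else {
    mx <- max(sense$count)
    hits <- sense[sense$count == mx, , drop = FALSE]
    hits <- hits[order(hits$codon), , drop = FALSE]
    top <- list(codon = hits$codon[1L],
                codon_rna = chartr("T", "U", hits$codon[1L]),
                aa = hits$aa[1L], family = hits$family[1L],
                count = mx, tie = nrow(hits) > 1L)
  }
  list(aa_usage = aa_tab, family_usage = fam_tab, top_codon = top)
}

#' Write an RSCU table as TSV (RNA alphabet for report codons)
#' @param rscu output of [compute_rscu()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rscu_tsv <- function(rscu, path) {
  out <- rscu
  out$rscu <- round(out$rscu, 4L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
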