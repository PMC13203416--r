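#' Count bases in a nucleotide string
#'
#' @param seq nucleotide string over A/C/G/T/N, case-insensitive.
#' @return named integer vector with counts for A, T, G, C, N; the five
#'   counts sum to the sequence length.
#' @export
count_bases <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    return(c(A = 0L, T = 0L, G = 0L, C = 0L, N = 0L))
  }
  s <- validate_dna(seq, context = "count_bases")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  tab <- table(factor(chars, levels = c("A", "T", "G", "C", "N")))
  setNames(as.integer(tab), names(tab))
}

#' AT-skew and GC-skew from base counts
#'
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), with the
#' zero-denominator convention that a skew whose denominator is zero is
#' reported as 0 (so an A+T-free or G+C-free region is "unskewed" rather
#' than undefined).
#'
#' @param counts named numeric vector carrying at least A, T, G, C.
#' @return named numeric `c(at_skew=, gc_skew=)`, each in `[-1, 1]`.
#' @export
compute_skews <- function(counts) {
  a <- as.numeric(counts[["A"]]); t <- as.numeric(counts[["T"]])
  g <- as.numeric(counts[["G"]]); c <- as.numeric(counts[["C"]])
  stopifnot(a >= 0, t >= 0, g >= 0, c >= 0)
  at <- if ((a + t) == 0) 0 else (a - t) / (a + t)
  gc <- if ((g + c) == 0) 0 else (g - c) / (g + c)
  c(at_skew = at, gc_skew = gc)
}

# One composition row for a labelled sequence. Percentages are over
# A+T+G+C (N excluded from all denominators).
composition_record <- function(region, seq) {
  k <- count_bases(seq)
  tot <- sum(k[c("A", "T", "G", "C")])
  pct <- if (tot == 0) c(A = 0, T = 0, G = 0, C = 0) else {
    100 * k[c("A", "T", "G", "C")] / tot
  }
  sk <- compute_skews(k)
  data.frame(region = region,
             A = k[["A"]], T = k[["T"]], G = k[["G"]], C = k[["C"]],
             N = k[["N"]],
             A_pct = pct[["A"]], T_pct = pct[["T"]],
             G_pct = pct[["G"]], C_pct = pct[["C"]],
             AT_pct = pct[["A"]] + pct[["T"]],
             GC_pct = pct[["G"]] + pct[["C"]],
             AT_skew = sk[["at_skew"]], GC_skew = sk[["gc_skew"]],
             stringsAsFactors = FALSE)
}

#' Composition profile of a genome and its annotated regions
#'
#' One record for the whole genome plus one per feature. Following the
#' usual mitogenome-report convention, per-feature statistics are computed
#' on the H-strand slice of each region regardless of coding strand;
#' `sense = "coding"` switches to coding-sense sequences for cross-checks.
#'
#' @param genome a [mito_genome()].
#' @param sense `"H"` (default) or `"coding"`.
#' @return data.frame of composition records (counts, percentages over
#'   A+T+G+C, AT/GC-skew), first row labelled `"genome"`.
#' @export
composition_profile <- function(genome, sense = c("H", "coding")) {
  sense <- match.arg(sense)
  rows <- list(composition_record("genome", genome$sequence))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    s <- if (sense == "H") {
      hstrand_slice(genome, f$start[i], f$end[i])
    } else {
      extract_gene_sequence(genome, i)
    }
    rows[[length(rows) + 1L]] <- composition_record(f$name[i], s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a composition profile as TSV
#'
#' Report rounding: two decimals for percentages, four for skews (full
#' precision is retained in the in-memory profile).
#'
#' @param profile output of [composition_profile()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(profile, path) {
  p <- profile
  pcts <- c("A_pct", "T_pct", "G_pct", "C_pct", "AT_pct", "GC_pct")
  p[pcts] <- lapply(p[pcts], round, 2L)
  p[c("AT_skew", "GC_skew")] <- lapply(p[c("AT_skew", "GC_skew")], round, 4L)
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
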