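#' Circular boundary table: overlaps, spacers and abutting gene pairs
#'
#' Walks consecutive features in start order around the circle (including
#' the wrap-around pair last -> first) and classifies each junction as an
#' overlap (shared bp), an intergenic spacer (bp strictly between), or
#' abutting (distance 0). Nested features (fully contained in another) are
#' excluded from the boundary chain and reported via the `"nested"`
#' attribute rather than silently merged.
#'
#' @param genome a circular [mito_genome()] with at least 2 features.
#' @return data.frame (upstream_gene, downstream_gene, kind, length) with
#'   attributes `summary` (counts and total bp per kind) and `nested`
#'   (names of excluded nested features).
#' @export
boundary_table <- function(genome) {
  f <- genome$features
  if (!genome$circular) stop("boundary_table requires a circular genome",
                             call. = FALSE)
  if (nrow(f) < 2L) stop("boundary_table requires >= 2 features", call. = FALSE)
  L <- genome$length
  s <- f$start
  e <- ifelse(f$end >= f$start, f$end, f$end + L)  # unrolled end

  nested <- rep(FALSE, nrow(f))
  for (i in seq_len(nrow(f))) {
    nested[i] <- any(s <= s[i] & e >= e[i] & seq_len(nrow(f)) != i &
                       !(s == s[i] & e == e[i]))
  }
  keep <- which(!nested)
  if (length(keep) < 2L) stop("fewer than 2 non-nested features", call. = FALSE)
  ord <- keep[order(s[keep])]
  n <- length(ord)
  up <- ord
  dn <- c(ord[-1L], ord[1L])
  next_start <- c(s[ord[-1L]], s[ord[1L]] + L)      # wrap pair unrolled
  gap <- next_start - e[up] - 1L

  out <- data.frame(upstream_gene = f$name[up], downstream_gene = f$name[dn],
                    kind = ifelse(gap > 0L, "spacer",
                           ifelse(gap == 0L, "abutting", "overlap")),
                    length = abs(gap), stringsAsFactors = FALSE)
  attr(out, "summary") <- list(
    n_overlap = sum(out$kind == "overlap"),
    n_spacer = sum(out$kind == "spacer"),
    n_abutting = sum(out$kind == "abutting"),
    total_overlap_bp = sum(out$length[out$kind == "overlap"]),
    total_spacer_bp = sum(out$length[out$kind == "spacer"]),
    max_overlap_bp = if (any(out$kind == "overlap")) {
      max(out$length[out$kind == "overlap"])
    } else 0L,
    max_spacer_bp = if (any(out$kind == "spacer")) {
      max(out$length[out$kind == "spacer"])
    } else 0L)
  attr(out, "nested") <- f$name[nested]
  out
}

#' Summary of a boundary table
#' @param boundaries output of [boundary_table()].
#' @return the `summary` attribute (counts and totals per junction kind).
#' @export
boundary_summary <- function(boundaries) attr(boundaries, "summary")

#' Feature counts per strand and type
#'
#' @param genome a [mito_genome()].
#' @return list with `overall` (named counts H/L) and `by_type`
#'   (data.frame type, H, L).
#' @export
strand_distribution <- function(genome) {
  f <- genome$features
  types <- FEATURE_TYPES
  by_type <- data.frame(type = types,
                        H = vapply(types, function(t) {
                          sum(f$type == t & f$strand == "H")
                        }, integer(1L)),
                        L = vapply(types, function(t) {
                          sum(f$type == t & f$strand == "L")
                        }, integer(1L)),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(overall = c(H = sum(f$strand == "H"), L = sum(f$strand == "L")),
       by_type = by_type)
}

#' Start/stop codon audit of protein-coding genes
#'
#' The start codon is the first 3 nt of the coding-sense sequence. The stop
#' codon is the final 3-mer when the gene length is a multiple of 3, or the
#' trailing 1 or 2 nt otherwise — the incomplete stops (T, TA) completed to
#' TAA by post-transcriptional polyadenylation. AGA/AGG are complete stops
#' under the vertebrate mitochondrial code.
#'
#' @param genome a [mito_genome()] with PCG features.
#' @param code a [genetic_code()] (default table 2).
#' @return data.frame (gene, start_codon, stop_codon, stop_class, note);
#'   `stop_class` is `complete`, `incomplete_TA` or `incomplete_T`; `note`
#'   flags genes whose nominal complete stop does not map to STOP, or
#'   incomplete stops that are not T/TA.
#' @export
codon_boundary_audit <- function(genome, code = genetic_code(2L)) {
  pcgs <- which(genome$features$type == "PCG")
  rows <- lapply(pcgs, function(i) {
    gene <- genome$features$name[i]
    s <- extract_gene_sequence(genome, i)
    n <- nchar(s)
    if (n < 6L) {
      stop(sprintf("audit error: PCG '%s' is shorter than 6 nt (%d)", gene, n),
           call. = FALSE)
    }
    r <- n %% 3L
    start_codon <- substr(s, 1L, 3L)
    if (r == 0L) {
      stop_codon <- substr(s, n - 2L, n)
      stop_class <- "complete"
      note <- if (isTRUE(is_stop_codon(stop_codon, code))) "" else
        "terminal codon is not a stop"
    } else if (r == 2L) {
      stop_codon <- substr(s, n - 1L, n)
      stop_class <- "incomplete_TA"
      note <- if (stop_codon == "TA") "" else "trailing 2-mer is not TA"
    } else {
      stop_codon <- substr(s, n, n)
      stop_class <- "incomplete_T"
      note <- if (stop_codon == "T") "" else "trailing base is not T"
    }
    data.frame(gene = gene, start_codon = start_codon, stop_codon = stop_codon,
               stop_class = stop_class, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), start_codon = character(),
                      stop_codon = character(), stop_class = character(),
                      note = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Protein-coding gene summary
#'
#' Total PCG length, its share of the genome (a percentage, two decimals),
#' and the encoded amino-acid total computed as `round(total / 3)` — the
#' conventional summary arithmetic (e.g. 11,421 bp -> 3807 codons), even
#' though incomplete stops make per-gene codon counts ragged.
#'
#' @param genome a [mito_genome()].
#' @return list with `total_pcg_bp`, `genome_bp`, `fraction_pct`,
#'   `codon_total`, `n_pcgs`, `missing` (canonical symbols not annotated).
#' @export
summarize_pcgs <- function(genome) {
  f <- genome$features
  pcg <- f[f$type == "PCG", , drop = FALSE]
  missing <- setdiff(canonical_pcgs(), pcg$name)
  if (length(missing) > 0L) {
    warning("missing canonical PCG(s): ", paste(missing, collapse = ", "))
  }
  total <- sum(feature_lengths(pcg$start, pcg$end, genome$length))
  list(total_pcg_bp = as.integer(total),
       genome_bp = genome$length,
       fraction_pct = round(100 * total / genome$length, 2L),
       codon_total = as.integer(round(total / 3)),
       n_pcgs = nrow(pcg),
       missing = missing)
}
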