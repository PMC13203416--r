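#' Configuration for a characterization run
#'
#' One declarative object capturing every analysis parameter so a run's
#' settings are reviewable data: repeat search (minimum length 20 bp,
#' 3 mismatches), genetic code table 2, collinearity anchor length, and
#' the RSCU stop-codon flag.
#'
#' @param min_repeat_len minimum dispersed-repeat length (bp).
#' @param max_repeat_mismatch substitutions tolerated in a repeat.
#' @param genetic_code_id NCBI translation table id.
#' @param anchor_min_len minimum collinearity anchor length (bp).
#' @param rscu_include_stops include stop codons in RSCU tables.
#' @param composition_sense `"H"` or `"coding"` for per-region composition.
#' @return list of class `characterization_config`.
#' @export
characterization_config <- function(min_repeat_len = 20L,
                                    max_repeat_mismatch = 3L,
                                    genetic_code_id = 2L,
                                    anchor_min_len = 20L,
                                    rscu_include_stops = FALSE,
                                    composition_sense = "H") {
  structure(list(min_repeat_len = as.integer(min_repeat_len),
                 max_repeat_mismatch = as.integer(max_repeat_mismatch),
                 genetic_code_id = as.integer(genetic_code_id),
                 anchor_min_len = as.integer(anchor_min_len),
                 rscu_include_stops = isTRUE(rscu_include_stops),
                 composition_sense = composition_sense),
            class = "characterization_config")
}

# Coerce an input (mito_genome or file path) to a genome object.
as_mito_genome <- function(x) {
  if (inherits(x, "mito_genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_genbank(x))
  stop("inputs must be mito_genome objects or GenBank file paths",
       call. = FALSE)
}

#' Run the full characterization over one or more genomes
#'
#' Per-genome sections: composition profile, boundary table, strand
#' distribution, codon audit, PCG summary, codon usage (counts, RSCU,
#' amino-acid usage), dispersed repeats and their length histogram.
#' Cross-genome sections (when >= 2 inputs): pairwise Ka/Ks, collinearity
#' of each genome against the first, and (>= 2) the concatenated PCG
#' alignment with partitions, plus a neighbor-joining sanity tree when
#' >= 3 genomes. Per-genome failures are isolated: the report marks that
#' genome failed and the others proceed. Sections that cannot run are
#' explicitly marked skipped.
#'
#' @param inputs list of [mito_genome()] objects and/or GenBank paths.
#' @param config a [characterization_config()].
#' @param out_dir optional directory: writes per-section TSVs and a
#'   machine-readable report JSON (deterministic, no timestamps, so
#'   identical inputs reproduce byte-identical artifacts).
#' @return list of class `characterization_report` with `genomes` (per-id
#'   section lists), `cross` (kaks/collinearity/concat/tree or "skipped"
#'   markers), and `provenance` (ids, lengths, config, package version).
#' @export
run_characterization <- function(inputs, config = characterization_config(),
                                 out_dir = NULL) {
  if (length(inputs) == 0L) stop("usage error: no input genomes", call. = FALSE)
  genomes <- lapply(inputs, as_mito_genome)
  ids <- vapply(genomes, `[[`, character(1L), "id")
  names(genomes) <- ids
  code <- genetic_code(config$genetic_code_id)

  per_genome <- lapply(genomes, function(g) {
    tryCatch({
      pcg_seqs <- vapply(which(g$features$type == "PCG"),
                         function(i) extract_gene_sequence(g, i),
                         character(1L))
      counts <- count_codons(pcg_seqs)
      reps <- find_repeats(g$sequence, config$min_repeat_len,
                           config$max_repeat_mismatch)
      list(status = "ok",
           composition = composition_profile(g, config$composition_sense),
           boundaries = boundary_table(g),
           strands = strand_distribution(g),
           codon_audit = codon_boundary_audit(g, code),
           pcg_summary = summarize_pcgs(g),
           codon_counts = counts,
           rscu = compute_rscu(counts, code, config$rscu_include_stops),
           aa_usage = amino_acid_usage(counts, code),
           repeats = reps,
           repeat_histogram = repeat_length_histogram(reps))
    }, error = function(e) list(status = "failed",
                                error = conditionMessage(e)))
  })

  cross <- list(kaks = "skipped", collinearity = "skipped",
                concat = "skipped", tree = "skipped")
  ok_ids <- ids[vapply(per_genome, function(x) x$status == "ok", logical(1L))]
  if (length(ok_ids) >= 2L) {
    gg <- genomes[ok_ids]
    cross$kaks <- pairwise_kaks_table(gg, code = code)
    ref <- gg[[1L]]
    cross$collinearity <- lapply(gg[-1L], function(q) {
      anc <- maximal_exact_matches(ref$sequence, q$sequence,
                                   config$anchor_min_len)
      dotplot_table(anc, ref$length)
    })
    cross$concat <- concat_pcgs(gg, code = code)
    if (length(ok_ids) >= 3L) {
      cross$tree <- nj_sanity_tree(cross$concat$alignment)
    }
  }

  report <- structure(list(
    genomes = per_genome, cross = cross,
    provenance = list(ids = ids,
                      lengths = vapply(genomes, `[[`, integer(1L), "length"),
                      config = unclass(config),
                      package_version =
                        as.character(utils::packageVersion("mitochar")))),
    class = "characterization_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization_report> %d genome(s): %s\n",
              length(x$genomes), paste(names(x$genomes), collapse = ", ")))
  for (id in names(x$genomes)) {
    g <- x$genomes[[id]]
    if (g$status != "ok") {
      cat(sprintf("  %s: FAILED (%s)\n", id, g$error))
    } else {
      cat(sprintf("  %s: PCGs %.2f%% of genome, %d repeats\n", id,
                  g$pcg_summary$fraction_pct, nrow(g$repeats)))
    }
  }
  invisible(x)
}

#' Write a characterization report's artifacts
#'
#' One TSV per section per genome plus `report.json`. Deterministic output
#' (sorted sections, no timestamps).
#'
#' @param report a `characterization_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  summaries <- list()
  for (id in names(report$genomes)) {
    g <- report$genomes[[id]]
    if (g$status != "ok") {
      summaries[[id]] <- list(status = "failed", error = g$error)
      next
    }
    write_composition_tsv(g$composition, p("composition_", id, ".tsv"))
    write.table(g$boundaries, p("boundaries_", id, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(g$codon_audit, p("codon_audit_", id, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_rscu_tsv(g$rscu, p("rscu_", id, ".tsv"))
    write.table(g$repeats, p("repeats_", id, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(g$repeat_histogram, p("repeat_histogram_", id, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summaries[[id]] <- list(status = "ok", pcg_summary = g$pcg_summary,
                            boundary_summary = boundary_summary(g$boundaries),
                            top_codon = g$aa_usage$top_codon,
                            n_repeats = nrow(g$repeats))
  }
  if (is.list(report$cross$kaks)) {
    write.table(report$cross$kaks$results, p("kaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(report$cross$kaks$summary, p("kaks_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (is.list(report$cross$concat)) {
    write_concat(report$cross$concat, p("concat_pcgs.fasta"),
                 p("concat_partitions.txt"))
  }
  if (inherits(report$cross$tree, "phylo")) {
    ape::write.tree(report$cross$tree, p("nj_tree.nwk"))
  }
  jsonlite::write_json(list(provenance = report$provenance,
                            genomes = summaries),
                       p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Concatenated protein-guided codon alignment of the 13 PCGs
#'
#' Per-gene codon alignments are built by aligning every genome's protein
#' to the first genome carrying the gene (reference-anchored merge:
#' insertions relative to the reference open gap columns for everyone;
#' insertions from different genomes at the same reference gap are
#' left-aligned, the usual center-star behavior) and concatenated in
#' canonical gene order. A genome missing a gene contributes an all-gap
#' block for it, with a warning.
#'
#' @param genomes named list of [mito_genome()] objects (>= 2).
#' @param genes gene symbols in concatenation order (default ND1..CYTB
#'   canonical order).
#' @param code a [genetic_code()].
#' @return list with `alignment` (named equal-length gapped nucleotide
#'   strings) and `partitions` (gene, start, end; spans tile the
#'   alignment exactly).
#' @export
concat_pcgs <- function(genomes, genes = canonical_pcgs(),
                        code = genetic_code(2L)) {
  stopifnot(length(genomes) >= 2L)
  ids <- names(genomes)
  if (is.null(ids)) {
    ids <- vapply(genomes, `[[`, character(1L), "id")
    names(genomes) <- ids
  }
  blocks <- setNames(vector("list", length(ids)), ids)
  for (id in ids) blocks[[id]] <- character()
  partitions <- list()
  col0 <- 0L
  for (gene in genes) {
    have <- ids[vapply(genomes, function(g) gene %in% g$features$name,
                       logical(1L))]
    if (length(have) == 0L) next
    if (length(have) < length(ids)) {
      warning(sprintf("gene %s missing in %s: gap block inserted", gene,
                      paste(setdiff(ids, have), collapse = ", ")))
    }
    seqs <- lapply(genomes[have], function(g) {
      strip_terminal_stop(extract_gene_sequence(g, gene), code)
    })
    aligned <- anchor_align(seqs, gene, code)
    width <- nchar(aligned[[1L]])
    for (id in ids) {
      blocks[[id]] <- c(blocks[[id]],
                        if (id %in% have) aligned[[id]] else
                          strrep("-", width))
    }
    partitions[[length(partitions) + 1L]] <- data.frame(
      gene = gene, start = col0 + 1L, end = col0 + width,
      stringsAsFactors = FALSE)
    col0 <- col0 + width
  }
  list(alignment = vapply(blocks, paste, character(1L), collapse = ""),
       partitions = do.call(rbind, partitions))
}

# Reference-anchored codon MSA of one gene across genomes: pairwise
# protein-guided alignment of each sequence to the first, merged on
# reference coordinates with per-gap maximal insertion widths.
anchor_align <- function(seqs, gene, code) {
  ids <- names(seqs)
  if (length(ids) == 1L) return(setNames(list(seqs[[1L]]), ids))
  ref_id <- ids[1L]
  pairs <- lapply(ids[-1L], function(id) {
    align_codon_pair(gene, seqs[[ref_id]], seqs[[id]], code)
  })
  names(pairs) <- ids[-1L]
  ref_cods <- split_codons(seqs[[ref_id]])
  R <- length(ref_cods)
  # decompose each pairwise alignment into per-reference-position events
  decomp <- lapply(pairs, function(aln) {
    a1 <- split_codons(aln$seq1)
    a2 <- split_codons(aln$seq2)
    at_ref <- rep(NA_character_, R)      # codon aligned to each ref position
    ins <- vector("list", R + 1L)        # insertions after ref position r
    for (k in seq_len(R + 1L)) ins[[k]] <- character()
    r <- 0L
    for (j in seq_along(a1)) {
      if (a1[j] == "---") {
        ins[[r + 1L]] <- c(ins[[r + 1L]], a2[j])
      } else {
        r <- r + 1L
        at_ref[r] <- a2[j]
      }
    }
    list(at_ref = at_ref, ins = ins)
  })
  max_ins <- vapply(seq_len(R + 1L), function(k) {
    max(c(0L, vapply(decomp, function(d) length(d$ins[[k]]), integer(1L))))
  }, integer(1L))
  build_row <- function(at_ref, ins) {
    out <- character()
    for (k in seq_len(R + 1L)) {
      pad <- max_ins[k] - length(ins[[k]])
      out <- c(out, ins[[k]], rep("---", pad))
      if (k <= R) out <- c(out, at_ref[k])
    }
    paste(out, collapse = "")
  }
  rows <- setNames(vector("list", length(ids)), ids)
  rows[[ref_id]] <- build_row(ref_cods,
                              lapply(seq_len(R + 1L),
                                     function(k) rep("---", 0L)))
  for (id in ids[-1L]) {
    rows[[id]] <- build_row(decomp[[id]]$at_ref, decomp[[id]]$ins)
  }
  rows
}

#' Write a concatenated alignment as FASTA plus RAxML-style partitions
#'
#' @param concat output of [concat_pcgs()].
#' @param fasta_path,partition_path output paths.
#' @return list of paths, invisibly.
#' @export
write_concat <- function(concat, fasta_path, partition_path) {
  ss <- Biostrings::DNAStringSet(concat$alignment)
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  lines <- sprintf("DNA, %s = %d-%d", concat$partitions$gene,
                   concat$partitions$start, concat$partitions$end)
  writeLines(lines, partition_path)
  invisible(list(fasta = fasta_path, partitions = partition_path))
}

#' Neighbor-joining sanity tree from a concatenated alignment
#'
#' A lightweight topology check on the concatenated PCG alignment:
#' Kimura 2-parameter distances and neighbor joining, deterministic given
#' the alignment. Saturated (undefined) distances are capped at twice the
#' largest finite distance and flagged via the `"capped"` attribute.
#'
#' @param alignment named equal-length gapped nucleotide strings (>= 3).
#' @return an [ape::nj()] `phylo` tree with branch lengths.
#' @export
nj_sanity_tree <- function(alignment) {
  stopifnot(length(alignment) >= 3L)
  mat <- do.call(rbind, lapply(alignment, function(s) {
    tolower(strsplit(s, "")[[1L]])
  }))
  rownames(mat) <- names(alignment)
  dna <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE)
  capped <- FALSE
  bad <- !is.finite(d)
  if (any(bad)) {
    capped <- TRUE
    mx <- if (any(!bad)) max(d[!bad]) else 1
    d[bad] <- 2 * mx
  }
  tr <- ape::nj(d)
  attr(tr, "capped") <- capped
  tr
}
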