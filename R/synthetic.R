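# ---------------------------------------------------------------------------
# Seeded generator of annotated circular mitogenomes carrying ground truth
# for every downstream statistic: a 37-gene vertebrate layout (13 PCGs,
# 22 tRNAs, 2 rRNAs) plus control region, configurable base composition,
# planted overlaps/spacers, planted dispersed repeats of each class, and
# controlled synonymous/nonsynonymous divergence between genome pairs.
# ---------------------------------------------------------------------------

#' Canonical 37-gene layout for a synthetic water-shrew-like mitogenome
#'
#' Gene order, strands and junction gaps follow the canonical vertebrate
#' mitochondrial plan (WANCY tRNA cluster with the large tRNA-Asn/tRNA-Cys
#' spacer at the light-strand replication origin, the 43 bp ATP8/ATP6
#' overlap, ND6 and eight tRNAs on the L-strand, D-loop between tRNA-Pro
#' and tRNA-Phe). The three variants reproduce the genome arithmetic of
#' three congeneric species: total PCG length 11,421 bp (CH, CL) or
#' 11,424 bp (CS, whose ND5 is 3 bp longer), genome lengths
#' 17,218 / 17,202 / 17,211 bp, nine overlaps totaling 78 bp and fourteen
#' spacers totaling 72 / 73 / 70 bp.
#'
#' `gap_after` is the junction to the next gene in circular order
#' (negative = overlap, 0 = abutting, positive = spacer; the last row's gap
#' is the wrap-around junction to the first gene).
#'
#' @param variant `"CH"`, `"CL"` or `"CS"`.
#' @return data.frame (name, type, length, strand, gap_after, start_codon,
#'   stop_codon).
#' @export
mito_gene_layout <- function(variant = c("CH", "CL", "CS")) {
  variant <- match.arg(variant)
  rrnL_len <- c(CH = 1671L, CL = 1665L, CS = 1672L)[[variant]]
  nd5_len <- c(CH = 1821L, CL = 1821L, CS = 1824L)[[variant]]
  dloop_len <- c(CH = 1750L, CL = 1739L, CS = 1741L)[[variant]]
  asn_gap <- c(CH = 43L, CL = 43L, CS = 42L)[[variant]]
  wrap_gap <- c(CH = 12L, CL = 13L, CS = 11L)[[variant]]
  cox1_stop <- c(CH = "TAG", CL = "TAA", CS = "TAG")[[variant]]

  lay <- data.frame(
    name = c("tRNA-Phe", "rrnS", "tRNA-Val", "rrnL", "tRNA-Leu(UUR)",
             "ND1", "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp",
             "tRNA-Ala", "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "COX1",
             "tRNA-Ser(UCN)", "tRNA-Asp", "COX2", "tRNA-Lys", "ATP8",
             "ATP6", "COX3", "tRNA-Gly", "ND3", "tRNA-Arg", "ND4L", "ND4",
             "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)", "ND5", "ND6",
             "tRNA-Glu", "CYTB", "tRNA-Thr", "tRNA-Pro", "D-loop"),
    type = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA", "PCG", "tRNA", "tRNA",
             "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "tRNA", "tRNA", "PCG",
             "tRNA", "tRNA", "PCG", "tRNA", "PCG", "PCG", "PCG", "tRNA",
             "PCG", "tRNA", "PCG", "PCG", "tRNA", "tRNA", "tRNA", "PCG",
             "PCG", "tRNA", "PCG", "tRNA", "tRNA", "control_region"),
    length = c(65L, 956L, 65L, rrnL_len, 65L, 957L, 65L, 65L, 65L, 1056L,
               65L, 65L, 65L, 65L, 65L, 1545L, 65L, 65L, 684L, 63L, 204L,
               681L, 785L, 65L, 345L, 63L, 297L, 1378L, 65L, 65L, 65L,
               nd5_len, 528L, 65L, 1140L, 65L, 65L, dloop_len),
    strand = c("H", "H", "H", "H", "H", "H", "H", "L", "H", "H", "H", "L",
               "L", "L", "L", "H", "L", "H", "H", "H", "H", "H", "H", "H",
               "H", "H", "H", "H", "H", "H", "H", "H", "L", "L", "H", "H",
               "L", "H"),
    gap_after = c(0L, 0L, 0L, 0L, 2L, 0L, -3L, 0L, 0L, 0L, 1L, 1L, asn_gap,
                  -2L, 1L, -3L, 2L, 0L, 1L, 1L, -43L, -1L, 0L, 0L, 1L, 0L,
                  -7L, 0L, 0L, 1L, 0L, -17L, -1L, 2L, 1L, -1L, 3L, wrap_gap),
    stringsAsFactors = FALSE)

  lay$start_codon <- NA_character_
  lay$stop_codon <- NA_character_
  pcg <- lay$type == "PCG"
  lay$start_codon[pcg] <- ifelse(lay$name[pcg] %in% c("ND2", "ND3", "ND5"),
                                 "ATA", "ATG")
  lay$stop_codon[pcg] <- "TAA"
  lay$stop_codon[lay$name == "ND4"] <- "T"
  lay$stop_codon[lay$name == "COX3"] <- "TA"
  lay$stop_codon[lay$name == "CYTB"] <- "AGA"
  lay$stop_codon[lay$name == "COX1"] <- cox1_stop
  lay
}

#' Default plan of planted dispersed repeats
#'
#' One representative of each class plus extra 20 bp forward copies so that
#' the planted length distribution has its mode at 20 bp, the dominant
#' repeat length in surveyed mitogenomes.
#'
#' @return data.frame (klass, length, mismatches).
#' @export
default_repeat_plan <- function() {
  data.frame(klass = c("F", "P", "C", "R", "F", "F", "F"),
             length = c(25L, 24L, 22L, 20L, 20L, 20L, 21L),
             mismatches = c(0L, 1L, 2L, 0L, 0L, 1L, 0L),
             stringsAsFactors = FALSE)
}

#' Default per-gene divergence rates for evolved genome pairs
#'
#' Rates are per-site proportions: `syn_rate` is the planted fraction of
#' synonymous sites substituted, `nonsyn_rate` the fraction of
#' nonsynonymous sites. The defaults emulate strong purifying selection on
#' all 13 PCGs with relaxed constraint on ATP8 (5x the baseline
#' nonsynonymous rate) and the strongest constraint on COX1/COX2 (1/5 of
#' baseline), giving Ka/Ks values spanning roughly 0.01-0.27.
#'
#' @return data.frame (gene, syn_rate, nonsyn_rate).
#' @export
default_divergence <- function() {
  genes <- canonical_pcgs()
  d <- data.frame(gene = genes, syn_rate = 0.10, nonsyn_rate = 0.0056,
                  stringsAsFactors = FALSE)
  d$nonsyn_rate[d$gene == "ATP8"] <- 0.028
  d$nonsyn_rate[d$gene %in% c("COX1", "COX2")] <- 0.0011
  d
}

#' Specification for a synthetic mitogenome
#'
#' @param variant layout variant (`"CH"`, `"CL"`, `"CS"`).
#' @param seed integer RNG seed; identical specs with identical seeds
#'   produce byte-identical genomes.
#' @param base_probs sampling probabilities for A/T/G/C. The default
#'   follows the composition printed for the emulated genomes: T > A
#'   (negative AT-skew) and G > C (positive GC-skew), A+T = 65%.
#' @param layout a [mito_gene_layout()]-shaped data.frame.
#' @param repeat_plan planted dispersed repeats ([default_repeat_plan()]),
#'   or NULL for none.
#' @param id genome label.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(variant = "CH", seed = 1L,
                           base_probs = c(A = 0.314, T = 0.336,
                                          G = 0.225, C = 0.125),
                           layout = mito_gene_layout(variant),
                           repeat_plan = default_repeat_plan(),
                           id = paste0("SYN_", variant)) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-9,
            setequal(names(base_probs), DNA_BASES))
  coords <- layout_coords(layout)
  structure(list(variant = variant, seed = as.integer(seed),
                 base_probs = base_probs, layout = coords,
                 repeat_plan = repeat_plan,
                 genome_length = attr(coords, "genome_length"), id = id),
            class = "synthetic_spec")
}

# Resolve a layout into 1-based coordinates; errors if the junction
# arithmetic is inconsistent (spec error before generation).
layout_coords <- function(layout) {
  n <- nrow(layout)
  start <- integer(n); end <- integer(n)
  start[1L] <- 1L
  for (i in seq_len(n)) {
    end[i] <- start[i] + layout$length[i] - 1L
    if (i < n) start[i + 1L] <- end[i] + layout$gap_after[i] + 1L
  }
  L <- end[n] + layout$gap_after[n]
  if (any(start < 1L) || any(end > L)) {
    stop("inconsistent layout arithmetic: feature outside [1, genome length]",
         call. = FALSE)
  }
  out <- cbind(layout, start = start, end = end)
  attr(out, "genome_length") <- as.integer(L)
  out
}

# Genome positions of a gene in coding order (H: start..end; L: end..start,
# complemented on access).
coding_positions <- function(start, end, strand) {
  if (strand == "H") start:end else end:start
}

COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Read/write coding-sense bases of a gene on the genome character vector.
read_coding <- function(chars, pos, strand) {
  b <- chars[pos]
  if (strand == "L") b <- unname(COMP_MAP[b])
  b
}
write_coding <- function(chars, pos, strand, bases) {
  if (strand == "L") bases <- unname(COMP_MAP[bases])
  chars[pos] <- bases
  chars
}

# Non-stop codon sampling distribution matched to base probabilities.
nonstop_codon_probs <- function(base_probs, code) {
  codons <- all_codons()
  p <- base_probs[substr(codons, 1, 1)] * base_probs[substr(codons, 2, 2)] *
    base_probs[substr(codons, 3, 3)]
  p[translate_codons(codons, code) == "*"] <- 0
  setNames(p / sum(p), codons)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic for a fixed spec + seed. The background is sampled from
#' the spec's base probabilities; PCG interiors are sampled codon-wise from
#' a non-stop codon distribution matched to those probabilities, so genes
#' are translatable without rejection loops; start and stop codons
#' (complete or incomplete, per layout) are planted; interior in-frame
#' stops that arise in gene-overlap regions are repaired without touching
#' planted codons; dispersed repeats are planted in the control region.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (a [mito_genome()]) and `truth` (layout with
#'   coordinates, planted repeat table, protected positions, boundary-gap
#'   bookkeeping, base probabilities, seed).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code(2L)
  lay <- spec$layout
  L <- spec$genome_length

  with_seed(spec$seed, {
    chars <- sample(names(spec$base_probs), L, replace = TRUE,
                    prob = spec$base_probs)
    cod_p <- nonstop_codon_probs(spec$base_probs, code)

    pcg_rows <- which(lay$type == "PCG")
    for (i in pcg_rows) {
      ncod <- lay$length[i] %/% 3L
      extra <- lay$length[i] %% 3L
      cods <- sample(names(cod_p), ncod, replace = TRUE, prob = cod_p)
      bases <- strsplit(paste(cods, collapse = ""), "")[[1L]]
      if (extra > 0L) {
        bases <- c(bases, sample(names(spec$base_probs), extra,
                                 replace = TRUE, prob = spec$base_probs))
      }
      pos <- coding_positions(lay$start[i], lay$end[i], lay$strand[i])
      chars <- write_coding(chars, pos, lay$strand[i], bases)
    }

    # plant start/stop codons after all interiors are laid down
    frozen <- integer()
    for (i in pcg_rows) {
      pos <- coding_positions(lay$start[i], lay$end[i], lay$strand[i])
      sc <- strsplit(lay$start_codon[i], "")[[1L]]
      chars <- write_coding(chars, pos[1:3], lay$strand[i], sc)
      st <- strsplit(lay$stop_codon[i], "")[[1L]]
      k <- length(st)
      stop_pos <- pos[(lay$length[i] - k + 1L):lay$length[i]]
      chars <- write_coding(chars, stop_pos, lay$strand[i], st)
      frozen <- c(frozen, pos[1:3], stop_pos)
    }

    chars <- repair_internal_stops(chars, lay, code, frozen)

    repeats <- data.frame(klass = character(), start1 = integer(),
                          start2 = integer(), length = integer(),
                          mismatches = integer(), stringsAsFactors = FALSE)
    protected <- integer()
    if (!is.null(spec$repeat_plan) && nrow(spec$repeat_plan) > 0L) {
      dl <- which(lay$type == "control_region")[1L]
      planted <- plant_repeats_chars(chars, spec$repeat_plan,
                                     region = c(lay$start[dl], lay$end[dl]),
                                     base_probs = spec$base_probs)
      chars <- planted$chars
      repeats <- planted$truth
      protected <- planted$protected
    }

    feats <- gene_features(lay$name, lay$type, lay$start, lay$end, lay$strand)
    genome <- mito_genome(spec$id, paste(chars, collapse = ""), feats,
                          circular = TRUE)
    truth <- list(layout = lay, genome_length = L, repeats = repeats,
                  protected_positions = sort(unique(c(protected, frozen))),
                  base_probs = spec$base_probs, seed = spec$seed,
                  n_overlaps = sum(lay$gap_after < 0L),
                  n_spacers = sum(lay$gap_after > 0L),
                  total_overlap_bp = sum(-lay$gap_after[lay$gap_after < 0L]),
                  total_spacer_bp = sum(lay$gap_after[lay$gap_after > 0L]))
    list(genome = genome, truth = truth)
  })
}

# Interior codon indices of a PCG: every complete codon except the first
# (start) and, for genes whose length is a multiple of 3, the last (stop).
interior_codons <- function(len) {
  ncod <- len %/% 3L
  last <- if (len %% 3L == 0L) ncod - 1L else ncod
  if (last < 2L) integer() else 2L:last
}

# Remove in-frame stop codons from PCG interiors (they can arise where
# genes overlap or where a planted codon straddles another gene's frame)
# by changing one non-frozen base per offending codon, checked against the
# frames of every PCG covering that base. Frame offsets in the layout
# guarantee a free position exists; errors after max_pass if not.
repair_internal_stops <- function(chars, lay, code, frozen, max_pass = 20L) {
  pcg_rows <- which(lay$type == "PCG")
  pos_maps <- lapply(pcg_rows, function(i) {
    coding_positions(lay$start[i], lay$end[i], lay$strand[i])
  })
  names(pos_maps) <- as.character(pcg_rows)
  covering <- function(pos) {
    hits <- list()
    for (i in pcg_rows) {
      if (pos >= lay$start[i] && pos <= lay$end[i]) {
        hits[[length(hits) + 1L]] <- i
      }
    }
    hits
  }
  codon_at <- function(i, idx) {
    pm <- pos_maps[[as.character(i)]]
    paste(read_coding(chars, pm[(3L * idx - 2L):(3L * idx)], lay$strand[i]),
          collapse = "")
  }
  bad_codons <- function() {
    out <- list()
    for (i in pcg_rows) {
      for (idx in interior_codons(lay$length[i])) {
        if (isTRUE(is_stop_codon(codon_at(i, idx), code))) {
          out[[length(out) + 1L]] <- c(i, idx)
        }
      }
    }
    out
  }
  for (pass in seq_len(max_pass)) {
    bad <- bad_codons()
    if (length(bad) == 0L) return(chars)
    for (b in bad) {
      i <- b[1L]; idx <- b[2L]
      pm <- pos_maps[[as.character(i)]]
      cpos <- pm[(3L * idx - 2L):(3L * idx)]
      if (!isTRUE(is_stop_codon(codon_at(i, idx), code))) next
      fixed <- FALSE
      for (pos in setdiff(cpos, frozen)) {
        for (base in DNA_BASES) {
          if (base == chars[pos]) next
          old <- chars[pos]
          chars[pos] <- base
          ok <- TRUE
          for (j in unlist(covering(pos))) {
            pmj <- pos_maps[[as.character(j)]]
            cj <- ceiling(match(pos, pmj) / 3)
            if (cj %in% interior_codons(lay$length[j]) &&
                isTRUE(is_stop_codon(codon_at(j, cj), code))) {
              ok <- FALSE
              break
            }
          }
          if (ok) { fixed <- TRUE; break }
          chars[pos] <- old
        }
        if (fixed) break
      }
      if (!fixed) {
        stop("cannot repair interior stop codon without touching planted codons",
             call. = FALSE)
      }
    }
  }
  if (length(bad_codons()) > 0L) {
    stop("interior stop repair did not converge", call. = FALSE)
  }
  chars
}

# Core repeat-planting on a character vector. Each planted pair consists of
# a copy at locus1 (existing content), a transformed copy at locus2 with
# exactly `mismatches` substitutions, and guard bases just outside both
# copies set to mismatch under the class transform so the planted match is
# maximal at exactly its planted length.
plant_repeats_chars <- function(chars, plan, region, base_probs) {
  lo <- region[1L]; hi <- region[2L]
  occupied <- integer()
  truth <- list()
  protected <- integer()
  other_base <- function(b) DNA_BASES[DNA_BASES != b][1L]

  for (r in seq_len(nrow(plan))) {
    len <- plan$length[r]; mm <- plan$mismatches[r]; kl <- plan$klass[r]
    loci <- integer(2L)
    for (copy in 1:2) {
      placed <- FALSE
      for (try in 1:200) {
        p <- sample(seq(lo + 1L, hi - len), 1L)
        span <- (p - 1L):(p + len)          # copy plus both guards
        if (!any(span %in% occupied)) {
          loci[copy] <- p
          occupied <- c(occupied, span)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("planning error: cannot place repeat without collision",
                        call. = FALSE)
    }
    p1 <- min(loci); p2 <- max(loci)
    c1 <- chars[p1:(p1 + len - 1L)]
    perfect <- switch(kl,
                      F = c1,
                      R = rev(c1),
                      C = unname(COMP_MAP[c1]),
                      P = rev(unname(COMP_MAP[c1])))
    c2 <- perfect
    if (mm > 0L) {
      at <- sample(len, mm)
      for (a in at) c2[a] <- other_base(perfect[a])
    }
    chars[p2:(p2 + len - 1L)] <- c2

    # guard bases: the diagonal columns just outside the planted window
    # must mismatch so the maximal window is exactly the planted copy pair
    if (kl %in% c("F", "C")) {
      tr <- if (kl == "C") function(b) unname(COMP_MAP[b]) else identity
      chars[p2 - 1L] <- other_base(tr(chars[p1 - 1L]))
      chars[p2 + len] <- other_base(tr(chars[p1 + len]))
    } else {
      tr <- if (kl == "P") function(b) unname(COMP_MAP[b]) else identity
      chars[p2 + len] <- other_base(tr(chars[p1 - 1L]))
      chars[p2 - 1L] <- other_base(tr(chars[p1 + len]))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      klass = kl, start1 = p1, start2 = p2, length = len, mismatches = mm,
      stringsAsFactors = FALSE)
    protected <- c(protected, (p1 - 1L):(p1 + len), (p2 - 1L):(p2 + len))
  }
  list(chars = chars, truth = do.call(rbind, truth),
       protected = sort(unique(protected)))
}

#' Plant dispersed repeats into a genome's control region
#'
#' Writes each planned repeat pair into non-colliding loci of the D-loop
#' with exactly the requested mismatch count under its class transform,
#' plus guard mismatches so each planted match is maximal at its planted
#' length.
#'
#' @param genome a [mito_genome()] with a control-region feature.
#' @param plan data.frame (klass, length, mismatches); empty plan returns
#'   the genome unchanged.
#' @param seed RNG seed for locus placement.
#' @return list with `genome` (modified) and `truth` (planted repeat table
#'   in [find_repeats()] coordinates) and `protected` positions.
#' @export
plant_repeats <- function(genome, plan, seed = 1L) {
  if (is.null(plan) || nrow(plan) == 0L) {
    return(list(genome = genome,
                truth = data.frame(klass = character(), start1 = integer(),
                                   start2 = integer(), length = integer(),
                                   mismatches = integer(),
                                   stringsAsFactors = FALSE),
                protected = integer()))
  }
  dl <- which(genome$features$type == "control_region")
  if (length(dl) == 0L) stop("no control-region feature to plant into",
                             call. = FALSE)
  f <- genome$features[dl[1L], ]
  stopifnot(f$end >= f$start)
  chars <- strsplit(genome$sequence, "")[[1L]]
  planted <- with_seed(seed, {
    plant_repeats_chars(chars, plan, region = c(f$start, f$end),
                        base_probs = NULL)
  })
  g2 <- mito_genome(genome$id, paste(planted$chars, collapse = ""),
                    genome$features, circular = genome$circular)
  list(genome = g2, truth = planted$truth, protected = planted$protected)
}

#' Evolve a divergent copy of a genome with planted substitution counts
#'
#' Introduces codon-level substitutions into each PCG, classified at
#' planting time as synonymous or nonsynonymous under the vertebrate
#' mitochondrial code. Rates are per-site proportions and the planted
#' counts are deterministic — `round(rate x sites)` per gene — with random
#' placement, so divergence ranks between genes are reproducible across
#' seeds; at most one substitution is planted per codon, never creating an
#' in-frame stop. Start and stop codons, codons shared with an overlapping
#' PCG, and `protect`ed positions are never touched. Non-coding positions
#' are mutated independently at a flat per-base rate.
#'
#' @param genome a [mito_genome()] with annotated PCGs.
#' @param divergence data.frame (gene, syn_rate, nonsyn_rate); see
#'   [default_divergence()].
#' @param seed RNG seed.
#' @param noncoding_rate flat per-base substitution probability outside
#'   PCGs (default 0.03).
#' @param protect integer genome positions never mutated (e.g. planted
#'   repeat loci and their guards).
#' @param id label for the evolved genome.
#' @return list with `genome` (the evolved copy) and `events` (per gene:
#'   planted synonymous and nonsynonymous substitution counts and the
#'   site totals used).
#' @export
evolve_pair <- function(genome, divergence = default_divergence(), seed = 1L,
                        noncoding_rate = 0.03, protect = integer(),
                        id = paste0(genome$id, "_evolved")) {
  code <- genetic_code(2L)
  tab <- codon_sites_table(code)
  f <- genome$features
  chars <- strsplit(genome$sequence, "")[[1L]]
  pcg_rows <- which(f$type == "PCG")
  pcg_span <- unique(unlist(lapply(pcg_rows, function(i) {
    feature_positions(f$start[i], f$end[i], genome$length)
  })))

  with_seed(seed, {
    events <- list()
    for (i in pcg_rows) {
      gene <- f$name[i]
      dv <- divergence[divergence$gene == gene, ]
      if (nrow(dv) == 0L) next
      len <- feature_lengths(f$start[i], f$end[i], genome$length)
      pm <- coding_positions(f$start[i], f$end[i], f$strand[i])
      ncod <- len %/% 3L
      cods <- vapply(seq_len(ncod), function(j) {
        paste(read_coding(chars, pm[(3L * j - 2L):(3L * j)], f$strand[i]),
              collapse = "")
      }, character(1L))
      sense <- which(!is.na(tab[cods, "s"]))  # non-stop codons
      S_gene <- sum(tab[cods[sense], "s"])
      N_gene <- sum(tab[cods[sense], "n"])

      other_span <- unique(unlist(lapply(setdiff(pcg_rows, i), function(j) {
        feature_positions(f$start[j], f$end[j], genome$length)
      })))
      cand <- intersect(interior_codons(len), sense)
      cand <- cand[vapply(cand, function(j) {
        p3 <- pm[(3L * j - 2L):(3L * j)]
        !any(p3 %in% other_span) && !any(p3 %in% protect)
      }, logical(1L))]

      n_syn <- as.integer(round(dv$syn_rate * S_gene))
      n_non <- as.integer(round(dv$nonsyn_rate * N_gene))
      picks <- plant_gene_substitutions(cods, cand, n_syn, n_non, code)
      for (p in picks) {
        j <- p$codon_idx
        p3 <- pm[(3L * j - 2L):(3L * j)]
        chars <- write_coding(chars, p3, f$strand[i],
                              strsplit(p$new_codon, "")[[1L]])
      }
      events[[length(events) + 1L]] <- data.frame(
        gene = gene, syn_planted = n_syn, nonsyn_planted = n_non,
        S = S_gene, N = N_gene, stringsAsFactors = FALSE)
    }

    nc <- setdiff(seq_len(genome$length), c(pcg_span, protect))
    hit <- nc[stats::runif(length(nc)) < noncoding_rate]
    for (pos in hit) {
      chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    }

    g2 <- mito_genome(id, paste(chars, collapse = ""), f,
                      circular = genome$circular)
    list(genome = g2, events = do.call(rbind, events))
  })
}

# Choose codons and single-nucleotide changes realizing the requested
# synonymous and nonsynonymous counts; at most one change per codon.
plant_gene_substitutions <- function(cods, candidates, n_syn, n_non, code) {
  options_for <- function(codon, want_syn) {
    aa <- translate_codons(codon, code)
    out <- list()
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        aa2 <- translate_codons(mut, code)
        if (aa2 == "*") next
        if (identical(aa2, aa) == want_syn) {
          out[[length(out) + 1L]] <- mut
        }
      }
    }
    out
  }
  picks <- list()
  avail <- candidates[sample.int(length(candidates))]  # seeded by caller
  take <- function(n, want_syn) {
    got <- 0L
    while (got < n && length(avail) > 0L) {
      j <- avail[1L]
      avail <<- avail[-1L]
      opts <- options_for(cods[j], want_syn)
      if (length(opts) == 0L) next
      picks[[length(picks) + 1L]] <<- list(
        codon_idx = j, new_codon = opts[[sample.int(length(opts), 1L)]])
      got <- got + 1L
    }
    if (got < n) {
      stop(sprintf("requested rate too high: only %d of %d %ssynonymous changes placeable",
                   got, n, if (want_syn) "" else "non"), call. = FALSE)
    }
  }
  take(n_syn, TRUE)
  take(n_non, FALSE)
  picks
}

#' Generate the three-variant synthetic trio
#'
#' Independently generated genomes under the CH/CL/CS layout variants —
#' the fixture trio whose printed summary arithmetic (PCG totals and
#' fractions, codon totals, overlap/spacer bookkeeping) the analysis
#' modules are checked against.
#'
#' @param seed integer seed (each variant uses `seed + 0,1,2`).
#' @return named list of `generate_genome()` results (`CH`, `CL`, `CS`).
#' @export
synthetic_trio <- function(seed = 1L) {
  out <- list()
  variants <- c("CH", "CL", "CS")
  for (k in seq_along(variants)) {
    out[[variants[k]]] <-
      generate_genome(synthetic_spec(variants[k], seed = seed + k - 1L))
  }
  out
}

#' Generate an evolved trio for selection-pressure recovery
#'
#' One ancestral genome plus two independently evolved copies under the
#' per-gene divergence rates — the planted-ground-truth input for Ka/Ks
#' rank recovery (ATP8 fastest, COX1/COX2 slowest under the defaults).
#'
#' @param seed integer seed.
#' @param divergence per-gene rates ([default_divergence()]).
#' @return named list of three [mito_genome()] objects (`A`, `B`, `C`)
#'   with attribute `events` (per-copy planted counts).
#' @export
evolved_trio <- function(seed = 1L, divergence = default_divergence()) {
  anc <- generate_genome(synthetic_spec("CH", seed = seed, id = "A"))
  prot <- anc$truth$protected_positions
  b <- evolve_pair(anc$genome, divergence, seed = seed + 1L,
                   protect = prot, id = "B")
  c_ <- evolve_pair(anc$genome, divergence, seed = seed + 2L,
                    protect = prot, id = "C")
  out <- list(A = anc$genome, B = b$genome, C = c_$genome)
  attr(out, "events") <- list(B = b$events, C = c_$events)
  out
}
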