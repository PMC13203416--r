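# Orderings in which the differing codon positions can be traversed when
# counting substitution pathways (1, 2 or 6 orderings for 1-3 differences).
path_orders <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the nine single-nucleotide changes of the codon, the change
#' is synonymous when it preserves the encoded amino acid; changes that
#' create a stop codon count as nonsynonymous. The synonymous site count is
#' the synonymous fraction at each position summed over the three
#' positions, so s + n = 3 for every codon.
#'
#' @param codon a 3-mer over A/C/G/T (not a stop codon).
#' @param code a [genetic_code()].
#' @return named numeric `c(s=, n=)`.
#' @export
ng86_sites <- function(codon, code = genetic_code(2L)) {
  codon <- toupper(codon)
  aa <- translate_codons(codon, code)
  if (is.na(aa)) stop("site error: codon with gap/N: ", codon, call. = FALSE)
  if (aa == "*") stop("site error: stop codon has no sites: ", codon,
                      call. = FALSE)
  s <- 0
  for (pos in 1:3) {
    from <- substr(codon, pos, pos)
    syn <- 0L
    for (b in setdiff(DNA_BASES, from)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (identical(translate_codons(mut, code), aa)) syn <- syn + 1L
    }
    s <- s + syn / 3
  }
  c(s = s, n = 3 - s)
}

# Cached 64-row site table for a code (stop codons NA).
codon_sites_table <- function(code) {
  key <- paste0("sites_", code$table_id)
  if (!is.null(.mitochar_cache[[key]])) return(.mitochar_cache[[key]])
  codons <- all_codons()
  aa <- translate_codons(codons, code)
  s <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (aa[i] != "*") s[i] <- ng86_sites(codons[i], code)[["s"]]
  }
  tab <- data.frame(codon = codons, aa = aa, s = s, n = 3 - s,
                    stringsAsFactors = FALSE)
  rownames(tab) <- codons
  .mitochar_cache[[key]] <- tab
  tab
}

.mitochar_cache <- new.env(parent = emptyenv())

#' Synonymous/nonsynonymous differences between two codons (NG86 pathways)
#'
#' Zero differences give (0,0); a single difference is classified directly;
#' with 2-3 differences the synonymous and nonsynonymous step counts are
#' averaged over all orderings of the changes (2 or 6 pathways). Pathways
#' passing through a stop codon are excluded and the average renormalized
#' over the remaining pathways; if every pathway is blocked the average
#' falls back to including them.
#'
#' @param codon1,codon2 3-mers over A/C/G/T, neither a stop codon.
#' @param code a [genetic_code()].
#' @return named numeric `c(sd=, nd=)` with `sd + nd` = number of
#'   differing positions.
#' @export
ng86_differences <- function(codon1, codon2, code = genetic_code(2L)) {
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  for (cd in c(codon1, codon2)) {
    aa <- translate_codons(cd, code)
    if (is.na(aa)) stop("skip signal: codon with gap/N: ", cd, call. = FALSE)
    if (aa == "*") stop("stop codon in ng86_differences: ", cd, call. = FALSE)
  }
  ng86_differences_compute(codon1, codon2, code)
}

# Uncached pathway computation behind ng86_differences().
ng86_differences_compute <- function(codon1, codon2, code) {
  b1 <- strsplit(codon1, "")[[1L]]
  b2 <- strsplit(codon2, "")[[1L]]
  diff_pos <- which(b1 != b2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))

  paths <- lapply(path_orders(k), function(ord) {
    cur <- b1
    sd <- 0L; nd <- 0L; blocked <- FALSE
    for (step in seq_len(k)) {
      pos <- diff_pos[ord[step]]
      nxt <- cur
      nxt[pos] <- b2[pos]
      aa_cur <- translate_codons(paste(cur, collapse = ""), code)
      aa_nxt <- translate_codons(paste(nxt, collapse = ""), code)
      if (aa_nxt == "*" && step < k) blocked <- TRUE
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  open <- !vapply(paths, `[[`, logical(1L), "blocked")
  use <- if (any(open)) paths[open] else paths
  sd <- mean(vapply(use, `[[`, integer(1L), "sd"))
  nd <- mean(vapply(use, `[[`, integer(1L), "nd"))
  c(sd = sd, nd = nd)
}

# Cached 64 x 64 pathway-difference tables (sd and nd) for a code; rows and
# columns indexed by all_codons() order, NA where either codon is a stop.
codon_diff_tables <- function(code) {
  key <- paste0("diffs_", code$table_id)
  if (!is.null(.mitochar_cache[[key]])) return(.mitochar_cache[[key]])
  codons <- all_codons()
  stops <- is_stop_codon(codons, code)
  sd <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  nd <- sd
  for (i in which(!stops)) {
    for (j in which(!stops)) {
      d <- ng86_differences_compute(codons[i], codons[j], code)
      sd[i, j] <- d[["sd"]]
      nd[i, j] <- d[["nd"]]
    }
  }
  .mitochar_cache[[key]] <- list(sd = sd, nd = nd)
  .mitochar_cache[[key]]
}

#' Jukes-Cantor distance correction
#' @param p proportion of sites differing (0 <= p < 3/4 for a finite value).
#' @return corrected distance `-(3/4) ln(1 - 4p/3)`, or NA when `p >= 3/4`.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' A pairwise codon alignment
#'
#' @param gene gene symbol.
#' @param seq1,seq2 equal-length codon-aligned nucleotide strings (gaps
#'   `-`, length a multiple of 3).
#' @param code a [genetic_code()].
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene, seq1, seq2, code = genetic_code(2L)) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3L == 0L)
  structure(list(gene = gene, seq1 = toupper(seq1), seq2 = toupper(seq2),
                 code = code),
            class = "codon_alignment")
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, seq(1L, by = 3L, length.out = n),
            seq(3L, by = 3L, length.out = n))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and pathway-averaged differences codon by codon, converts the
#' proportions ps = Sd/S and pn = Nd/N to rates with the Jukes-Cantor
#' correction, and reports omega = Ka/Ks. Codon columns containing a gap or
#' N in either sequence are dropped from both; the ratio is flagged
#' undefined when Ks = 0 or a correction is inapplicable (p >= 3/4).
#'
#' @param aln a [codon_alignment()] with at least 10 comparable codons.
#' @return list of class `kaks_result`: gene, n_codons, S, N, Sd, Nd, ps,
#'   pn, Ks, Ka, ratio, flag ("" when the ratio is defined).
#' @export
ng86_kaks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- aln$code
  c1 <- split_codons(aln$seq1)
  c2 <- split_codons(aln$seq2)
  usable <- !grepl("[-N]", c1) & !grepl("[-N]", c2)
  c1 <- c1[usable]; c2 <- c2[usable]
  stops <- is_stop_codon(c1, code) | is_stop_codon(c2, code)
  if (any(stops)) {
    warning(sum(stops), " stop-containing codon column(s) dropped")
    c1 <- c1[!stops]; c2 <- c2[!stops]
  }
  n_codons <- length(c1)
  if (n_codons < 10L) {
    stop(sprintf("too few comparable codons: %d (need >= 10)", n_codons),
         call. = FALSE)
  }
  tab <- codon_sites_table(code)
  S <- (sum(tab[c1, "s"]) + sum(tab[c2, "s"])) / 2
  N <- 3 * n_codons - S
  d <- which(c1 != c2)
  dt <- codon_diff_tables(code)
  Sd <- sum(dt$sd[cbind(c1[d], c2[d])])
  Nd <- sum(dt$nd[cbind(c1[d], c2[d])])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  flag <- ""
  ratio <- NA_real_
  if (is.na(Ks) || is.na(Ka)) {
    flag <- "correction inapplicable (p >= 3/4)"
  } else if (Ks == 0) {
    flag <- "Ks = 0: ratio undefined"
  } else {
    ratio <- Ka / Ks
  }
  structure(list(gene = aln$gene, n_codons = n_codons, S = S, N = N,
                 Sd = Sd, Nd = Nd, ps = ps, pn = pn, Ks = Ks, Ka = Ka,
                 ratio = ratio, flag = flag),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %s: Ka=%.4f Ks=%.4f Ka/Ks=%s (%d codons)%s\n",
              x$gene, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio),
              x$n_codons,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

# Strip the trailing partial codon (incomplete stop) and a terminal stop
# codon from a coding sequence, leaving sense codons only.
strip_terminal_stop <- function(seq, code) {
  n <- nchar(seq)
  seq <- substr(seq, 1L, n - (n %% 3L))
  n <- nchar(seq)
  if (n >= 3L) {
    last <- substr(seq, n - 2L, n)
    if (!grepl("[-N]", last) && isTRUE(is_stop_codon(last, code))) {
      seq <- substr(seq, 1L, n - 3L)
    }
  }
  seq
}

#' Protein-guided pairwise codon alignment
#'
#' Strips trailing partial codons and terminal stops, translates both
#' sequences, aligns the proteins with an affine-gap global alignment
#' (BLOSUM62, gap open 10, extend 0.5; internal stops scored as X), and
#' back-maps the protein alignment to codons.
#'
#' @param gene gene symbol for the result.
#' @param nt1,nt2 coding-sense nucleotide sequences.
#' @param code a [genetic_code()].
#' @return a [codon_alignment()].
#' @export
align_codon_pair <- function(gene, nt1, nt2, code = genetic_code(2L)) {
  nt1 <- strip_terminal_stop(toupper(nt1), code)
  nt2 <- strip_terminal_stop(toupper(nt2), code)
  p1 <- protein_string(nt1, code)
  p2 <- protein_string(nt2, code)
  if (is.null(.mitochar_cache$blosum62)) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    .mitochar_cache$blosum62 <- data_env$BLOSUM62
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = .mitochar_cache$blosum62,
    gapOpening = 10, gapExtension = 0.5, type = "global")
  a1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  cods1 <- split_codons(nt1)
  cods2 <- split_codons(nt2)
  i1 <- 0L; i2 <- 0L
  out1 <- character(length(a1)); out2 <- character(length(a2))
  for (j in seq_along(a1)) {
    if (a1[j] == "-") out1[j] <- "---" else {
      i1 <- i1 + 1L; out1[j] <- cods1[i1]
    }
    if (a2[j] == "-") out2[j] <- "---" else {
      i2 <- i2 + 1L; out2[j] <- cods2[i2]
    }
  }
  codon_alignment(gene, paste(out1, collapse = ""),
                  paste(out2, collapse = ""), code)
}

# Translate a coding sequence to a protein string; codons with N become X,
# internal stops become X (flagged by a warning) so alignment can proceed.
protein_string <- function(nt, code) {
  cods <- split_codons(nt)
  aa <- translate_codons(cods, code)
  aa[is.na(aa)] <- "X"
  if (any(aa == "*")) {
    warning(sum(aa == "*"), " internal stop codon(s) translated as X")
    aa[aa == "*"] <- "X"
  }
  paste(aa, collapse = "")
}

#' Batched pairwise Ka/Ks over genomes and genes
#'
#' For every gene present in all genomes, builds protein-guided codon
#' alignments for every unordered genome pair and computes NG86 Ka/Ks;
#' genes missing from any genome are skipped with a warning.
#'
#' @param genomes named list of [mito_genome()] objects (>= 2).
#' @param genes gene symbols (default the 13 canonical PCGs).
#' @param code a [genetic_code()].
#' @return list with `results` (one row per gene x pair: gene, genome1,
#'   genome2, n_codons, S, N, Sd, Nd, Ka, Ks, ratio, flag) and `summary`
#'   (per-gene min/median/max of the defined ratios).
#' @export
pairwise_kaks_table <- function(genomes, genes = canonical_pcgs(),
                                code = genetic_code(2L)) {
  stopifnot(length(genomes) >= 2L)
  ids <- names(genomes)
  if (is.null(ids)) {
    ids <- vapply(genomes, `[[`, character(1L), "id")
    names(genomes) <- ids
  }
  pairs <- utils::combn(ids, 2L)
  rows <- list()
  for (gene in genes) {
    present <- vapply(genomes, function(g) gene %in% g$features$name,
                      logical(1L))
    if (!all(present)) {
      warning(sprintf("gene %s missing in %s: skipped", gene,
                      paste(ids[!present], collapse = ", ")))
      next
    }
    seqs <- lapply(genomes, extract_gene_sequence, feature = gene)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      aln <- align_codon_pair(gene, seqs[[g1]], seqs[[g2]], code)
      res <- ng86_kaks(aln)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, genome1 = g1, genome2 = g2, n_codons = res$n_codons,
        S = res$S, N = res$N, Sd = res$Sd, Nd = res$Nd,
        Ka = res$Ka, Ks = res$Ks, ratio = res$ratio, flag = res$flag,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- NULL
  if (!is.null(results)) {
    summary <- do.call(rbind, lapply(split(results, results$gene), function(d) {
      r <- d$ratio[!is.na(d$ratio)]
      data.frame(gene = d$gene[1L], n_pairs = nrow(d),
                 min_ratio = if (length(r)) min(r) else NA_real_,
                 median_ratio = if (length(r)) median(r) else NA_real_,
                 max_ratio = if (length(r)) max(r) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    summary <- summary[match(intersect(genes, summary$gene), summary$gene), ,
                       drop = FALSE]
    rownames(summary) <- NULL
  }
  list(results = results, summary = summary)
}
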