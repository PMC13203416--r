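# Exact match runs (maximal, >= min_len) between two encoded sequences
# along shared-kmer diagonals. Returns p (ref start), q (target start), len.
exact_diagonal_runs <- function(sv, tv, min_len) {
  n <- length(sv); m <- length(tv)
  k <- min(12L, min_len)
  diags <- shared_kmer_diagonals(sv, tv, k)
  if (length(diags) == 0L) {
    return(data.frame(p = integer(), q = integer(), len = integer()))
  }
  out <- list()
  for (d in diags) {
    p0 <- max(1L, 1L - d)
    p1 <- min(n, m - d)
    if (p1 - p0 + 1L < min_len) next
    idx <- p0:p1
    eq <- sv[idx] == tv[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    if (length(hit) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      p = p0 + starts[hit] - 1L, q = p0 + starts[hit] - 1L + d,
      len = r$lengths[hit])
  }
  if (length(out) == 0L) {
    return(data.frame(p = integer(), q = integer(), len = integer()))
  }
  # each diagonal is scanned once, so runs cannot repeat
  do.call(rbind, out)
}

#' Maximal exact matches between two sequences
#'
#' All maximal exact matches of at least `min_len` bp between `ref` and
#' `qry` (forward orientation) and between `ref` and the reverse complement
#' of `qry` (reverse orientation). Matches are maximal per diagonal: they
#' cannot be extended with equality in either direction. Anchors are the
#' raw material for an assembly-verification dotplot.
#'
#' @param ref,qry nucleotide strings (nonempty).
#' @param min_len minimum anchor length (default 20; below 12 a warning is
#'   issued because short anchors flood a dotplot).
#' @param unique_only drop anchors whose ref or qry span overlaps another
#'   anchor's span in the same orientation (a simple uniqueness filter).
#' @return data.frame (ref_start, ref_end, qry_start, qry_end, length,
#'   orientation) sorted by ref_start; qry coordinates are on the original
#'   query strand with `qry_start <= qry_end`.
#' @export
maximal_exact_matches <- function(ref, qry, min_len = 20L,
                                  unique_only = FALSE) {
  ref <- validate_dna(ref, "ref")
  qry <- validate_dna(qry, "qry")
  stopifnot(nchar(ref) > 0L, nchar(qry) > 0L)
  if (min_len < 12L) warning("min_len < 12 may flood the anchor table")
  sv <- dna_ints(ref, n_code = 5L)
  m <- nchar(qry)

  fwd <- exact_diagonal_runs(sv, dna_ints(qry, n_code = 6L), min_len)
  fwd <- if (nrow(fwd)) data.frame(
    ref_start = fwd$p, ref_end = fwd$p + fwd$len - 1L,
    qry_start = fwd$q, qry_end = fwd$q + fwd$len - 1L,
    length = fwd$len, orientation = "forward", stringsAsFactors = FALSE)
  else NULL

  rev <- exact_diagonal_runs(sv, dna_ints(revcomp(qry), n_code = 6L), min_len)
  rev <- if (nrow(rev)) data.frame(
    ref_start = rev$p, ref_end = rev$p + rev$len - 1L,
    qry_start = m - (rev$q + rev$len - 1L) + 1L, qry_end = m - rev$q + 1L,
    length = rev$len, orientation = "reverse", stringsAsFactors = FALSE)
  else NULL

  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  }
  if (unique_only && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      other <- seq_len(nrow(out)) != i & out$orientation == out$orientation[i]
      clash <- other & (
        (out$ref_start <= out$ref_end[i] & out$ref_end >= out$ref_start[i]) |
        (out$qry_start <= out$qry_end[i] & out$qry_end >= out$qry_start[i]))
      if (any(clash)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$ref_start, out$qry_start, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dotplot table and reference coverage from anchors
#'
#' @param anchors output of [maximal_exact_matches()].
#' @param ref_len length of the reference sequence.
#' @return list with `table` (one row per anchor, both coordinate spans)
#'   and `coverage` (fraction of ref positions inside >= 1 anchor).
#' @export
dotplot_table <- function(anchors, ref_len) {
  coverage <- 0
  if (nrow(anchors) > 0L) {
    covered <- logical(ref_len)
    for (i in seq_len(nrow(anchors))) {
      covered[anchors$ref_start[i]:anchors$ref_end[i]] <- TRUE
    }
    coverage <- mean(covered)
  }
  list(table = anchors, coverage = coverage)
}

#' Best-rotation search for circular queries
#'
#' Circular genomes deposited with different numbering origins produce
#' broken dotplots; this finds the query rotation maximizing the single
#' longest anchor against the reference, via matching on the doubled query
#' string.
#'
#' @param ref,qry nucleotide strings; `qry` is treated as circular.
#' @param min_len minimum anchor length.
#' @return list with `rotation` (0-based offset applied to `qry`) and
#'   `qry_rotated` (the rotated query string).
#' @export
best_rotation <- function(ref, qry, min_len = 20L) {
  m <- nchar(qry)
  doubled <- paste0(qry, qry)
  runs <- exact_diagonal_runs(dna_ints(ref, n_code = 5L),
                              dna_ints(doubled, n_code = 6L), min_len)
  if (nrow(runs) == 0L) {
    return(list(rotation = 0L, qry_rotated = qry))
  }
  best <- runs[which.max(runs$len), ]
  rot <- (best$q - best$p) %% m
  rotated <- if (rot == 0L) qry else {
    paste0(substr(qry, rot + 1L, m), substr(qry, 1L, rot))
  }
  list(rotation = as.integer(rot), qry_rotated = rotated)
}
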