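REPEAT_CLASSES <- c("F", "P", "C", "R")

# Target string for a repeat class: a repeat of class K is a local
# Hamming match between the sequence S and K(S).
#   F: K = identity        (direct copy)
#   R: K = reverse         (reversed copy)
#   C: K = complement      (base-complemented copy)
#   P: K = revcomp         (palindrome / inverted repeat)
class_target <- function(seq, klass) {
  switch(klass,
         F = seq,
         R = dna_reverse(seq),
         C = dna_complement(seq),
         P = revcomp(seq),
         stop("unknown repeat class: ", klass, call. = FALSE))
}

# Does the class transform reverse coordinate order in the target?
class_reverses <- function(klass) klass %in% c("R", "P")

# Map a match (p, q, len) in S-vs-target diagonal space back to the two
# copy intervals in S coordinates, and canonicalize so start1 <= start2.
canonical_match <- function(klass, p, q, len, mm, n) {
  a_start <- p
  if (class_reverses(klass)) {
    b_start <- n - (q + len - 1L) + 1L
  } else {
    b_start <- q
  }
  s1 <- pmin(a_start, b_start)
  s2 <- pmax(a_start, b_start)
  data.frame(klass = klass, start1 = s1, start2 = s2, length = len,
             mismatches = mm, end1 = s1 + len - 1L, end2 = s2 + len - 1L,
             stringsAsFactors = FALSE)
}

# Drop matches whose two copy intervals are both sub-intervals of another
# match's copy intervals (same class). Only strictly longer matches can
# contain, and containment is transitive, so each match is checked against
# the strictly-longer prefix of the length-sorted table. Exact duplicates
# are removed first.
# Integer-keyed row dedupe on (start1, start2, length): within one class
# these determine the match (and its mismatch count) completely. Avoids
# the string materialization of unique.data.frame on large match sets.
dedupe_matches <- function(df) {
  if (nrow(df) < 2L) return(df)
  d <- df[order(df$start1, df$start2, df$length), , drop = FALSE]
  n <- nrow(d)
  dup <- c(FALSE, d$start1[-1L] == d$start1[-n] &
             d$start2[-1L] == d$start2[-n] & d$length[-1L] == d$length[-n])
  d[!dup, , drop = FALSE]
}

suppress_contained <- function(df) {
  if (nrow(df) < 2L) return(df)
  k <- nrow(df)
  d <- df[order(df$start1, df$start2, df$length), , drop = FALSE]
  s1 <- d$start1; e1 <- d$end1; s2 <- d$start2; e2 <- d$end2
  len <- d$length
  # a container j must be strictly longer and start at most
  # (max length - length_i) positions before start1_i, with s1_j <= s1_i:
  # expand only those candidate pairs (s1 is sorted)
  lmax <- max(len)
  lo <- findInterval(s1 - (lmax - len) - 0.5, s1) + 1L
  hi <- findInterval(s1 + 0.5, s1)
  counts <- hi - lo + 1L
  keep <- rep(TRUE, k)
  # expand candidate pairs in bounded chunks (dense match sets would
  # otherwise materialize hundreds of millions of pairs at once)
  chunk <- max(1L, as.integer(2e6 / max(1L, ceiling(mean(counts)))))
  for (from in seq(1L, k, by = chunk)) {
    to <- min(k, from + chunk - 1L)
    rows <- from:to
    ii <- rep.int(rows, counts[rows])
    jj <- sequence(counts[rows], from = lo[rows])
    bad <- len[jj] > len[ii] & s1[jj] <= s1[ii] & e1[jj] >= e1[ii] &
      s2[jj] <= s2[ii] & e2[jj] >= e2[ii]
    keep[unique(ii[bad])] <- FALSE
  }
  d[keep, , drop = FALSE]
}

sort_matches <- function(df) {
  df <- df[order(df$klass, df$start1, df$start2, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_matches <- function() {
  data.frame(klass = character(), start1 = integer(), start2 = integer(),
             length = integer(), mismatches = integer(), end1 = integer(),
             end2 = integer(), stringsAsFactors = FALSE)
}

# Diagonals to scan for a class. Non-reversing transforms (F, C) are
# symmetric under swapping the two copies within a diagonal pair (d, -d),
# so only d > 0 is enumerated (d = 0 is the trivial self-diagonal for F and
# can hold no match for C). Reversing transforms (R, P) pair matches within
# a single diagonal, so every diagonal is scanned and duplicates removed
# after canonicalization.
class_diagonals <- function(klass, n) {
  if (class_reverses(klass)) (1L - n):(n - 1L) else seq_len(n - 1L)
}

# Mismatch indicator along diagonal d: columns i pair S[p0+i-1] with
# target[p0+d+i-1].
diag_mismatch <- function(sv, tv, d, n) {
  p0 <- max(1L, 1L - d)
  p1 <- min(n, n - d)
  if (p0 > p1) return(NULL)
  idx <- p0:p1
  list(p0 = p0, mm = sv[idx] != tv[idx + d])
}

# All maximal Hamming windows (<= max_mm mismatches, not extendable) along
# a mismatch indicator, via the sentinel formula: with mismatch positions
# x_1 < ... < x_k and sentinels x_0 = 0, x_{k+1} = D+1, the maximal windows
# are [x_j + 1, x_{j+max_mm+1} - 1] for j = 0..k-max_mm (or the whole
# diagonal when k <= max_mm).
windows_sentinel <- function(mm, max_mm) {
  D <- length(mm)
  x <- which(mm)
  k <- length(x)
  if (k <= max_mm) {
    return(data.frame(start = 1L, end = D, mm = k))
  }
  xs <- c(0L, x, D + 1L)
  j <- 0:(k - max_mm)
  data.frame(start = xs[j + 1L] + 1L, end = xs[j + max_mm + 2L] - 1L,
             mm = max_mm)
}

# Independent derivation used by the oracle: for every start column,
# extend right as far as the mismatch budget allows (cumulative-sum
# search), then keep the windows that are also left-maximal.
windows_by_extension <- function(mm, max_mm) {
  D <- length(mm)
  cs <- c(0L, cumsum(as.integer(mm)))
  s <- seq_len(D)
  e <- findInterval(cs[s] + max_mm, cs) - 1L
  left_max <- s == 1L | (cs[e + 1L] - cs[pmax(s - 1L, 1L)]) > max_mm
  # each maximal window is found exactly once (unique left-maximal start)
  res <- data.frame(start = s[left_max], end = e[left_max])
  res$mm <- cs[res$end + 1L] - cs[res$start]
  res
}

scan_class <- function(seq, klass, min_len, max_mm, diags, window_fun) {
  n <- nchar(seq)
  sv <- dna_ints(seq, n_code = 5L)
  tv <- dna_ints(class_target(seq, klass), n_code = 6L)  # N never matches
  ps <- list(); qs <- list(); lens <- list(); mms <- list()
  for (d in diags) {
    dg <- diag_mismatch(sv, tv, d, n)
    if (is.null(dg) || length(dg$mm) < min_len) next
    w <- window_fun(dg$mm, max_mm)
    ok <- w$end - w$start + 1L >= min_len
    if (!any(ok)) next
    i <- length(ps) + 1L
    ps[[i]] <- dg$p0 + w$start[ok] - 1L
    qs[[i]] <- ps[[i]] + d
    lens[[i]] <- w$end[ok] - w$start[ok] + 1L
    mms[[i]] <- w$mm[ok]
  }
  if (length(ps) == 0L) return(empty_matches())
  cand <- canonical_match(klass, unlist(ps), unlist(qs), unlist(lens),
                          unlist(mms), n)
  if (klass == "F") cand <- cand[cand$start1 != cand$start2, , drop = FALSE]
  suppress_contained(dedupe_matches(cand))
}

#' Find dispersed repeats in four classes
#'
#' Detects all maximal repeat matches of classes Forward, Palindrome,
#' Complementary and Reverse with a minimum length and a substitution-only
#' (Hamming) mismatch tolerance. A match is maximal when extending it one
#' bp in either direction would exceed `max_mismatch` or run off the
#' sequence; matches whose two copies are sub-intervals of another match's
#' copies (same class) are suppressed. The search runs on the linear
#' H-strand string (no origin wrap), matching standard repeat-finder
#' behavior on deposited sequences.
#'
#' The finder seeds candidate diagonals with shared exact k-mers
#' (k chosen by the pigeonhole bound so no qualifying match can be missed)
#' and scans only those diagonals; [oracle_find_repeats()] is the
#' brute-force reference it is tested against.
#'
#' @param seq nucleotide string (length >= `min_len`).
#' @param min_len minimum repeat length in bp (>= 8; default 20).
#' @param max_mismatch maximum substitutions tolerated (default 3).
#' @param classes repeat classes to search (default all four).
#' @return data.frame (klass, start1, start2, length, mismatches, end1,
#'   end2) sorted by (klass, start1, start2); positions are 1-based starts
#'   of the two copies on the input strand.
#' @export
find_repeats <- function(seq, min_len = 20L, max_mismatch = 3L,
                         classes = REPEAT_CLASSES) {
  seq <- validate_dna(seq, context = "find_repeats")
  min_len <- as.integer(min_len)
  max_mismatch <- as.integer(max_mismatch)
  if (min_len < 8L) stop("min_len must be >= 8 (seed-explosion guard)",
                         call. = FALSE)
  n <- nchar(seq)
  if (min_len > n) {
    warning("min_len exceeds sequence length: no repeats reportable")
    return(empty_matches())
  }
  k <- min(15L, max(1L, (min_len - max_mismatch) %/% (max_mismatch + 1L)))
  out <- lapply(classes, function(kl) {
    diags <- seed_diagonals(seq, kl, k)
    scan_class(seq, kl, min_len, max_mismatch, diags, windows_sentinel)
  })
  sort_matches(do.call(rbind, out))
}

# Candidate diagonals for a class from shared exact k-mers between the
# sequence and its class target. Any Hamming match of length >= min_len
# with <= max_mismatch substitutions contains an exact run of length
# >= (min_len - max_mismatch)/(max_mismatch + 1), so seeding with k-mers of
# that length cannot miss a qualifying diagonal. k = 1 degenerates to all
# diagonals.
seed_diagonals <- function(seq, klass, k) {
  n <- nchar(seq)
  all_d <- class_diagonals(klass, n)
  if (k <= 1L || n <= k) return(all_d)
  sv <- dna_ints(seq, n_code = 5L)
  tv <- dna_ints(class_target(seq, klass), n_code = 6L)
  intersect(shared_kmer_diagonals(sv, tv, k), all_d)
}

# All diagonals q - p over position pairs (p in sv, q in tv) sharing an
# exact k-mer, via a vectorized code-group cross join.
shared_kmer_diagonals <- function(sv, tv, k) {
  cs <- kmer_codes(sv, k)
  ct <- kmer_codes(tv, k)
  pos_s <- which(cs$ok); code_s <- cs$code[cs$ok]
  pos_t <- which(ct$ok); code_t <- ct$code[ct$ok]
  common <- intersect(unique(code_s), unique(code_t))
  if (length(common) == 0L) return(integer())
  ls <- split(pos_s[code_s %in% common],
              factor(code_s[code_s %in% common], levels = common))
  lt <- split(pos_t[code_t %in% common],
              factor(code_t[code_t %in% common], levels = common))
  ns <- lengths(ls); nt <- lengths(lt)
  q <- unlist(rep(lt, ns), use.names = FALSE)
  p <- rep(unlist(ls, use.names = FALSE), times = rep(nt, ns))
  sort(unique(q - p))
}

# Rolling k-mer integer codes (base-4); positions containing N are marked
# not-ok. k is capped so codes stay within integer range.
kmer_codes <- function(v, k) {
  n <- length(v)
  stopifnot(k >= 1L, k <= 15L)
  npos <- n - k + 1L
  code <- integer(npos)
  ok <- rep(TRUE, npos)
  for (i in seq_len(k)) {
    b <- v[i:(i + npos - 1L)]
    ok <- ok & b <= 4L
    code <- code * 4L + (pmin(b, 4L) - 1L)
  }
  list(code = code, ok = ok)
}

#' Brute-force repeat-detection oracle
#'
#' Exhaustively scans every diagonal of the sequence-vs-transform
#' comparison, extending from every start column to its maximal window,
#' and applies the same canonicalization, maximality and containment rules
#' as [find_repeats()]. Quadratic: refused above 2000 bp.
#'
#' @inheritParams find_repeats
#' @return same shape as [find_repeats()].
#' @export
oracle_find_repeats <- function(seq, min_len = 20L, max_mismatch = 3L,
                                classes = REPEAT_CLASSES) {
  seq <- validate_dna(seq, context = "oracle_find_repeats")
  n <- nchar(seq)
  if (n > 2000L) stop("oracle refuses sequences above 2000 bp", call. = FALSE)
  min_len <- as.integer(min_len)
  max_mismatch <- as.integer(max_mismatch)
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  if (min_len > n) {
    warning("min_len exceeds sequence length: no repeats reportable")
    return(empty_matches())
  }
  out <- lapply(classes, function(kl) {
    scan_class(seq, kl, min_len, max_mismatch, class_diagonals(kl, n),
               windows_by_extension)
  })
  sort_matches(do.call(rbind, out))
}

#' Repeat length histogram per class
#'
#' @param matches output of [find_repeats()].
#' @return data.frame (klass, length, count), sorted.
#' @export
repeat_length_histogram <- function(matches) {
  if (nrow(matches) == 0L) {
    return(data.frame(klass = character(), length = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(count = rep(1L, nrow(matches))),
                   by = list(klass = matches$klass, length = matches$length),
                   FUN = sum)
  agg <- agg[order(agg$klass, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Recompute the mismatch count of a reported match
#'
#' Re-extracts the two copies of a match and compares them under the class
#' transform; used to verify that every reported match has exactly its
#' reported Hamming distance.
#'
#' @param seq the searched sequence.
#' @param match one row of a [find_repeats()] result.
#' @return integer mismatch count.
#' @export
verify_match_mismatches <- function(seq, match) {
  c1 <- substr(seq, match$start1, match$start1 + match$length - 1L)
  c2 <- substr(seq, match$start2, match$start2 + match$length - 1L)
  expected <- switch(match$klass,
                     F = c1, R = dna_reverse(c1), C = dna_complement(c1),
                     P = revcomp(c1))
  sum(strsplit(c2, "")[[1L]] != strsplit(expected, "")[[1L]])
}
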