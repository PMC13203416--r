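#' @keywords internal
"_PACKAGE"

#' @importFrom stats median setNames aggregate ave
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Validate a nucleotide string
#'
#' Checks that a sequence contains only A, C, G, T or N (case-insensitive).
#' Any other character — including IUPAC ambiguity codes other than N — is
#' rejected, because every downstream statistic (composition, codon usage,
#' repeat matching) is defined only on the four bases plus N.
#'
#' @param seq single character string.
#' @param context label used in error messages.
#' @return the validated sequence, upper-cased, invisibly usable.
#' @export
validate_dna <- function(seq, context = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(DNA_BASES, "N"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: disallowed character '%s' at position %d",
                 context, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param seq character string over A/C/G/T/N (case-insensitive).
#' @return reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  dna_reverse(dna_complement(seq))
}

#' Complement (no reversal) of a DNA string
#' @param seq DNA string.
#' @return complemented string.
#' @export
dna_complement <- function(seq) {
  chartr("ACGTNacgtn", "TGCANTGCAN", seq)
}

#' Reverse (no complement) of a DNA string
#' @param seq DNA string.
#' @return reversed string.
#' @export
dna_reverse <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Integer encoding A=1 C=2 G=3 T=4, N=5. `n_code` lets callers force N on one
# side of a comparison to a value that can never match the other side.
dna_ints <- function(seq, n_code = 5L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  v <- match(chars, DNA_BASES)
  v[is.na(v)] <- n_code
  v
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Sample a random DNA string from per-base probabilities.
random_dna <- function(n, base_probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
        collapse = "")
}
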