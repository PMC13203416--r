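#' Genetic code table
#'
#' Builds a genetic-code object from an NCBI translation-table id. Table 2,
#' the vertebrate mitochondrial code, is the default used throughout: it
#' maps AGA and AGG to STOP, ATA to Met and TGA to Trp, which is what makes
#' mitochondrial codon bookkeeping (Met/Trp two-codon families, a four-codon
#' stop set) differ from the standard code.
#'
#' @param table_id integer NCBI translation table id (default 2).
#' @return object of class `genetic_code`: list with `table_id` and
#'   `codon_to_aa`, a 64-entry named character vector (stop = `"*"`).
#' @export
genetic_code <- function(table_id = 2L) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- sort(names(tab))
  map <- unname(tab[codons])
  names(map) <- codons
  stopifnot(length(map) == 64L, !anyNA(map))
  structure(list(table_id = as.integer(table_id), codon_to_aa = map),
            class = "genetic_code")
}

#' All 64 codons in lexicographic order
#' @return character vector of 64 codons.
#' @export
all_codons <- function() {
  grid <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$p1, grid$p2, grid$p3))
}

#' Translate codons
#' @param codons character vector of 3-mers over A/C/G/T.
#' @param code a [genetic_code()] object.
#' @return amino acids (one-letter, `"*"` for stop); NA for codons with
#'   N/gaps.
#' @export
translate_codons <- function(codons, code = genetic_code(2L)) {
  unname(code$codon_to_aa[codons])
}

#' Is a codon a stop codon?
#' @inheritParams translate_codons
#' @return logical vector (NA for unrecognized codons).
#' @export
is_stop_codon <- function(codons, code = genetic_code(2L)) {
  translate_codons(codons, code) == "*"
}

#' @export
print.genetic_code <- function(x, ...) {
  stops <- names(x$codon_to_aa)[x$codon_to_aa == "*"]
  cat(sprintf("<genetic_code> table %d; stop codons: %s\n",
              x$table_id, paste(stops, collapse = ", ")))
  invisible(x)
}
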