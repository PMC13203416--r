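FEATURE_TYPES <- c("PCG", "tRNA", "rRNA", "control_region")

#' The 13 canonical vertebrate mitochondrial protein-coding genes
#' @return character vector of gene symbols in canonical order (ND1..CYTB).
#' @export
canonical_pcgs <- function() {
  c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
    "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")
}

#' Normalize strand labels to H/L
#'
#' External feature tables use several strand dialects; all are mapped onto
#' the mitochondrial H (annotated top strand) / L (complement) vocabulary:
#' `H`, `+`, `1`, `plus` become `H`; `L`, `-`, `−` (minus sign), `-1`,
#' `minus` become `L`.
#'
#' @param strand character vector of strand labels.
#' @return character vector over {"H","L"}.
#' @export
normalize_strand <- function(strand) {
  s <- trimws(as.character(strand))
  out <- ifelse(s %in% c("H", "h", "+", "1", "plus"), "H",
         ifelse(s %in% c("L", "l", "-", "−", "-1", "minus"), "L", NA))
  if (anyNA(out)) {
    stop("unrecognized strand label(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Build a gene feature table
#'
#' Coordinates are 1-based inclusive throughout the package (GenBank
#' convention). An origin-spanning feature on a circular genome is encoded
#' with `end < start`.
#'
#' @param name gene symbols.
#' @param type one of `PCG`, `tRNA`, `rRNA`, `control_region` (recycled).
#' @param start,end 1-based inclusive coordinates.
#' @param strand strand labels, normalized via [normalize_strand()].
#' @return data.frame with columns name, type, start, end, strand.
#' @export
gene_features <- function(name, type, start, end, strand) {
  df <- data.frame(name = as.character(name), type = as.character(type),
                   start = as.integer(start), end = as.integer(end),
                   strand = normalize_strand(strand),
                   stringsAsFactors = FALSE)
  bad <- !df$type %in% FEATURE_TYPES
  if (any(bad)) {
    stop("unknown feature type(s): ", paste(unique(df$type[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$start < 1L) || any(df$end < 1L)) {
    stop("feature coordinates must be >= 1", call. = FALSE)
  }
  df
}

#' Construct an annotated mitochondrial genome
#'
#' @param id text label.
#' @param sequence nucleotide string over A/C/G/T/N (H-strand orientation).
#' @param features a [gene_features()] data.frame (may be empty).
#' @param circular logical; origin-spanning features (`end < start`) are
#'   valid only on circular genomes.
#' @return object of class `mito_genome` with fields `id`, `sequence`,
#'   `length`, `circular`, `features` (sorted by start).
#' @export
mito_genome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- validate_dna(sequence, context = paste0("genome '", id, "'"))
  if (nchar(sequence) == 0L) stop("genome length must be > 0", call. = FALSE)
  if (is.null(features)) {
    features <- gene_features(character(), character(), integer(), integer(),
                              character())
  }
  g <- structure(list(id = as.character(id), sequence = sequence,
                      length = nchar(sequence), circular = isTRUE(circular),
                      features = features),
                 class = "mito_genome")
  validate_mito_genome(g)
}

#' Validate a mito_genome object
#' @param genome a `mito_genome`.
#' @return the genome (features re-sorted by start), or an error.
#' @export
validate_mito_genome <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  f <- genome$features
  L <- genome$length
  if (nrow(f) > 0L) {
    if (any(f$start > L) || any(f$end > L)) {
      stop(sprintf("genome '%s': feature beyond sequence end (length %d)",
                   genome$id, L), call. = FALSE)
    }
    wraps <- f$end < f$start
    if (any(wraps) && !genome$circular) {
      stop(sprintf("genome '%s': origin-spanning feature '%s' on a linear genome",
                   genome$id, f$name[which(wraps)[1L]]), call. = FALSE)
    }
    genome$features <- f[order(f$start, f$end), , drop = FALSE]
    rownames(genome$features) <- NULL
  }
  genome
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s, %d features\n", x$id, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0L) {
    tab <- table(x$features$type)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Feature length in bp, wrap-aware
#'
#' For a feature with `end >= start` the length is `end - start + 1`; an
#' origin-spanning feature (`end < start`) on a circular genome of length L
#' has length `(L - start + 1) + end`.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param genome_length total genome length.
#' @return integer lengths.
#' @export
feature_lengths <- function(start, end, genome_length) {
  ifelse(end >= start, end - start + 1L, (genome_length - start + 1L) + end)
}

# Genome positions covered by a feature, in H-strand order (wrap-aware).
feature_positions <- function(start, end, genome_length) {
  if (end >= start) start:end else c(start:genome_length, 1:end)
}

# H-strand slice of a region (wrap-aware), as a character string.
hstrand_slice <- function(genome, start, end) {
  if (end >= start) {
    substr(genome$sequence, start, end)
  } else {
    if (!genome$circular) {
      stop(sprintf("genome '%s': origin-spanning slice on a linear genome",
                   genome$id), call. = FALSE)
    }
    paste0(substr(genome$sequence, start, genome$length),
           substr(genome$sequence, 1L, end))
  }
}

# Resolve a feature reference (row index, gene name, or one-row data.frame /
# list) to a one-row list with name/type/start/end/strand.
resolve_feature <- function(genome, feature) {
  if (is.numeric(feature) && length(feature) == 1L) {
    feature <- genome$features[feature, , drop = FALSE]
  } else if (is.character(feature) && length(feature) == 1L) {
    hit <- which(genome$features$name == feature)
    if (length(hit) == 0L) {
      stop(sprintf("genome '%s': no feature named '%s'", genome$id, feature),
           call. = FALSE)
    }
    feature <- genome$features[hit[1L], , drop = FALSE]
  }
  as.list(feature)
}

#' Extract the coding-sense sequence of a gene
#'
#' Returns the H-strand slice for H-strand features and the reverse
#' complement of the slice for L-strand features; origin-spanning features
#' concatenate the suffix and prefix of the circular sequence before
#' orienting.
#'
#' @param genome a [mito_genome()].
#' @param feature a row index into `genome$features`, a gene name, or a
#'   one-row feature data.frame/list.
#' @return coding-sense nucleotide string.
#' @export
extract_gene_sequence <- function(genome, feature) {
  f <- resolve_feature(genome, feature)
  s <- hstrand_slice(genome, f$start, f$end)
  if (identical(f$strand, "L")) revcomp(s) else s
}
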