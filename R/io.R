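# Feature-key mapping between GenBank flat files and the internal type
# vocabulary. "gene" keys are ignored on read (they duplicate CDS/tRNA/rRNA
# keys for annotated mitogenomes); "source" and other keys are skipped.
GB_KEY_TO_TYPE <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    "D-loop" = "control_region")
TYPE_TO_GB_KEY <- setNames(names(GB_KEY_TO_TYPE), unname(GB_KEY_TO_TYPE))

#' Read a GenBank flat file into a mito_genome
#'
#' A minimal reader for single-record GenBank flat files (LOCUS / FEATURES /
#' ORIGIN) as written by annotation pipelines and by [write_genbank()].
#' CDS, tRNA, rRNA and D-loop features are kept (1-based inclusive
#' coordinates; `complement(...)` maps to strand L); an origin-spanning
#' `join(a..L,1..b)` location becomes a feature with `end < start`.
#' Topology is taken from the LOCUS line.
#'
#' @param path path to a GenBank flat file.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: no LOCUS line",
                                call. = FALSE)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("^circular$", toks, ignore.case = TRUE))

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) {
    stop("GenBank format error: no ORIGIN/sequence section", call. = FALSE)
  }
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1L] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("GenBank format error: empty sequence", call. = FALSE)
  }

  feats_at <- grep("^FEATURES", lines)
  feat <- list()
  if (length(feats_at) > 0L) {
    block <- lines[(feats_at[1L] + 1L):(origin_at[1L] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^     \\S", ln)) {               # new feature key line
        if (!is.null(cur)) feat[[length(feat) + 1L]] <- cur
        key <- sub("^\\s*(\\S+).*", "\\1", ln)
        loc <- trimws(sub("^\\s*\\S+\\s*", "", ln))
        cur <- list(key = key, loc = loc, name = NA_character_)
      } else if (!is.null(cur)) {
        q <- trimws(ln)
        if (grepl("^/(gene|product)=", q) && is.na(cur$name)) {
          cur$name <- gsub("\"", "", sub("^/(gene|product)=", "", q))
        } else if (!grepl("^/", q) && nchar(q) > 0L && !grepl("\\d", cur$loc)) {
          cur$loc <- paste0(cur$loc, q)           # wrapped location line
        }
      }
    }
    if (!is.null(cur)) feat[[length(feat) + 1L]] <- cur
  }

  rows <- lapply(feat, function(fe) {
    if (!fe$key %in% names(GB_KEY_TO_TYPE)) return(NULL)
    p <- parse_gb_location(fe$loc, nchar(sequence))
    nm <- if (is.na(fe$name)) fe$key else fe$name
    data.frame(name = nm, type = unname(GB_KEY_TO_TYPE[fe$key]),
               start = p$start, end = p$end, strand = p$strand,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  features <- if (is.null(rows)) NULL else {
    gene_features(rows$name, rows$type, rows$start, rows$end, rows$strand)
  }
  mito_genome(id, sequence, features, circular = circular)
}

# Parse a GenBank location: "a..b", "complement(a..b)",
# "join(a..L,1..b)" and complement(join(...)). Returns start/end/strand with
# the origin-spanning join encoded as end < start.
parse_gb_location <- function(loc, genome_length) {
  strand <- "H"
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "L"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, parse_gb_range)
    if (length(rng) == 2L && rng[[1L]]$end == genome_length &&
        rng[[2L]]$start == 1L) {
      return(list(start = rng[[1L]]$start, end = rng[[2L]]$end,
                  strand = strand))
    }
    stop("unsupported GenBank join() location: ", loc, call. = FALSE)
  }
  r <- parse_gb_range(x)
  list(start = r$start, end = r$end, strand = strand)
}

parse_gb_range <- function(x) {
  m <- regmatches(x, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", x))[[1L]]
  if (length(m) != 3L) stop("cannot parse GenBank range: ", x, call. = FALSE)
  list(start = as.integer(m[2L]), end = as.integer(m[3L]))
}

#' Write a mito_genome as a GenBank flat file
#'
#' @param genome a [mito_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome$length
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA",
                   genome$id, L, if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  f <- genome$features
  if (nrow(f) > 0L) {
    for (i in seq_len(nrow(f))) {
      loc <- if (f$end[i] >= f$start[i]) {
        sprintf("%d..%d", f$start[i], f$end[i])
      } else {
        sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
      }
      if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
      out <- c(out,
               sprintf("     %-15s %s", TYPE_TO_GB_KEY[f$type[i]], loc),
               sprintf("                     /gene=\"%s\"", f$name[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA plus TSV feature table into a mito_genome
#'
#' The TSV must carry columns name, type, start, end, strand (header
#' optional if in that order); coordinates are taken verbatim as 1-based
#' inclusive, and strand dialects (+/-, 1/-1) are normalized to H/L.
#'
#' @param fasta path to a single-record FASTA file.
#' @param table path to the feature TSV.
#' @param circular logical topology flag (TSV files carry no topology).
#' @return a [mito_genome()].
#' @export
read_fasta_with_table <- function(fasta, table, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) {
    stop(sprintf("ambiguity error: FASTA '%s' holds %d records, expected 1",
                 fasta, length(ss)), call. = FALSE)
  }
  id <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  sequence <- as.character(ss[[1L]])

  tab <- tryCatch(
    read.delim(table, header = TRUE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) stop("feature table format error: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(tab) == 0L) {
    warning("empty feature table: genome has zero features")
    return(mito_genome(id, sequence, NULL, circular = circular))
  }
  expected <- c("name", "type", "start", "end", "strand")
  if (!all(expected %in% tolower(names(tab)))) {
    # headerless table in canonical column order
    tab <- read.delim(table, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(tab) < 5L) stop("feature table format error: need 5 columns",
                             call. = FALSE)
    names(tab)[1:5] <- expected
  } else {
    names(tab) <- tolower(names(tab))
  }
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      gene_features(tab$name[i], tab$type[i], tab$start[i], tab$end[i],
                    tab$strand[i]),
      error = function(e) stop(sprintf("feature table row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  })
  mito_genome(id, sequence, do.call(rbind, feats), circular = circular)
}

#' Write a mito_genome as FASTA plus TSV feature table
#'
#' @param genome a [mito_genome()].
#' @param fasta,table output paths.
#' @return list of the two paths, invisibly.
#' @export
write_fasta_with_table <- function(genome, fasta, table) {
  ss <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  write_feature_table(genome, table)
  invisible(list(fasta = fasta, table = table))
}

#' Write the normalized feature table of a genome
#'
#' Columns: name, type, start, end, strand, length (wrap-aware).
#'
#' @param genome a [mito_genome()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  f$length <- feature_lengths(f$start, f$end, genome$length)
  write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
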