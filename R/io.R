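#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and U is mapped to T, so RNA-alphabet tRNA inputs
#' normalise to the package's internal DNA alphabet. The first whitespace-
#' delimited token of each header is the record identifier; the remainder is
#' kept as the description.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `description`, `sequence`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_format(sprintf("not FASTA-formatted: %s (%s)",
                                            path, conditionMessage(e)))
  )
  if (length(set) == 0L) stop_format(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop_format(sprintf("record '%s' has an empty sequence in %s",
                        ids[!nzchar(seqs)][1], path))
  }
  bad <- !is_dna(seqs)
  if (any(bad)) {
    stop_format(sprintf("record '%s' contains non-DNA characters in %s",
                        ids[bad][1], path))
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description` (as returned by [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse tRNAscan-SE tabular output
#'
#' Accepts tRNAscan-SE v2.0 tab-delimited output, with or without its 3-line
#' header block. Coordinates keep the tRNAscan-SE convention at this boundary:
#' 1-based inclusive, `begin > end` meaning the reverse strand (exposed as the
#' logical `reverse` column). Pseudogene-flagged rows are retained and marked.
#'
#' @param path path to a tRNAscan-SE output table.
#' @return data.frame with columns `source_sequence`, `gene_index`, `begin`,
#'   `end`, `isotype`, `anticodon` (uppercase DNA), `score`, `pseudo`,
#'   `reverse`, `line` (source line number).
#' @export
parse_trnascan_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("annotation table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_header <- function(ln, idx) {
    if (idx > 3L) return(FALSE)
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    length(f) < 4L || startsWith(f[1], "-") ||
      grepl("^(Sequence|Name|tRNA)", f[1]) || is.na(suppressWarnings(as.numeric(f[2])))
  }
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (is_header(ln, i)) next
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(f) < 6L) {
      stop_format(sprintf("line %d: expected >= 6 tab-delimited fields", i))
    }
    begin <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    if (is.na(begin) || is.na(end)) {
      stop_format(sprintf("line %d: non-numeric coordinates ('%s', '%s')",
                          i, f[3], f[4]))
    }
    if (begin == end) {
      stop_format(sprintf("line %d: begin equals end (%d)", i, begin))
    }
    anticodon <- toupper(chartr("Uu", "Tt", f[6]))
    if (nchar(anticodon) != 3L || !is_dna(anticodon)) {
      stop_format(sprintf("line %d: anticodon '%s' is not a 3-mer DNA string",
                          i, f[6]))
    }
    score <- if (length(f) >= 9L) suppressWarnings(as.numeric(f[9])) else NA_real_
    pseudo <- any(grepl("pseudo", f[-(1:6)], ignore.case = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      source_sequence = f[1],
      gene_index = as.integer(f[2]),
      begin = begin, end = end,
      isotype = f[5], anticodon = anticodon,
      score = score, pseudo = pseudo,
      reverse = begin > end, line = i,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(source_sequence = character(), gene_index = integer(),
                      begin = integer(), end = integer(), isotype = character(),
                      anticodon = character(), score = numeric(),
                      pseudo = logical(), reverse = logical(), line = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

CATALOG_COLUMNS <- c("nuclease_name", "source_organism", "isotype", "anticodon",
                     "cleavage_bond", "motif", "modification_dependent",
                     "citation_note")

#' Load an anticodon-nuclease target catalog
#'
#' The catalog is a TSV with one row per (nuclease, isoacceptor target):
#' columns `nuclease_name`, `source_organism`, `isotype` (three-letter code,
#' `fMet` or `Sup`), `anticodon` (3-mer or `*` wildcard for all isoacceptors of
#' the isotype), `cleavage_bond` (integer 0-5, the scissile bond between loop
#' indices b and b+1, or `anticodon` for a cut inside the anticodon whose exact
#' bond is uncharacterised), `motif` (dinucleotide straddling the cut, or `-`),
#' `modification_dependent` (0/1), `citation_note`.
#'
#' Two fixtures ship with the package:
#' `system.file("extdata", "catalog_mycobacteria.tsv", package = "phanticodon")`
#' and `catalog_enterobacteria.tsv`.
#'
#' @param path path to a catalog TSV.
#' @return data.frame of class `acn_catalog`; `bond` is an integer companion
#'   column (`NA` for the `anticodon` sentinel).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("catalog file not found: %s", path))
  df <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  missing <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing)) {
    stop_format(sprintf("catalog %s lacks column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  as_catalog(df)
}

#' Validate and class a catalog data.frame
#'
#' @param df data.frame with the catalog TSV columns (see [load_catalog()]).
#' @return the validated data.frame, classed `acn_catalog`.
#' @export
as_catalog <- function(df) {
  df <- df[, CATALOG_COLUMNS, drop = FALSE]
  if (nrow(df) > 0L) {
    bad_iso <- !(df$isotype %in% AA_CODES)
    if (any(bad_iso)) {
      stop_validation(sprintf("unknown isotype code '%s' in catalog",
                              df$isotype[bad_iso][1]))
    }
    df$anticodon <- ifelse(df$anticodon == "*", "*",
                           tolower(chartr("Uu", "Tt", df$anticodon)))
    bad_ac <- df$anticodon != "*" &
      !(nchar(df$anticodon) == 3L & grepl("^[acgt]{3}$", df$anticodon))
    if (any(bad_ac)) {
      stop_validation(sprintf("anticodon '%s' is neither a 3-mer nor '*'",
                              df$anticodon[bad_ac][1]))
    }
    ok_bond <- df$cleavage_bond == "anticodon" | df$cleavage_bond %in% as.character(0:5)
    if (any(!ok_bond)) {
      stop_validation(sprintf(
        "cleavage_bond '%s' outside 0..5 and not the 'anticodon' sentinel",
        df$cleavage_bond[!ok_bond][1]))
    }
    df$motif <- toupper(df$motif)
    bad_motif <- df$motif != "-" & !(nchar(df$motif) == 2L & is_dna(df$motif, allow_n = FALSE))
    if (any(bad_motif)) {
      stop_validation(sprintf("motif '%s' is not a dinucleotide or '-'",
                              df$motif[bad_motif][1]))
    }
    if (!all(df$modification_dependent %in% c("0", "1"))) {
      stop_validation("modification_dependent must be 0 or 1")
    }
    # per-nuclease modification dependence must be consistent
    md <- tapply(df$modification_dependent, df$nuclease_name,
                 function(x) length(unique(x)))
    if (any(md > 1L)) {
      stop_validation(sprintf("nuclease '%s' mixes modification_dependent flags",
                              names(md)[md > 1L][1]))
    }
  }
  df$modification_dependent <- df$modification_dependent == "1"
  df$bond <- suppressWarnings(as.integer(df$cleavage_bond))
  class(df) <- c("acn_catalog", "data.frame")
  df
}

#' Write a uniform report as TSV
#'
#' Tab-separated, UTF-8, Unix newlines, one header line. List columns (for
#' example differing loop positions) are collapsed with `";"`. Row order is
#' whatever the producing module sorted; this function does not reorder.
#'
#' @param rows data.frame of uniform records (possibly 0 rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.list(rows[[j]])) {
      rows[[j]] <- vapply(rows[[j]], function(v) paste(v, collapse = ";"), "")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a report written by [write_report_tsv()]
#'
#' @param path path to a report TSV.
#' @return data.frame.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
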