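# Queries against an anticodon-nuclease target catalog (see load_catalog()
# for the column dialect). A catalog row is one TargetSpec: an isoacceptor
# key (isotype + anticodon, "*" = all isoacceptors of the isotype), the
# cleavage bond, an optional dinucleotide motif straddling the cut, and the
# nuclease it belongs to.

#' Does a target specification place the cut inside the anticodon?
#'
#' True when the cleavage bond is the `"anticodon"` sentinel, when the integer
#' bond is 2 or 3 (both flanking nucleotides at loop indices 2-4, i.e. tRNA
#' positions 34-36), or when a cleavage motif is present and anchored inside a
#' concrete anticodon (the motif occurs within the 3-mer). Isoacceptors cut
#' inside the anticodon cannot evade cleavage by loop mutations without
#' changing decoding identity, which is why they are the avoidance candidates.
#'
#' @param spec one catalog row (one-row data.frame or list with fields
#'   `cleavage_bond`, `anticodon`, `motif`).
#' @return logical scalar.
#' @examples
#' cat <- load_catalog(system.file("extdata", "catalog_mycobacteria.tsv",
#'                                 package = "phanticodon"))
#' bond_in_anticodon(cat[1, ])
#' @export
bond_in_anticodon <- function(spec) {
  if (identical(as.character(spec$cleavage_bond), "anticodon")) return(TRUE)
  b <- suppressWarnings(as.integer(spec$cleavage_bond))
  if (!is.na(b) && b %in% c(2L, 3L)) return(TRUE)
  motif <- toupper(spec$motif %||% "-")
  if (motif != "-" && spec$anticodon != "*" &&
      grepl(motif, toupper(spec$anticodon), fixed = TRUE)) {
    return(TRUE)
  }
  FALSE
}

#' Catalog targets matching one isoacceptor
#'
#' Returns the catalog rows whose key matches `(isotype, anticodon)` exactly,
#' plus wildcard rows (`anticodon == "*"`) matching the isotype, in catalog
#' order.
#'
#' @param isotype three-letter code, `"fMet"` or `"Sup"`.
#' @param anticodon 3-mer (case-insensitive).
#' @param catalog an `acn_catalog` (see [load_catalog()]).
#' @return subset of `catalog` (possibly 0 rows).
#' @export
targets_for <- function(isotype, anticodon, catalog) {
  anticodon <- tolower(anticodon)
  hit <- catalog$isotype == isotype &
    (catalog$anticodon == anticodon | catalog$anticodon == "*")
  catalog[hit, , drop = FALSE]
}

#' Host isoacceptors with at least one nuclease target
#'
#' @param host_set tRNA gene table (see [trna_genes()]).
#' @param catalog an `acn_catalog`.
#' @return data.frame of distinct keys (`isotype`, `anticodon`), sorted by
#'   isotype then anticodon.
#' @export
targeted_isoacceptors <- function(host_set, catalog) {
  keys <- unique(host_set[, c("isotype", "anticodon")])
  hit <- vapply(seq_len(nrow(keys)), function(i) {
    nrow(targets_for(keys$isotype[i], keys$anticodon[i], catalog)) > 0L
  }, NA)
  keys <- keys[hit, , drop = FALSE]
  keys <- keys[order(keys$isotype, keys$anticodon), , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

# Loop indices (0-based, 0..6) that count as the cleavage site for a spec,
# resolved against the host loop:
#   - motif present and found in the host loop -> all positions covered by
#     its occurrences;
#   - integer bond b -> the two flanking indices {b, b+1};
#   - "anticodon" sentinel (and motif absent or not found) -> the anticodon
#     window {2,3,4}, since the cut is inside the anticodon but the exact
#     bond is uncharacterised.
cleavage_site_positions <- function(spec, host_loop) {
  motif <- toupper(spec$motif %||% "-")
  if (motif != "-") {
    hits <- find_all_occurrences(toupper(host_loop), motif)
    if (length(hits)) {
      pos <- unique(unlist(lapply(hits, function(p) (p - 1L):(p + nchar(motif) - 2L))))
      return(sort(pos[pos >= 0L & pos <= 6L]))
    }
  }
  b <- suppressWarnings(as.integer(spec$cleavage_bond))
  if (!is.na(b)) return(c(b, b + 1L))
  2:4
}
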