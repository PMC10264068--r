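# Headline analysis: classify each phage tRNA against its host counterpart at
# each nuclease cleavage site, and quantify isoacceptor prevalence and
# avoidance across a phage collection.

CALL_LEVELS <- c("mutated_at_cleavage_site", "mutated_in_loop", "loop_identical",
                 "modification_dependent_unresolved", "no_host_counterpart")

#' Find the host counterpart of a phage tRNA
#'
#' Exact `(isotype, anticodon)` matches are preferred; among multiple host
#' copies, the one with the smallest full-sequence edit distance to the phage
#' gene wins (tie: lexicographically smallest `gene_id`). If no host gene
#' shares the anticodon, the search falls back to the same isotype (smallest
#' edit distance) and the result is flagged `match_level = "isotype"` —
#' anticodon-shifted phage tRNAs are exactly the interesting evasion
#' candidates, so they are compared rather than dropped. `NULL` if the host
#' lacks the isotype entirely.
#'
#' @param phage_gene one tRNA gene (one-row data.frame or list).
#' @param host_set host tRNA gene table.
#' @return one-row data.frame with attribute `match_level` (`"exact"` or
#'   `"isotype"`), or `NULL`.
#' @export
match_host_counterpart <- function(phage_gene, host_set) {
  same_iso <- host_set[host_set$isotype == phage_gene$isotype, , drop = FALSE]
  if (nrow(same_iso) == 0L) return(NULL)
  exact <- same_iso[same_iso$anticodon == tolower(phage_gene$anticodon), , drop = FALSE]
  pool <- if (nrow(exact) > 0L) exact else same_iso
  level <- if (nrow(exact) > 0L) "exact" else "isotype"
  d <- as.vector(utils::adist(phage_gene$sequence, pool$sequence))
  pool <- pool[order(d, pool$gene_id), , drop = FALSE]
  out <- pool[1, , drop = FALSE]
  attr(out, "match_level") <- level
  out
}

#' Compare a phage anticodon loop with its host counterpart at a cleavage site
#'
#' Differences are reported as 0-based loop indices (0..6, tRNA positions
#' 32..38). The cleavage-site positions are the two indices flanking the
#' spec's integer bond, or the positions where the spec's motif occurs in the
#' host loop, or the anticodon window for the `"anticodon"` sentinel. The call
#' is `mutated_at_cleavage_site` if any difference hits a cleavage-site
#' position, `mutated_in_loop` if differences exist only elsewhere in the
#' loop, and `loop_identical` otherwise. For modification-dependent nucleases
#' (such as Colicin E5) any non-identical loop is reported as
#' `modification_dependent_unresolved`, since sequence alone cannot establish
#' whether the required modification is present.
#'
#' @param host_loop,phage_loop 7-mer loops from [extract_loop()].
#' @param spec one catalog row.
#' @param modification_dependent override of the spec's flag (default: the
#'   spec's own value).
#' @return list with `call` and `differing_positions` (integer vector).
#' @export
compare_loops <- function(host_loop, phage_loop, spec,
                          modification_dependent = NULL) {
  host_loop <- toupper(host_loop); phage_loop <- toupper(phage_loop)
  if (nchar(host_loop) != 7L || nchar(phage_loop) != 7L) {
    stop_argument("compare_loops(): both loops must be 7-mers")
  }
  md <- modification_dependent %||% isTRUE(spec$modification_dependent)
  h <- strsplit(host_loop, "", fixed = TRUE)[[1]]
  p <- strsplit(phage_loop, "", fixed = TRUE)[[1]]
  diff <- which(h != p) - 1L
  site <- cleavage_site_positions(spec, host_loop)
  call <- if (length(diff) == 0L) {
    "loop_identical"
  } else if (any(diff %in% site)) {
    "mutated_at_cleavage_site"
  } else {
    "mutated_in_loop"
  }
  if (md && call != "loop_identical") call <- "modification_dependent_unresolved"
  list(call = call, differing_positions = diff)
}

empty_calls <- function() {
  data.frame(phage = character(), phage_gene_id = character(),
             host_gene_id = character(), isotype = character(),
             anticodon = character(), nuclease_name = character(),
             cleavage_bond = character(), motif = character(),
             match_level = character(), call = character(),
             differing_positions = character(), stringsAsFactors = FALSE)
}

#' Classify every phage tRNA in a collection against the host and catalog
#'
#' One sensitivity call is made per (phage gene, matching catalog target).
#' Genes whose anticodon arm cannot be located are skipped with a reason row
#' rather than aborting the run. Calls are ordered by phage, gene, nuclease
#' and catalog row.
#'
#' The summary distinguishes isoacceptor species from gene copies: it reports
#' the number of distinct targeted keys encoded by any phage, how many of
#' those are predicted mutated at the cleavage site in *every* phage encoding
#' them, and the same tallies at gene-copy resolution.
#'
#' @param phage_sets named list of tRNA gene tables, one per phage.
#' @param host_set host tRNA gene table.
#' @param catalog an `acn_catalog`.
#' @return object of class `acn_sensitivity`: list with `calls` (data.frame,
#'   `differing_positions` `;`-joined), `skipped`, `summary`, `n_phages`.
#' @export
analyze_collection <- function(phage_sets, host_set, catalog) {
  stopifnot(is.list(phage_sets))
  if (is.null(names(phage_sets)) || any(!nzchar(names(phage_sets)))) {
    names(phage_sets) <- sprintf("phage%03d", seq_along(phage_sets))
  }
  host_loops <- new.env(parent = emptyenv())
  get_host_loop <- function(g) {
    key <- g$gene_id
    if (!is.null(host_loops[[key]])) return(host_loops[[key]])
    lp <- extract_loop(g$sequence, g$anticodon)
    host_loops[[key]] <- lp
    lp
  }
  calls <- list()
  skipped <- list()
  for (ph in names(phage_sets)) {
    genes <- phage_sets[[ph]]
    if (is.null(genes) || nrow(genes) == 0L) next
    genes <- genes[order(genes$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, , drop = FALSE]
      ploop <- tryCatch(extract_loop(g$sequence, g$anticodon), error = function(e) e)
      if (inherits(ploop, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          phage = ph, gene_id = g$gene_id,
          reason = conditionMessage(ploop), stringsAsFactors = FALSE)
        next
      }
      specs <- targets_for(g$isotype, g$anticodon, catalog)
      if (nrow(specs) == 0L) next
      for (j in seq_len(nrow(specs))) {
        spec <- specs[j, , drop = FALSE]
        host <- match_host_counterpart(g, host_set)
        if (is.null(host)) {
          calls[[length(calls) + 1L]] <- data.frame(
            phage = ph, phage_gene_id = g$gene_id, host_gene_id = NA_character_,
            isotype = g$isotype, anticodon = tolower(g$anticodon),
            nuclease_name = spec$nuclease_name,
            cleavage_bond = as.character(spec$cleavage_bond), motif = spec$motif,
            match_level = "none", call = "no_host_counterpart",
            differing_positions = "", stringsAsFactors = FALSE)
          next
        }
        hloop <- tryCatch(get_host_loop(host), error = function(e) e)
        if (inherits(hloop, "error")) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            phage = ph, gene_id = host$gene_id,
            reason = conditionMessage(hloop), stringsAsFactors = FALSE)
          next
        }
        cmp <- compare_loops(hloop, ploop, spec)
        calls[[length(calls) + 1L]] <- data.frame(
          phage = ph, phage_gene_id = g$gene_id, host_gene_id = host$gene_id,
          isotype = g$isotype, anticodon = tolower(g$anticodon),
          nuclease_name = spec$nuclease_name,
          cleavage_bond = as.character(spec$cleavage_bond), motif = spec$motif,
          match_level = attr(host, "match_level"), call = cmp$call,
          differing_positions = paste(cmp$differing_positions, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(phage = character(), gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(calls = calls, skipped = skipped,
                 summary = summarize_calls(calls),
                 n_phages = length(phage_sets)),
            class = "acn_sensitivity")
}

summarize_calls <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(n_targeted_keys = 0L, n_targeted_keys_mutated_in_all = 0L,
                n_targeted_copies = 0L, n_targeted_copies_mutated = 0L))
  }
  key <- paste(calls$isotype, calls$anticodon, sep = "|")
  keys <- unique(key)
  mutated_all <- vapply(keys, function(k) {
    sub <- calls[key == k, , drop = FALSE]
    all(vapply(split(sub, sub$phage), function(s)
      any(s$call == "mutated_at_cleavage_site"), NA))
  }, NA)
  copy <- paste(calls$phage, calls$phage_gene_id, sep = "|")
  copies <- unique(copy)
  copy_mut <- vapply(copies, function(k)
    any(calls$call[copy == k] == "mutated_at_cleavage_site"), NA)
  list(n_targeted_keys = length(keys),
       n_targeted_keys_mutated_in_all = sum(mutated_all),
       n_targeted_copies = length(copies),
       n_targeted_copies_mutated = sum(copy_mut))
}

#' @export
print.acn_sensitivity <- function(x, ...) {
  s <- x$summary
  cat("Phage tRNA anticodon-nuclease sensitivity analysis\n")
  cat(sprintf("  phages analysed:               %d\n", x$n_phages))
  cat(sprintf("  sensitivity calls:             %d (%d gene(s) skipped)\n",
              nrow(x$calls), nrow(x$skipped)))
  cat(sprintf("  targeted isoacceptor keys:     %d\n", s$n_targeted_keys))
  cat(sprintf("  ... predicted mutated at the cleavage site in every phage: %d\n",
              s$n_targeted_keys_mutated_in_all))
  cat(sprintf("  targeted gene copies:          %d (%d with a cleavage-site mutation)\n",
              s$n_targeted_copies, s$n_targeted_copies_mutated))
  invisible(x)
}

#' @export
summary.acn_sensitivity <- function(object, ...) {
  tab <- table(factor(object$calls$call, levels = CALL_LEVELS))
  out <- c(object$summary, list(call_table = tab))
  class(out) <- "summary.acn_sensitivity"
  out
}

#' @export
print.summary.acn_sensitivity <- function(x, ...) {
  cat("Call classes:\n")
  print(x$call_table)
  cat(sprintf("Targeted keys: %d; mutated-in-all-phages: %d; copies: %d (%d mutated)\n",
              x$n_targeted_keys, x$n_targeted_keys_mutated_in_all,
              x$n_targeted_copies, x$n_targeted_copies_mutated))
  invisible(x)
}

#' Isoacceptor prevalence across a phage collection
#'
#' A phage counts once per key regardless of gene copy number (presence /
#' absence per phage).
#'
#' @param phage_sets named list of tRNA gene tables.
#' @return data.frame with `isotype`, `anticodon`, `phages_encoding`,
#'   `collection_size`, `fraction`, sorted by isotype then anticodon.
#' @export
prevalence <- function(phage_sets) {
  if (!is.list(phage_sets) || length(phage_sets) == 0L) {
    stop_argument("prevalence(): the phage collection must be non-empty")
  }
  n <- length(phage_sets)
  per_phage <- lapply(phage_sets, function(g) {
    if (is.null(g) || nrow(g) == 0L) return(NULL)
    unique(g[, c("isotype", "anticodon")])
  })
  all_keys <- do.call(rbind, per_phage)
  if (is.null(all_keys) || nrow(all_keys) == 0L) {
    return(data.frame(isotype = character(), anticodon = character(),
                      phages_encoding = integer(), collection_size = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(all_keys$isotype, all_keys$anticodon, sep = "|")
  counts <- table(key)
  parts <- strsplit(names(counts), "|", fixed = TRUE)
  out <- data.frame(
    isotype = vapply(parts, `[[`, "", 1L),
    anticodon = vapply(parts, `[[`, "", 2L),
    phages_encoding = as.integer(counts),
    collection_size = n,
    stringsAsFactors = FALSE)
  out$fraction <- out$phages_encoding / n
  out <- out[order(out$isotype, out$anticodon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Avoidance of anticodon-targeted isoacceptors
#'
#' Lists every host isoacceptor targeted *within the anticodon itself* (see
#' [bond_in_anticodon()]) together with its prevalence across the phage
#' collection; the key is called avoided when that prevalence does not exceed
#' `threshold`. Such isoacceptors cannot evade cleavage by loop mutations
#' without changing identity, so the evolutionary expectation is omission.
#'
#' @param phage_sets named list of tRNA gene tables.
#' @param host_set host tRNA gene table.
#' @param catalog an `acn_catalog`.
#' @param threshold prevalence fraction at or below which a key counts as
#'   avoided (default 0.05).
#' @return data.frame with `isotype`, `anticodon`, `nuclease_name`
#'   (`;`-joined when several within-anticodon nucleases hit the key),
#'   `within_anticodon`, `prevalence_fraction`, `avoided`.
#' @export
avoidance <- function(phage_sets, host_set, catalog, threshold = 0.05) {
  if (threshold < 0 || threshold > 1) {
    stop_argument("avoidance(): threshold must lie in [0, 1]")
  }
  keys <- targeted_isoacceptors(host_set, catalog)
  prev <- prevalence(phage_sets)
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    specs <- targets_for(keys$isotype[i], keys$anticodon[i], catalog)
    within <- vapply(seq_len(nrow(specs)), function(j)
      bond_in_anticodon(specs[j, , drop = FALSE]), NA)
    if (!any(within)) next
    hit <- prev$isotype == keys$isotype[i] & prev$anticodon == keys$anticodon[i]
    frac <- if (any(hit)) prev$fraction[hit] else 0
    rows[[length(rows) + 1L]] <- data.frame(
      isotype = keys$isotype[i], anticodon = keys$anticodon[i],
      nuclease_name = paste(unique(specs$nuclease_name[within]), collapse = ";"),
      within_anticodon = TRUE, prevalence_fraction = frac,
      avoided = frac <= threshold, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(isotype = character(), anticodon = character(),
                      nuclease_name = character(), within_anticodon = logical(),
                      prevalence_fraction = numeric(), avoided = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
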