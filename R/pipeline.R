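# Pipeline layer: each run_* function is one analysis stage over files on
# disk, writing the TSV reports. A thin command-line wrapper around these
# lives at inst/cli/phanticodon.R (subcommands simulate / sensitivity /
# codon / all).

#' Read tRNA genes from a FASTA + tRNAscan-SE table pair
#'
#' Each annotation row is resolved against the FASTA record named by its
#' `source_sequence` column and normalised to the sense strand.
#'
#' @param fasta_path genome (or contig set) FASTA.
#' @param annot_path tRNAscan-SE tabular output for the same sequences.
#' @param drop_pseudo drop pseudogene-flagged rows (default TRUE).
#' @return tRNA gene table (see [trna_genes()]).
#' @export
genes_from_files <- function(fasta_path, annot_path, drop_pseudo = TRUE) {
  genome <- read_fasta(fasta_path)
  rows <- parse_trnascan_table(annot_path)
  if (drop_pseudo) rows <- rows[!rows$pseudo, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(trna_genes(character(), character(), character(), character(),
                      character())[0, ])
  }
  miss <- setdiff(unique(rows$source_sequence), genome$id)
  if (length(miss)) {
    stop_validation(sprintf("annotation references sequence '%s' absent from %s",
                            miss[1], fasta_path))
  }
  parts <- lapply(unique(rows$source_sequence), function(sid) {
    normalize_genes(rows[rows$source_sequence == sid, , drop = FALSE],
                    genome[genome$id == sid, , drop = FALSE])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write a scenario's synthetic fixtures to a directory
#'
#' Produces `host.fasta` + `host_trnascan.tsv`, one `phages/phageNN.fasta` +
#' `.trnascan.tsv` pair per phage, the scenario-implied `catalog.tsv`, the
#' two CDS FASTA sets (`cds_group_a.fasta`, `cds_group_b.fasta`),
#' `ground_truth.tsv` and `scenario.json`. Deterministic: the same scenario
#' always yields byte-identical files.
#'
#' @param scn an `acn_scenario` (or path to a `scenario.json`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `host`, `phages`, `catalog`
#'   and the output directory.
#' @export
run_simulate <- function(scn, out_dir) {
  if (is.character(scn)) scn <- read_scenario(scn)
  stopifnot(inherits(scn, "acn_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  host <- generate_host_trnas(scn, dir = out_dir)
  phages <- generate_phage_collection(scn, host, dir = out_dir)
  cat_df <- scenario_catalog(scn)
  cat_out <- cat_df[, CATALOG_COLUMNS, drop = FALSE]
  cat_out$modification_dependent <- as.integer(cat_out$modification_dependent)
  write_report_tsv(cat_out, file.path(out_dir, "catalog.tsv"))
  prof <- scn$codon_profiles
  write_fasta(generate_cds_set(prof[[1]], scn$n_cds, scn$cds_length,
                               derive_seed(scn$seed, "cds_group_a")),
              file.path(out_dir, "cds_group_a.fasta"))
  write_fasta(generate_cds_set(prof[[2]], scn$n_cds, scn$cds_length,
                               derive_seed(scn$seed, "cds_group_b")),
              file.path(out_dir, "cds_group_b.fasta"))
  write_scenario(scn, file.path(out_dir, "scenario.json"))
  invisible(list(host = host, phages = phages, catalog = cat_df,
                 out_dir = out_dir))
}

#' Serialise / read a scenario as JSON
#'
#' @param scn an `acn_scenario`.
#' @param path JSON path.
#' @return `path` invisibly / the scenario.
#' @export
write_scenario <- function(scn, path) {
  x <- unclass(scn)
  # keep codon names: named vectors serialise to JSON objects only as lists
  x$codon_profiles <- lapply(x$codon_profiles, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("scenario file not found: %s", path))
  x <- jsonlite::fromJSON(path)
  prof <- lapply(x$codon_profiles, function(p) unlist(p))
  tg <- as.data.frame(x$targets, stringsAsFactors = FALSE)
  tg$mutate_at <- if (is.null(tg$mutate_at)) NA_integer_ else
    suppressWarnings(as.integer(tg$mutate_at))
  scenario(seed = x$seed, n_phages = x$n_phages,
           host_keys = as.data.frame(x$host_keys, stringsAsFactors = FALSE),
           targets = tg, codon_profiles = prof,
           n_cds = x$n_cds, cds_length = x$cds_length)
}

find_phage_inputs <- function(phage_dir) {
  if (!dir.exists(phage_dir)) {
    stop_input(sprintf("phage directory not found: %s", phage_dir))
  }
  fas <- sort(list.files(phage_dir, pattern = "\\.(fasta|fa|fna)$",
                         full.names = TRUE))
  if (length(fas) == 0L) stop_input(sprintf("no phages found in %s", phage_dir))
  ann <- vapply(fas, function(f) {
    base <- sub("\\.(fasta|fa|fna)$", "", f)
    cand <- paste0(base, c(".trnascan.tsv", "_trnascan.tsv", ".tsv"))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0L) {
      stop_input(sprintf("no tRNAscan-SE table found for %s", f))
    }
    hit[1]
  }, "")
  data.frame(name = tools::file_path_sans_ext(basename(fas)),
             fasta = fas, annot = unname(ann), stringsAsFactors = FALSE)
}

#' Run the sensitivity stage over files on disk
#'
#' Reads the host genome + annotation, every phage FASTA/annotation pair in
#' `phage_dir` (a `<name>.fasta` with a sibling `<name>.trnascan.tsv`), and a
#' nuclease catalog; writes `sensitivity_calls.tsv`, `prevalence.tsv`,
#' `avoidance.tsv`, `summary.tsv` and (when genes were skipped)
#' `skipped.tsv` to `out_dir`.
#'
#' @param host_fasta,host_annot host genome FASTA and tRNAscan-SE table.
#' @param phage_dir directory of per-phage FASTA + annotation pairs.
#' @param catalog_path catalog TSV (see [load_catalog()]).
#' @param threshold avoidance prevalence threshold in `[0, 1]`.
#' @param out_dir report directory (created if needed).
#' @return invisibly, a list with the `acn_sensitivity` object, `prevalence`,
#'   `avoidance` and the written file paths.
#' @export
run_sensitivity <- function(host_fasta, host_annot, phage_dir, catalog_path,
                            threshold = 0.05, out_dir) {
  inputs <- find_phage_inputs(phage_dir)
  catalog <- load_catalog(catalog_path)
  host_set <- genes_from_files(host_fasta, host_annot)
  phage_sets <- stats::setNames(
    lapply(seq_len(nrow(inputs)), function(i)
      genes_from_files(inputs$fasta[i], inputs$annot[i])),
    inputs$name)
  res <- analyze_collection(phage_sets, host_set, catalog)
  prev <- prevalence(phage_sets)
  avoid <- avoidance(phage_sets, host_set, catalog, threshold = threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    write_report_tsv(res$calls, file.path(out_dir, "sensitivity_calls.tsv")),
    write_report_tsv(prev, file.path(out_dir, "prevalence.tsv")),
    write_report_tsv(avoid, file.path(out_dir, "avoidance.tsv")),
    write_report_tsv(
      data.frame(metric = c("n_phages", "n_targeted_keys",
                            "n_targeted_keys_mutated_in_all",
                            "n_targeted_copies", "n_targeted_copies_mutated",
                            "n_genes_skipped"),
                 value = c(res$n_phages, res$summary$n_targeted_keys,
                           res$summary$n_targeted_keys_mutated_in_all,
                           res$summary$n_targeted_copies,
                           res$summary$n_targeted_copies_mutated,
                           nrow(res$skipped)),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "summary.tsv")))
  if (nrow(res$skipped) > 0L) {
    files <- c(files, write_report_tsv(res$skipped,
                                       file.path(out_dir, "skipped.tsv")))
  }
  invisible(list(sensitivity = res, prevalence = prev, avoidance = avoid,
                 files = files))
}

run_test_safely <- function(expr, name) {
  tryCatch(expr, acn_degenerate_error = function(e) {
    stat_result(NA_real_, NA_real_, NA_real_, name,
                note = conditionMessage(e))
  })
}

#' Run the codon-usage stage over files on disk
#'
#' Computes cusp-style codon usage tables for a phage and a host CDS set,
#' the preferred-codon concordance (restricted to the amino-acid families
#' decoded by the phage tRNA repertoire when one is supplied), Welch's
#' two-sample t-test of per-1000 codon frequency between tRNA-decoded and
#' non-decoded sense codons of the phage, and the paired t-test of per-1000
#' frequency between phage and host (paired by sense codon). Degenerate
#' inputs (for example identical phage and host tables) are recorded in
#' `stats.tsv` rather than aborting.
#'
#' @param phage_cds,host_cds CDS FASTA paths.
#' @param repertoire optional tRNA repertoire: a tRNA gene table, a data.frame
#'   with an `anticodon` column, or a character vector of anticodons.
#' @param out_dir report directory.
#' @return invisibly, a list with both `codon_usage_table`s, the concordance,
#'   the two `acn_stat` results and written file paths.
#' @export
run_codon <- function(phage_cds, host_cds, repertoire = NULL, out_dir) {
  phage_tab <- count_codons(read_fasta(phage_cds))
  host_tab <- count_codons(read_fasta(host_cds))
  decoded <- if (!is.null(repertoire)) codons_decoded_by(repertoire) else NULL
  families <- if (!is.null(decoded)) {
    setdiff(unique(codon_amino_acids(decoded)), "*")
  } else NULL
  conc <- concordance(phage_tab, host_tab, families = families)

  sense <- phage_tab$amino_acid != "*"
  welch <- if (is.null(decoded)) {
    stat_result(NA_real_, NA_real_, NA_real_, "Welch two-sample t-test",
                note = "no tRNA repertoire supplied; decoded/non-decoded split unavailable")
  } else {
    in_dec <- phage_tab$codon %in% decoded
    run_test_safely(
      welch_t_test(phage_tab$per_1000[sense & in_dec],
                   phage_tab$per_1000[sense & !in_dec]),
      "Welch two-sample t-test")
  }
  paired <- run_test_safely(
    paired_t_test(phage_tab$per_1000[sense], host_tab$per_1000[sense]),
    "paired t-test")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stats_df <- data.frame(
    test_name = c(welch$test_name, paired$test_name),
    statistic = c(welch$statistic, paired$statistic),
    df = c(welch$df, paired$df),
    p_value = c(welch$p_value, paired$p_value),
    note = c(welch$note, paired$note),
    stringsAsFactors = FALSE)
  files <- c(
    write_report_tsv(as.data.frame(phage_tab),
                     file.path(out_dir, "codon_usage_phage.tsv")),
    write_report_tsv(as.data.frame(host_tab),
                     file.path(out_dir, "codon_usage_host.tsv")),
    write_report_tsv(conc$comparison, file.path(out_dir, "concordance.tsv")),
    write_report_tsv(stats_df, file.path(out_dir, "stats.tsv")))
  invisible(list(phage_table = phage_tab, host_table = host_tab,
                 concordance = conc, welch = welch, paired = paired,
                 files = files))
}
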