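# Codon-usage arm: cusp-equivalent usage tables, preferred-codon concordance,
# the strict tRNA -> codon mapping, and the two t-tests used to probe the
# codon-compensation hypothesis.

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))[order(
    as.vector(outer(outer(b, b, paste0), b, paste0)))]
}

codon_amino_acids <- function(codons) {
  # Bacterial translation table 11: same codon -> amino-acid map as the
  # standard code (tables differ only in permitted start codons).
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Codon usage table for a set of coding sequences
#'
#' Reproduces the semantics of the EMBOSS `cusp` utility: per codon, the raw
#' count, the fraction among synonymous codons of the same amino acid (stop
#' codons form the `*` family), and the frequency per 1000 codons. Codons are
#' translated with the bacterial genetic code (translation table 11).
#' Sequences whose length is not a multiple of 3 lose the trailing partial
#' codon with a warning; codons containing N are skipped and tallied in the
#' `skipped_codons` attribute.
#'
#' @param cds_set data.frame with a `sequence` column ([read_fasta()] output),
#'   or a character vector of CDS sequences.
#' @return data.frame of class `codon_usage_table`, 64 rows with columns
#'   `codon`, `amino_acid` (one-letter, `*` = stop), `count`, `fraction`,
#'   `per_1000`; attributes `total_codons` and `skipped_codons`.
#' @examples
#' count_codons("ATGAAATAA")
#' @export
count_codons <- function(cds_set) {
  seqs <- if (is.data.frame(cds_set)) cds_set$sequence else cds_set
  if (length(seqs) == 0L) stop_argument("count_codons(): empty CDS set")
  seqs <- toupper(chartr("Uu", "Tt", seqs))
  trimmed <- nchar(seqs) %% 3L != 0L
  if (any(trimmed)) {
    warning(sprintf("%d CDS length(s) not divisible by 3; trailing partial codon dropped",
                    sum(trimmed)))
    seqs[trimmed] <- substr(seqs[trimmed], 1L, nchar(seqs[trimmed]) %/% 3L * 3L)
  }
  codons <- unlist(lapply(seqs, function(s) {
    if (nchar(s) < 3L) return(character())
    substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
  }))
  universe <- all_codons()
  valid <- codons %in% universe
  skipped <- sum(!valid)
  counts <- table(factor(codons[valid], levels = universe))
  total <- sum(counts)
  aa <- codon_amino_acids(universe)
  fam_tot <- tapply(as.integer(counts), aa, sum)[aa]
  fraction <- ifelse(fam_tot > 0, as.integer(counts) / fam_tot, 0)
  per_1000 <- if (total > 0) as.integer(counts) / total * 1000 else rep(0, 64L)
  out <- data.frame(codon = universe, amino_acid = aa,
                    count = as.integer(counts), fraction = unname(fraction),
                    per_1000 = per_1000, stringsAsFactors = FALSE)
  attr(out, "total_codons") <- total
  attr(out, "skipped_codons") <- skipped
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Preferred codon of each synonymous family
#'
#' Per amino-acid family with a nonzero count, the most frequently used
#' codon; ties go to the alphabetically first codon and are flagged.
#'
#' @param table a `codon_usage_table`.
#' @return data.frame with `amino_acid`, `codon`, `count`, `tie_flag`, sorted
#'   by amino acid.
#' @export
preferred_codons <- function(table) {
  stopifnot(inherits(table, "codon_usage_table") || is.data.frame(table))
  rows <- lapply(split(seq_len(nrow(table)), table$amino_acid), function(idx) {
    sub <- table[idx, , drop = FALSE]
    if (sum(sub$count) == 0L) return(NULL)
    sub <- sub[order(-sub$count, sub$codon), , drop = FALSE]
    tie <- nrow(sub) > 1L && sub$count[2] == sub$count[1]
    data.frame(amino_acid = sub$amino_acid[1], codon = sub$codon[1],
               count = sub$count[1], tie_flag = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(out)) {
    return(data.frame(amino_acid = character(), codon = character(),
                      count = integer(), tie_flag = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$amino_acid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preferred-codon concordance between two gene sets
#'
#' Compares the preferred codon of each amino-acid family between (typically)
#' a phage and its host. Stop codons are excluded ("per amino acid"). The
#' default family restriction is the amino acids with nonzero counts in both
#' tables; pass `families` (one-letter codes) to restrict to, for example, the
#' families decoded by the phage's tRNA repertoire.
#'
#' @param phage_table,host_table `codon_usage_table` objects.
#' @param families optional character vector of one-letter amino-acid codes.
#' @return list with `comparison` (data.frame: `amino_acid`,
#'   `phage_preferred`, `host_preferred`, `match`, `tie_flag`) and
#'   `mismatches` (integer count).
#' @export
concordance <- function(phage_table, host_table, families = NULL) {
  pp <- preferred_codons(phage_table)
  hp <- preferred_codons(host_table)
  fams <- intersect(pp$amino_acid, hp$amino_acid)
  fams <- setdiff(fams, "*")
  if (!is.null(families)) fams <- intersect(fams, families)
  fams <- sort(fams)
  cmp <- data.frame(
    amino_acid = fams,
    phage_preferred = pp$codon[match(fams, pp$amino_acid)],
    host_preferred = hp$codon[match(fams, hp$amino_acid)],
    stringsAsFactors = FALSE)
  cmp$match <- cmp$phage_preferred == cmp$host_preferred
  cmp$tie_flag <- pp$tie_flag[match(fams, pp$amino_acid)] |
    hp$tie_flag[match(fams, hp$amino_acid)]
  list(comparison = cmp, mismatches = sum(!cmp$match))
}

#' Codons decoded by a tRNA repertoire (strict mapping)
#'
#' Strict reverse-complement mapping, no wobble or superwobble expansion: each
#' anticodon decodes exactly the codon it Watson-Crick pairs with. Suppressor
#' (`Sup`) anticodons map to their (stop) codon like any other.
#'
#' @param repertoire data.frame with an `anticodon` column (e.g. a tRNA gene
#'   table or an isoacceptor key table), or a character vector of anticodons.
#' @return sorted, deduplicated character vector of uppercase codons.
#' @examples
#' codons_decoded_by(c("ttt", "gct"))  # AAA, AGC
#' @export
codons_decoded_by <- function(repertoire) {
  ac <- if (is.data.frame(repertoire)) repertoire$anticodon else repertoire
  if (length(ac) == 0L) return(character())
  sort(unique(revcomp(ac)))
}

stat_result <- function(statistic, df, p_value, test_name, note = NA_character_) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name, note = note),
            class = "acn_stat")
}

#' @export
print.acn_stat <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, df = %.4g, p-value = %.4g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  if (!is.na(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Used to compare codon frequencies between the
#' codons a phage encodes a tRNA for and those it does not.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return object of class `acn_stat` with `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) {
    stop_argument("welch_t_test(): each group needs n >= 2")
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    stop_degenerate("welch_t_test(): both groups have zero variance")
  }
  se2 <- va / na + vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  stat_result(t, df, p, "Welch two-sample t-test")
}

#' Paired t-test
#'
#' One-sample t on the elementwise differences `x - y`, df = n - 1, two-sided
#' p-value. Used to compare per-codon frequencies between phage and host gene
#' sets, paired by codon.
#'
#' @param x,y numeric vectors of equal length n >= 2, paired by index.
#' @return object of class `acn_stat`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    stop_argument("paired_t_test(): x and y must have equal length")
  }
  n <- length(x)
  if (n < 2L) stop_argument("paired_t_test(): need n >= 2 pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop_degenerate("paired_t_test(): all differences identical (zero variance)")
  }
  t <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  stat_result(t, df, p, "paired t-test")
}
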