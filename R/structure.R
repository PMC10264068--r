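# Anticodon-arm geometry.
#
# The arm is modelled as the canonical 5-bp stem + 7-nt loop. Loop positions
# are indexed 0..6 and correspond to standard tRNA numbering 32..38, with the
# anticodon at loop indices 2..4 (positions 34..36). `loop_start` is the
# 0-based offset of the loop within the gene sequence, so the arm occupies
# [loop_start - 5, loop_start + 11] (0-based inclusive).

STEM_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Count paired positions between the two strands of an anticodon stem
#'
#' Watson-Crick pairs plus the G:T wobble count as paired; position i of
#' `stem5` is checked against position 5 - i of `stem3` (antiparallel).
#'
#' @param stem5,stem3 5-mer DNA strings (5' and 3' strand of the stem, both
#'   written 5'→3').
#' @return integer in 0..5.
#' @examples
#' pairing_count("GGCGC", "GCGCC")  # 5
#' @export
pairing_count <- function(stem5, stem3) {
  stem5 <- toupper(stem5); stem3 <- toupper(stem3)
  if (nchar(stem5) != 5L || nchar(stem3) != 5L ||
      !is_dna(stem5) || !is_dna(stem3)) {
    stop_argument("pairing_count(): both stems must be 5-mer DNA strings")
  }
  a <- strsplit(stem5, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(stem3, "", fixed = TRUE)[[1]])
  sum(paste0(a, b) %in% STEM_PAIRS)
}

score_window <- function(sequence, loop_start0) {
  # 0-based loop_start -> 1-based substring coordinates
  L <- loop_start0
  stem5 <- substr(sequence, L - 4L, L)
  loop <- substr(sequence, L + 1L, L + 7L)
  stem3 <- substr(sequence, L + 8L, L + 12L)
  list(stem5 = stem5, loop = loop, stem3 = stem3, loop_start = L,
       pairing_count = pairing_count(stem5, stem3))
}

pick_candidate <- function(cands, n) {
  # max pairing; tie -> loop_start closest to 0.42 * length; tie -> smallest
  pc <- vapply(cands, `[[`, 0L, "pairing_count")
  ls <- vapply(cands, `[[`, 0L, "loop_start")
  dist <- abs(ls - 0.42 * n)
  ord <- order(-pc, dist, ls)
  cands[[ord[1]]]
}

#' Locate the anticodon arm in a tRNA gene sequence
#'
#' With an anticodon hint, every occurrence of the hint is tried as the
#' anticodon (loop indices 2-4) and the flanking 5-mers scored as the stem;
#' candidates pairing at >= 3 of 5 stem positions are kept. Without a hint,
#' every possible loop placement is scored and the threshold rises to 4.
#' Among the surviving candidates the one with maximal pairing wins; ties are
#' broken by proximity of `loop_start` to 0.42 x sequence length (the
#' anticodon-loop position of a canonical ~76-nt tRNA), then by the smallest
#' `loop_start`.
#'
#' @param sequence DNA string, length >= 17 (5 + 7 + 5).
#' @param anticodon optional 3-mer hint (the gene's annotated anticodon).
#' @return object of class `anticodon_arm`: list with `stem5`, `loop`,
#'   `stem3`, `loop_start` (0-based offset of the loop in `sequence`) and
#'   `pairing_count`.
#' @section Errors: if no candidate reaches the pairing threshold, an error of
#'   class `acn_arm_not_found` is signalled carrying the best rejected
#'   candidate in its `best_candidate` field for diagnostics.
#' @examples
#' seq <- paste0("AAAA", "GGCGC", "CTGCTAA", "GCGCC", "AAAA")
#' find_anticodon_arm(seq, "GCT")
#' @export
find_anticodon_arm <- function(sequence, anticodon = NULL) {
  sequence <- toupper(chartr("Uu", "Tt", sequence))
  n <- nchar(sequence)
  if (n < 17L || !is_dna(sequence)) {
    stop_argument("find_anticodon_arm(): sequence must be DNA of length >= 17")
  }
  if (!is.null(anticodon)) {
    anticodon <- toupper(chartr("Uu", "Tt", anticodon))
    if (nchar(anticodon) != 3L) {
      stop_argument("find_anticodon_arm(): anticodon hint must be a 3-mer")
    }
    hits <- find_all_occurrences(sequence, anticodon)
    # anticodon at loop 2..4: 1-based hit p -> 0-based loop_start p - 3
    loop_starts <- (hits - 3L)
    loop_starts <- loop_starts[loop_starts >= 5L & loop_starts + 12L <= n]
    threshold <- 3L
    if (length(loop_starts) == 0L) {
      acn_stop(sprintf(
        "arm not found: anticodon hint '%s' has no occurrence with full flanks",
        anticodon), "acn_arm_not_found", best_candidate = NULL)
    }
  } else {
    loop_starts <- seq.int(5L, n - 12L)
    threshold <- 4L
  }
  cands <- lapply(loop_starts, function(L) score_window(sequence, L))
  keep <- vapply(cands, `[[`, 0L, "pairing_count") >= threshold
  if (!any(keep)) {
    best <- pick_candidate(cands, n)
    acn_stop(sprintf(
      "arm not found: best candidate pairs at %d/5 (threshold %d) at loop_start %d",
      best$pairing_count, threshold, best$loop_start),
      "acn_arm_not_found", best_candidate = best)
  }
  arm <- pick_candidate(cands[keep], n)
  structure(arm, class = "anticodon_arm")
}

#' @export
print.anticodon_arm <- function(x, ...) {
  cat(sprintf("anticodon arm: 5'-%s [%s] %s-3'  loop_start=%d  pairs=%d/5\n",
              x$stem5, x$loop, x$stem3, x$loop_start, x$pairing_count))
  invisible(x)
}

#' Extract the 7-nt anticodon loop
#'
#' For a character sequence, `anticodon` is used as the hint for
#' [find_anticodon_arm()]; for a tRNA gene table (see [trna_genes()]) each
#' gene's own anticodon is the hint and a named character vector of loops is
#' returned. When a hint is used the anticodon always sits at loop indices
#' 2-4 of the result.
#'
#' @param x DNA string or a `data.frame` of tRNA genes.
#' @param ... passed on to methods.
#' @return 7-mer loop string(s).
#' @export
extract_loop <- function(x, ...) UseMethod("extract_loop")

#' @rdname extract_loop
#' @param anticodon 3-mer hint.
#' @export
extract_loop.character <- function(x, anticodon = NULL, ...) {
  find_anticodon_arm(x, anticodon)$loop
}

#' @rdname extract_loop
#' @export
extract_loop.data.frame <- function(x, ...) {
  out <- vapply(seq_len(nrow(x)), function(i) {
    find_anticodon_arm(x$sequence[i], x$anticodon[i])$loop
  }, "")
  names(out) <- x$gene_id
  out
}

#' Construct a table of tRNA genes
#'
#' The central in-memory container: one row per annotated tRNA gene, with the
#' sense-strand sequence and the gene's isoacceptor identity (isotype +
#' anticodon). Anticodons are stored lowercase, the field convention for
#' isoacceptor keys (for example `Ser(gct)`).
#'
#' @param gene_id unique text tokens.
#' @param source_genome identifier of the genome each gene came from.
#' @param isotype three-letter amino-acid code, `"fMet"` or `"Sup"`.
#' @param anticodon 3-mer DNA strings.
#' @param sequence sense-strand DNA, 55-120 nt.
#' @param origin `"annotation_table"` or `"arm_finder"`.
#' @return data.frame with those columns, anticodon lowercased.
#' @export
trna_genes <- function(gene_id, source_genome, isotype, anticodon, sequence,
                       origin = "annotation_table") {
  anticodon <- tolower(chartr("Uu", "Tt", anticodon))
  sequence <- toupper(chartr("Uu", "Tt", sequence))
  if (any(nchar(anticodon) != 3L)) {
    stop_validation("trna_genes(): every anticodon must be a 3-mer")
  }
  len <- nchar(sequence)
  if (any(len < 55L | len > 120L)) {
    stop_validation(sprintf(
      "trna_genes(): sequence length %d outside the 55-120 nt tRNA range",
      len[len < 55L | len > 120L][1]))
  }
  if (any(!is_dna(sequence))) stop_validation("trna_genes(): non-DNA sequence")
  if (!all(origin %in% c("annotation_table", "arm_finder"))) {
    stop_validation("trna_genes(): origin must be annotation_table or arm_finder")
  }
  data.frame(gene_id = gene_id, source_genome = source_genome,
             isotype = isotype, anticodon = anticodon, sequence = sequence,
             origin = origin, stringsAsFactors = FALSE)
}

#' Turn annotation rows into sense-strand tRNA genes
#'
#' Applies the tRNAscan-SE coordinate convention: 1-based inclusive
#' coordinates, `begin > end` meaning the gene lies on the reverse strand, in
#' which case the genomic slice is reverse-complemented so the stored sequence
#' is the tRNA sense strand.
#'
#' @param rows data.frame from [parse_trnascan_table()] (any subset of rows).
#' @param genome one record from [read_fasta()] (one-row data.frame or list
#'   with `id` and `sequence`).
#' @return tRNA gene table (see [trna_genes()]), `origin = "annotation_table"`.
#' @export
normalize_genes <- function(rows, genome) {
  glen <- nchar(genome$sequence)
  lo <- pmin(rows$begin, rows$end)
  hi <- pmax(rows$begin, rows$end)
  if (any(lo < 1L | hi > glen)) {
    bad <- which(lo < 1L | hi > glen)[1]
    stop_validation(sprintf(
      "gene %s.%d spans %d..%d, outside genome '%s' (1..%d)",
      rows$source_sequence[bad], rows$gene_index[bad], lo[bad], hi[bad],
      genome$id, glen))
  }
  seqs <- substring(genome$sequence, lo, hi)
  rev <- rows$begin > rows$end
  if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
  trna_genes(
    gene_id = paste0(rows$source_sequence, ".trna", rows$gene_index),
    source_genome = genome$id,
    isotype = rows$isotype,
    anticodon = rows$anticodon,
    sequence = seqs,
    origin = "annotation_table"
  )
}

#' @rdname normalize_genes
#' @param row a single annotation row.
#' @export
normalize_gene <- function(row, genome) normalize_genes(row, genome)
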