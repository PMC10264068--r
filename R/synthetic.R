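# Seeded synthetic host/phage fixtures with known ground truth.
#
# A scenario states a world: which isoacceptors the host encodes, which of
# them anticodon nucleases target (and where they cut), which targeted keys
# the phages avoid entirely, which loop position each targeted copy mutates,
# and the codon-weight profiles behind the CDS sets for the t-tests. The
# generators are pure functions of the scenario (seed included): repeated
# runs are byte-identical. One 31-bit sub-stream per generated object, keyed
# by a stable label, so adding a phage never perturbs earlier phages.

MUT_SUCCESSOR <- c(A = "C", C = "G", G = "T", T = "A")

# geometry of every generated gene: 26-nt 5' flank, 5-bp stem, 7-nt loop,
# 5-bp stem, 33-nt 3' flank -> 76 nt, loop_start 31 (= 0.41 x length)
SYN_FLANK5 <- 26L
SYN_FLANK3 <- 33L
SYN_LOOP_START <- SYN_FLANK5 + 5L   # 0-based

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Define a synthetic host/phage scenario
#'
#' @param seed master integer seed.
#' @param n_phages number of phages in the collection.
#' @param host_keys data.frame with `isotype`, `anticodon` (lowercase 3-mers),
#'   one row per host isoacceptor.
#' @param targets data.frame with `isotype`, `anticodon`, `nuclease_name`,
#'   `cleavage_bond` (integer 0-5 as character, or `"anticodon"`), `motif`
#'   (dinucleotide or `"-"`), `avoided` (logical: phages omit the key),
#'   `mutate_at` (0-based loop index of the planted mutation, `NA` for none).
#'   Every target key must be a host key; avoided keys must be cut within the
#'   anticodon; a planned index must be a cleavage-site position of its spec.
#' @param codon_profiles list of two named codon-weight vectors (`group_a`,
#'   `group_b`) for CDS generation.
#' @param n_cds,cds_length CDS set size and length (nt, multiple of 3).
#' @return object of class `acn_scenario`.
#' @seealso [default_scenario()], [run_simulate()]
#' @export
scenario <- function(seed, n_phages, host_keys, targets,
                     codon_profiles = list(group_a = uniform_codon_weights(),
                                           group_b = uniform_codon_weights()),
                     n_cds = 40L, cds_length = 300L) {
  seed <- as.integer(seed)
  host_keys$anticodon <- tolower(host_keys$anticodon)
  targets$anticodon <- tolower(targets$anticodon)
  hk <- paste(host_keys$isotype, host_keys$anticodon)
  tk <- paste(targets$isotype, targets$anticodon)
  if (!all(tk %in% hk)) {
    stop_validation(sprintf("targeted key %s is not a host key",
                            setdiff(tk, hk)[1]))
  }
  if (any(duplicated(hk))) stop_validation("duplicate host keys")
  targets$mutate_at <- suppressWarnings(as.integer(targets$mutate_at))
  bad_idx <- !is.na(targets$mutate_at) &
    (targets$mutate_at < 0L | targets$mutate_at > 6L)
  if (any(bad_idx)) {
    stop_validation(sprintf("mutation index %d for %s outside loop indices 0..6",
                            targets$mutate_at[bad_idx][1], tk[bad_idx][1]))
  }
  for (i in which(targets$avoided)) {
    spec <- list(cleavage_bond = targets$cleavage_bond[i],
                 anticodon = targets$anticodon[i], motif = targets$motif[i])
    if (!bond_in_anticodon(spec)) {
      stop_validation(sprintf(
        "avoided key %s is not cut within the anticodon", tk[i]))
    }
  }
  if (length(codon_profiles) != 2L) {
    stop_validation("codon_profiles must hold exactly two weight vectors")
  }
  if (cds_length %% 3L != 0L || cds_length < 9L) {
    stop_validation("cds_length must be a multiple of 3, at least 9")
  }
  structure(list(seed = seed, n_phages = as.integer(n_phages),
                 host_keys = host_keys, targets = targets,
                 codon_profiles = codon_profiles,
                 n_cds = as.integer(n_cds), cds_length = as.integer(cds_length)),
            class = "acn_scenario")
}

#' The shipped default scenario
#'
#' Twelve host isoacceptors; six targeted by synthetic nucleases, of which
#' four carry a planted cleavage-site loop mutation in every phage copy and
#' two (the serine keys cut within the anticodon at the GA site) are avoided —
#' omitted from every phage. Twenty phages; CDS profiles identical (null
#' ground truth for the codon-usage t-tests).
#'
#' @param seed master seed.
#' @param n_phages collection size.
#' @return an `acn_scenario`.
#' @export
default_scenario <- function(seed = 42L, n_phages = 20L) {
  host_keys <- data.frame(
    isotype = c("Ala", "Gly", "Met", "Phe", "Ser", "Trp",
                "Lys", "Ile", "Tyr", "Asn", "Ser", "Ser"),
    anticodon = c("agc", "gcc", "cat", "gaa", "gct", "cca",
                  "ttt", "gat", "gta", "gtt", "gga", "tga"),
    stringsAsFactors = FALSE)
  targets <- data.frame(
    isotype = c("Lys", "Ile", "Tyr", "Asn", "Ser", "Ser"),
    anticodon = c("ttt", "gat", "gta", "gtt", "gga", "tga"),
    nuclease_name = c("PrrC-like", "VapC-like", "ColD-like", "MazF-like",
                      "VapC-like", "VapC-like"),
    cleavage_bond = c("4", "4", "1", "0", "anticodon", "anticodon"),
    motif = c("-", "-", "-", "-", "GA", "GA"),
    avoided = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    mutate_at = c(5L, 5L, 1L, 0L, NA, NA),
    stringsAsFactors = FALSE)
  scenario(seed = seed, n_phages = n_phages, host_keys = host_keys,
           targets = targets)
}

#' Catalog implied by a scenario's targets
#'
#' @param scn an `acn_scenario`.
#' @return an `acn_catalog` with one row per scenario target.
#' @export
scenario_catalog <- function(scn) {
  t <- scn$targets
  as_catalog(data.frame(
    nuclease_name = t$nuclease_name, source_organism = "synthetic",
    isotype = t$isotype, anticodon = t$anticodon,
    cleavage_bond = as.character(t$cleavage_bond), motif = t$motif,
    modification_dependent = "0",
    citation_note = "synthetic scenario target", stringsAsFactors = FALSE))
}

#' Generate the host tRNA set of a scenario
#'
#' One 76-nt gene per host key: random flanks, a perfectly paired planted
#' 5-bp stem, and a 7-nt loop carrying the key's anticodon at loop indices
#' 2-4 (`loop_start` 31, i.e. 0.41 x length — the canonical position).
#' Flanks are re-drawn (within the same seeded stream) until the anticodon
#' occurs exactly once in the gene, so arm finding is unambiguous by
#' construction. Genes are also embedded into a synthetic "genome" record
#' (20-nt spacers; even-indexed genes on the minus strand) with a matching
#' tRNAscan-SE-dialect annotation table, exercising the same I/O path as real
#' inputs.
#'
#' @param scn an `acn_scenario`.
#' @param dir optional directory; when given, `host.fasta` and
#'   `host_trnascan.tsv` are written there.
#' @return list with `genes` (tRNA gene table, sense strand), `genome`
#'   (single FASTA record), `annotation` (tRNAscan-SE-style rows).
#' @export
generate_host_trnas <- function(scn, dir = NULL) {
  genes <- lapply(seq_len(nrow(scn$host_keys)), function(i) {
    iso <- scn$host_keys$isotype[i]
    ac <- scn$host_keys$anticodon[i]
    set.seed(derive_seed(scn$seed, paste0("host:", iso, ":", ac)))
    for (attempt in 1:100) {
      stem5 <- random_dna(5L)
      stem3 <- revcomp(stem5)
      loop <- paste0(random_dna(2L), toupper(ac), random_dna(2L))
      s <- paste0(random_dna(SYN_FLANK5), stem5, loop, stem3, random_dna(SYN_FLANK3))
      if (length(find_all_occurrences(s, toupper(ac))) != 1L) next
      arm <- tryCatch(find_anticodon_arm(s, ac), error = function(e) NULL)
      if (!is.null(arm) && arm$loop_start == SYN_LOOP_START) {
        return(trna_genes(sprintf("host_synthetic.trna%d", i), "host_synthetic",
                          iso, ac, s))
      }
    }
    stop_validation(sprintf("could not plant an unambiguous arm for %s(%s)", iso, ac))
  })
  genes <- do.call(rbind, genes)
  emb <- embed_genes(genes, "host_synthetic", scn$seed, "host")
  if (!is.null(dir)) {
    write_fasta(emb$genome, file.path(dir, "host.fasta"))
    write_trnascan_table(emb$annotation, file.path(dir, "host_trnascan.tsv"))
  }
  list(genes = genes, genome = emb$genome, annotation = emb$annotation)
}

# Concatenate genes into one genome record with 20-nt spacers; even-indexed
# genes go on the minus strand (begin > end in the annotation).
embed_genes <- function(genes, genome_id, seed, label) {
  set.seed(derive_seed(seed, paste0(label, ":spacer")))
  parts <- character()
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(genes))) {
    sp <- random_dna(20L)
    parts <- c(parts, sp)
    pos <- pos + 20L
    minus <- i %% 2L == 0L
    gseq <- genes$sequence[i]
    parts <- c(parts, if (minus) revcomp(gseq) else gseq)
    b <- pos + 1L
    e <- pos + nchar(gseq)
    pos <- e
    rows[[i]] <- data.frame(
      source_sequence = genome_id, gene_index = i,
      begin = if (minus) e else b, end = if (minus) b else e,
      isotype = genes$isotype[i], anticodon = toupper(genes$anticodon[i]),
      score = 55.0, stringsAsFactors = FALSE)
  }
  parts <- c(parts, random_dna(20L))
  genome <- data.frame(id = genome_id, description = "synthetic",
                       sequence = paste(parts, collapse = ""),
                       stringsAsFactors = FALSE)
  list(genome = genome, annotation = do.call(rbind, rows))
}

write_trnascan_table <- function(annotation, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("Sequence\t\ttRNA\tBounds\t\ttRNA\tAnti\tIntron Bounds\tInf",
           "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
           paste(rep("--------", 9), collapse = "\t"))
  writeLines(hdr, con)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f",
                       a$source_sequence, a$gene_index, a$begin, a$end,
                       a$isotype, a$anticodon, a$score), con)
  }
  invisible(path)
}

#' Generate the phage collection of a scenario
#'
#' Every phage copies each non-avoided host gene. For targeted keys with a
#' planned mutation the copy's loop is substituted at the planned
#' cleavage-site index with the next base in A<C<G<T cyclic order (a
#' deterministic change, checkable by eye in the fixtures). Avoided keys are
#' omitted from every phage. A ground-truth table records the expected
#' sensitivity call of every generated gene.
#'
#' @param scn an `acn_scenario`.
#' @param host result of [generate_host_trnas()] for the same scenario.
#' @param dir optional directory; per-phage `phages/phageNN.fasta` and
#'   `phages/phageNN.trnascan.tsv` files plus `ground_truth.tsv` are written.
#' @return list with `phage_sets` (named list of tRNA gene tables),
#'   `ground_truth` (data.frame: `phage`, `gene_id`, `isotype`, `anticodon`,
#'   `targeted`, `expected_call`), `avoided_keys`.
#' @export
generate_phage_collection <- function(scn, host, dir = NULL) {
  t <- scn$targets
  tkey <- paste(t$isotype, t$anticodon)
  hkey <- paste(host$genes$isotype, host$genes$anticodon)
  avoided <- tkey[t$avoided]
  keep <- !(hkey %in% avoided)
  host_loops <- extract_loop(host$genes)

  # validate mutation plans against the host loops they would edit
  for (i in which(!is.na(t$mutate_at))) {
    hidx <- match(tkey[i], hkey)
    if (is.na(hidx)) next
    site <- cleavage_site_positions(
      list(cleavage_bond = t$cleavage_bond[i], motif = t$motif[i],
           anticodon = t$anticodon[i]), host_loops[hidx])
    if (!(t$mutate_at[i] %in% site)) {
      stop_validation(sprintf(
        "planned mutation index %d for %s(%s) is not a cleavage-site position (%s)",
        t$mutate_at[i], t$isotype[i], t$anticodon[i],
        paste(site, collapse = ",")))
    }
  }

  phage_sets <- list()
  truth <- list()
  if (!is.null(dir)) dir.create(file.path(dir, "phages"),
                                showWarnings = FALSE, recursive = TRUE)
  for (p in seq_len(scn$n_phages)) {
    pname <- sprintf("phage%02d", p)
    genes <- host$genes[keep, , drop = FALSE]
    genes$source_genome <- pname
    # same id scheme that genes_from_files() derives from the annotation
    gid <- sprintf("%s.trna%d", pname, seq_len(nrow(genes)))
    for (gi in seq_len(nrow(genes))) {
      k <- paste(genes$isotype[gi], genes$anticodon[gi])
      ti <- match(k, tkey)
      expected <- "untargeted"
      if (!is.na(ti)) {
        expected <- "loop_identical"
        if (!is.na(t$mutate_at[ti])) {
          pos1 <- SYN_LOOP_START + t$mutate_at[ti] + 1L  # 1-based position
          base <- substr(genes$sequence[gi], pos1, pos1)
          substr(genes$sequence[gi], pos1, pos1) <- MUT_SUCCESSOR[[base]]
          # a mutation inside the anticodon changes the gene's identity
          loop <- substr(genes$sequence[gi], SYN_LOOP_START + 1L,
                         SYN_LOOP_START + 7L)
          genes$anticodon[gi] <- tolower(substr(loop, 3L, 5L))
          expected <- "mutated_at_cleavage_site"
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        phage = pname, gene_id = gid[gi], isotype = genes$isotype[gi],
        anticodon = genes$anticodon[gi], targeted = !is.na(ti),
        expected_call = expected, stringsAsFactors = FALSE)
    }
    genes$gene_id <- gid
    rownames(genes) <- NULL
    phage_sets[[pname]] <- genes
    if (!is.null(dir)) {
      emb <- embed_genes(genes, pname, scn$seed, pname)
      write_fasta(emb$genome, file.path(dir, "phages", paste0(pname, ".fasta")))
      write_trnascan_table(emb$annotation,
                           file.path(dir, "phages", paste0(pname, ".trnascan.tsv")))
    }
  }
  ground_truth <- do.call(rbind, truth)
  avoided_df <- t[t$avoided, c("isotype", "anticodon"), drop = FALSE]
  rownames(avoided_df) <- NULL
  if (!is.null(dir)) write_report_tsv(ground_truth, file.path(dir, "ground_truth.tsv"))
  list(phage_sets = phage_sets, ground_truth = ground_truth,
       avoided_keys = avoided_df)
}

#' Uniform codon-weight profile
#'
#' @param include_stops keep stop codons in the support (default drops them).
#' @return named numeric vector of equal weights.
#' @export
uniform_codon_weights <- function(include_stops = FALSE) {
  codons <- all_codons()
  if (!include_stops) codons <- codons[codon_amino_acids(codons) != "*"]
  stats::setNames(rep(1, length(codons)), codons)
}

#' Generate a coding-sequence set from a codon-weight profile
#'
#' Internal codons are drawn independently with probability proportional to
#' the weights (stop codons are excluded from internal positions); the first
#' codon is forced to ATG and the last to TAA. Deterministic under the seed;
#' one sub-stream per CDS record.
#'
#' @param weights named non-negative codon weights (names = DNA codons).
#' @param n_cds number of sequences.
#' @param cds_length sequence length in nt (multiple of 3, >= 9).
#' @param seed integer seed.
#' @return data.frame with `id`, `description`, `sequence` (FASTA-record
#'   shape, see [read_fasta()]).
#' @export
generate_cds_set <- function(weights, n_cds, cds_length, seed) {
  if (is.null(names(weights)) || !all(names(weights) %in% all_codons())) {
    stop_argument("generate_cds_set(): weights must be named by DNA codons")
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop_argument("generate_cds_set(): weights must be non-negative, not all zero")
  }
  if (cds_length %% 3L != 0L || cds_length < 9L) {
    stop_argument("generate_cds_set(): cds_length must be a multiple of 3, >= 9")
  }
  if (n_cds == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  sense <- weights[codon_amino_acids(names(weights)) != "*"]
  if (all(sense == 0)) stop_argument("generate_cds_set(): no sense codon has weight")
  n_internal <- cds_length %/% 3L - 2L
  seqs <- vapply(seq_len(n_cds), function(i) {
    set.seed(derive_seed(seed, paste0("cds:", i)))
    internal <- sample(names(sense), n_internal, replace = TRUE,
                       prob = sense / sum(sense))
    paste(c("ATG", internal, "TAA"), collapse = "")
  }, "")
  data.frame(id = sprintf("cds%04d", seq_len(n_cds)),
             description = "synthetic CDS", sequence = seqs,
             stringsAsFactors = FALSE)
}
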