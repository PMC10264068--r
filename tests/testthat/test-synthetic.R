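test_that("host generation is a pure function of the scenario", {
  scn <- default_scenario(seed = 7L, n_phages = 3L)
  h1 <- generate_host_trnas(scn)
  h2 <- generate_host_trnas(scn)
  expect_identical(h1, h2)
  expect_equal(nrow(h1$genes), 12L)
  # different seed: same keys, different flanks
  h3 <- generate_host_trnas(default_scenario(seed = 8L, n_phages = 3L))
  expect_equal(h3$genes[, c("isotype", "anticodon")],
               h1$genes[, c("isotype", "anticodon")])
  expect_false(any(h3$genes$sequence == h1$genes$sequence))
})

test_that("every generated host gene resolves to its planted arm", {
  scn <- default_scenario(seed = 19L, n_phages = 2L)
  genes <- generate_host_trnas(scn)$genes
  for (i in seq_len(nrow(genes))) {
    arm <- find_anticodon_arm(genes$sequence[i], genes$anticodon[i])
    expect_equal(arm$loop_start, 31L)
    expect_equal(arm$pairing_count, 5L)
    expect_equal(tolower(substr(arm$loop, 3, 5)), genes$anticodon[i])
  }
})

test_that("phage collections plant the scenario's evasion pattern", {
  scn <- default_scenario(seed = 3L, n_phages = 5L)
  host <- generate_host_trnas(scn)
  col <- generate_phage_collection(scn, host)
  expect_length(col$phage_sets, 5L)
  # avoided keys appear in no phage
  for (g in col$phage_sets) {
    expect_false(any(paste(g$isotype, g$anticodon) %in%
                     c("Ser gga", "Ser tga")))
  }
  # ground truth has one row per generated gene
  expect_equal(nrow(col$ground_truth),
               sum(vapply(col$phage_sets, nrow, 0L)))
  # planted mutations sit exactly at the planned loop position
  t <- scn$targets
  for (i in which(!is.na(t$mutate_at))) {
    hidx <- which(host$genes$isotype == t$isotype[i] &
                  host$genes$anticodon == t$anticodon[i])
    hloop <- extract_loop(host$genes[hidx, ])
    g <- col$phage_sets[[1]]
    pidx <- which(g$isotype == t$isotype[i] & g$anticodon == t$anticodon[i])
    ploop <- extract_loop(g[pidx, ])
    diffs <- which(strsplit(hloop, "")[[1]] != strsplit(ploop, "")[[1]]) - 1L
    expect_equal(diffs, t$mutate_at[i])
  }
})

test_that("an unmutated targeted key is expected loop_identical", {
  scn <- default_scenario(seed = 4L, n_phages = 2L)
  scn$targets$mutate_at[1] <- NA_integer_
  host <- generate_host_trnas(scn)
  col <- generate_phage_collection(scn, host)
  k <- paste(scn$targets$isotype[1], scn$targets$anticodon[1])
  gt <- col$ground_truth
  expect_true(all(gt$expected_call[paste(gt$isotype, gt$anticodon) == k] ==
                  "loop_identical"))
})

test_that("a planned index off the cleavage site is a scenario error", {
  scn <- default_scenario(seed = 4L, n_phages = 2L)
  # Tyr(gta) is cut at bond 1 (positions 1-2); index 6 is not a cleavage site
  scn$targets$mutate_at[scn$targets$isotype == "Tyr"] <- 6L
  host <- generate_host_trnas(scn)
  expect_error(generate_phage_collection(scn, host), "Tyr",
               class = "acn_validation_error")
})

test_that("full-pipeline ground-truth recovery holds across seeds", {
  for (seed in c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89,
                 101, 202, 303, 404, 505, 606, 707, 808, 909, 1001)) {
    scn <- default_scenario(seed = seed, n_phages = 2L)
    host <- generate_host_trnas(scn)
    col <- generate_phage_collection(scn, host)
    res <- analyze_collection(col$phage_sets, host$genes, scenario_catalog(scn))
    gt <- col$ground_truth[col$ground_truth$targeted, ]
    obs <- res$calls
    key <- paste(obs$phage, obs$phage_gene_id)
    for (i in seq_len(nrow(gt))) {
      calls <- obs$call[key == paste(gt$phage[i], gt$gene_id[i])]
      expect_equal(unique(calls), gt$expected_call[i],
                   info = sprintf("seed %d gene %s", seed, gt$gene_id[i]))
    }
    # untargeted genes generate no calls
    expect_equal(sort(unique(obs$phage_gene_id)),
                 sort(gt$gene_id[gt$expected_call != "untargeted"]))
  }
})

test_that("generate_cds_set honours weights, determinism and edge cases", {
  w <- c(AAA = 1)
  cds <- generate_cds_set(w, n_cds = 3L, cds_length = 30L, seed = 1L)
  internal <- substr(cds$sequence, 4, 27)
  expect_true(all(gsub("AAA", "", internal) == ""))
  expect_true(all(startsWith(cds$sequence, "ATG")))
  expect_true(all(endsWith(cds$sequence, "TAA")))
  expect_equal(generate_cds_set(w, 0L, 30L, 1L)$sequence, character())
  expect_identical(generate_cds_set(uniform_codon_weights(), 4L, 30L, 9L),
                   generate_cds_set(uniform_codon_weights(), 4L, 30L, 9L))
  expect_error(generate_cds_set(c(AAA = -1), 1L, 30L, 1L),
               class = "acn_argument_error")
  expect_error(generate_cds_set(c(AAA = 1), 1L, 31L, 1L),
               class = "acn_argument_error")
})

test_that("empirical codon frequencies converge to the generating weights", {
  w <- uniform_codon_weights()
  cds <- generate_cds_set(w, n_cds = 100L, cds_length = 300L, seed = 77L)
  internal <- substr(cds$sequence, 4, 297)  # drop forced start/stop codons
  tab <- count_codons(internal)
  n_internal <- attr(tab, "total_codons")
  p <- 1 / length(w)
  se <- sqrt(p * (1 - p) / n_internal)
  obs_p <- tab$count[tab$codon %in% names(w)] / n_internal
  expect_true(all(abs(obs_p - p) <= 3 * se))
})
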