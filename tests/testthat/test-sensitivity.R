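spec_b4 <- list(cleavage_bond = "4", anticodon = "ttt", motif = "-",
                modification_dependent = FALSE)

test_that("compare_loops classifies identity, loop and cleavage-site mutations", {
  id <- compare_loops("CTGGAAA", "CTGGAAA", spec_b4)
  expect_equal(id$call, "loop_identical")
  expect_length(id$differing_positions, 0L)
  at <- compare_loops("CTGGAAA", "CTGGTAA", spec_b4)  # position 4 flanks bond 4
  expect_equal(at$call, "mutated_at_cleavage_site")
  expect_equal(at$differing_positions, 4L)
  away <- compare_loops("CTGGAAA", "TTGGAAA", spec_b4)  # only position 0
  expect_equal(away$call, "mutated_in_loop")
  expect_equal(away$differing_positions, 0L)
  expect_error(compare_loops("CTGGAA", "CTGGAAA", spec_b4),
               class = "acn_argument_error")
})

test_that("compare_loops uses motif occurrences in the host loop", {
  spec <- list(cleavage_bond = "anticodon", anticodon = "gga", motif = "GA",
               modification_dependent = FALSE)
  # host loop CTGGATA: GA occurs at positions 3-4
  hit <- compare_loops("CTGGATA", "CTGGTTA", spec)
  expect_equal(hit$call, "mutated_at_cleavage_site")
  miss <- compare_loops("CTGGATA", "CTGGATT", spec)
  expect_equal(miss$call, "mutated_in_loop")
})

test_that("modification-dependent targets are reported unresolved", {
  spec <- modifyList(spec_b4, list(modification_dependent = TRUE))
  r <- compare_loops("CTGGAAA", "CTGGTAA", spec)
  expect_equal(r$call, "modification_dependent_unresolved")
  expect_equal(r$differing_positions, 4L)
  expect_equal(compare_loops("CTGGAAA", "CTGGAAA", spec)$call, "loop_identical")
})

test_that("differing positions are symmetric under host/phage swap", {
  set.seed(99)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
    expect_equal(compare_loops(a, b, spec_b4)$differing_positions,
                 compare_loops(b, a, spec_b4)$differing_positions)
  }
})

test_that("match_host_counterpart prefers exact keys and breaks ties stably", {
  host <- make_gene_set(c("Lys", "Lys", "Ser"), c("ttt", "ctt", "gct"))
  phage <- host[host$anticodon == "ttt", ]
  phage$gene_id <- "ph.trna1"
  m <- match_host_counterpart(phage, host)
  expect_equal(m$anticodon, "ttt")
  expect_equal(attr(m, "match_level"), "exact")
  # two identical host copies -> lexicographically first gene_id
  host2 <- rbind(host[1, ], host[1, ])
  host2$gene_id <- c("host.b", "host.a")
  expect_equal(match_host_counterpart(phage, host2)$gene_id, "host.a")
  # isotype-level fallback is flagged
  phage_shift <- phage
  phage_shift$anticodon <- "cgt"
  m2 <- match_host_counterpart(phage_shift, host)
  expect_equal(attr(m2, "match_level"), "isotype")
  # missing isotype entirely
  phage_ile <- phage
  phage_ile$isotype <- "Ile"
  expect_null(match_host_counterpart(phage_ile, host))
})

test_that("prevalence counts presence per phage, ignoring copy number", {
  lys <- make_gene_set("Lys", "ttt")
  ser <- make_gene_set("Ser", "gct")
  prev <- prevalence(list(p1 = lys, p2 = ser))
  expect_equal(prev$fraction[prev$isotype == "Lys"], 0.5)
  prev_all <- prevalence(list(p1 = lys, p2 = lys))
  expect_equal(prev_all$fraction, 1.0)
  dup <- rbind(lys, lys)
  dup$gene_id <- c("a", "b")
  prev_dup <- prevalence(list(p1 = dup, p2 = ser, p3 = ser, p4 = ser))
  expect_equal(prev_dup$fraction[prev_dup$isotype == "Lys"], 0.25)
  expect_error(prevalence(list()), class = "acn_argument_error")
})

test_that("removing a phage never increases a prevalence count", {
  scn <- default_scenario(seed = 5L, n_phages = 6L)
  host <- generate_host_trnas(scn)
  sets <- generate_phage_collection(scn, host)$phage_sets
  full <- prevalence(sets)
  reduced <- prevalence(sets[-3])
  merged <- merge(full, reduced, by = c("isotype", "anticodon"))
  expect_true(all(merged$phages_encoding.y <= merged$phages_encoding.x))
})

test_that("avoidance lists only within-anticodon targets", {
  host <- make_gene_set(c("Ser", "Lys", "Gly"), c("gga", "ttt", "gcc"))
  cat_rows <- data.frame(
    nuclease_name = c("VapC", "PrrC", "LoopCutter"),
    source_organism = "test", isotype = c("Ser", "Lys", "Gly"),
    anticodon = c("gga", "ttt", "gcc"),
    cleavage_bond = c("anticodon", "anticodon", "5"),
    motif = c("GA", "-", "-"), modification_dependent = "0",
    citation_note = "-", stringsAsFactors = FALSE)
  cat <- as_catalog(cat_rows)
  phages <- list(p1 = make_gene_set("Lys", "ttt"),
                 p2 = make_gene_set("Lys", "ttt", seed = 12L))
  av <- avoidance(phages, host, cat, threshold = 0.05)
  expect_setequal(av$anticodon, c("gga", "ttt"))  # bond-5 Gly not listed
  expect_true(av$avoided[av$anticodon == "gga"])   # 0 of 2 phages
  expect_false(av$avoided[av$anticodon == "ttt"])  # all phages encode it
  expect_true(all(av$within_anticodon))
})

test_that("analyze_collection handles empty and untargeted collections", {
  host <- make_gene_set("Lys", "ttt")
  cat <- entero_catalog()
  empty <- analyze_collection(list(p1 = host[0, ]), host, cat)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(empty$summary$n_targeted_keys, 0L)
  ser <- make_gene_set("Ser", "gct")
  untarg <- analyze_collection(list(p1 = ser), host, cat)
  expect_equal(nrow(untarg$calls), 0L)
  prev <- prevalence(list(p1 = ser))
  expect_equal(prev$phages_encoding, 1L)
})

test_that("phage genes with no host counterpart are reported as such", {
  host <- make_gene_set("Ser", "gct")
  phage <- make_gene_set("Lys", "ttt")
  res <- analyze_collection(list(p1 = phage), host, entero_catalog())
  expect_equal(res$calls$call, "no_host_counterpart")
})
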