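test_that("count_codons reproduces cusp semantics on toy CDS sets", {
  tab <- count_codons("ATGAAATAA")
  expect_equal(tab$count[tab$codon == "ATG"], 1L)
  expect_equal(tab$count[tab$codon == "AAA"], 1L)
  expect_equal(tab$count[tab$codon == "TAA"], 1L)
  expect_equal(tab$fraction[tab$codon == "AAA"], 1.0)  # only Lys codon seen
  expect_equal(tab$per_1000[tab$codon == "ATG"], 1000 / 3)
  expect_equal(attr(tab, "total_codons"), 3L)

  tab2 <- count_codons("AAAAAG")
  expect_equal(tab2$fraction[tab2$codon == "AAA"], 0.5)
  expect_equal(tab2$fraction[tab2$codon == "AAG"], 0.5)

  expect_warning(tab3 <- count_codons("ATGA"), "partial codon")
  expect_equal(attr(tab3, "total_codons"), 1L)
  expect_equal(tab3$count[tab3$codon == "ATG"], 1L)

  tab4 <- count_codons(c("ATGNNNAAA"))
  expect_equal(attr(tab4, "skipped_codons"), 1L)
  expect_equal(attr(tab4, "total_codons"), 2L)

  expect_error(count_codons(character()), class = "acn_argument_error")
})

test_that("codon table invariants hold on random CDS sets", {
  for (seed in 1:20) {
    cds <- generate_cds_set(uniform_codon_weights(), n_cds = 5L,
                            cds_length = 90L, seed = seed)
    tab <- count_codons(cds)
    expect_equal(sum(tab$per_1000), 1000, tolerance = 1e-9)
    fam <- tapply(tab$fraction, tab$amino_acid, sum)
    fam_count <- tapply(tab$count, tab$amino_acid, sum)
    expect_true(all(abs(fam[fam_count > 0] - 1) < 1e-9))
    expect_true(all(fam[fam_count == 0] == 0))
    expect_equal(sum(tab$count), attr(tab, "total_codons"))
  }
})

test_that("preferred_codons takes the modal codon with alphabetical ties", {
  tab <- count_codons(c("AAAAAAAAAAAG"))  # AAA x3, AAG x1
  pref <- preferred_codons(tab)
  expect_equal(pref$codon[pref$amino_acid == "K"], "AAA")
  expect_false(pref$tie_flag[pref$amino_acid == "K"])
  tab_tie <- count_codons("AAAAAGAAAAAG")  # 2 vs 2
  pref_tie <- preferred_codons(tab_tie)
  expect_equal(pref_tie$codon[pref_tie$amino_acid == "K"], "AAA")
  expect_true(pref_tie$tie_flag[pref_tie$amino_acid == "K"])
  # families with zero counts are omitted
  expect_false("W" %in% pref$amino_acid)
})

test_that("concordance counts preferred-codon mismatches per family", {
  a <- count_codons("AAAAAAAAGGGGGGTGGT")  # K prefers AAA, G prefers GGG
  same <- concordance(a, a)
  expect_equal(same$mismatches, 0L)
  b <- count_codons("AAGAAGAAGGGGGGTGGT")  # K prefers AAG
  diff <- concordance(a, b)
  expect_equal(diff$mismatches, 1L)
  expect_false(diff$comparison$match[diff$comparison$amino_acid == "K"])
  expect_equal(nrow(concordance(a, b, families = character())$comparison), 0L)
  restricted <- concordance(a, b, families = "G")
  expect_equal(restricted$mismatches, 0L)
})

test_that("codons_decoded_by is the strict reverse complement", {
  expect_equal(codons_decoded_by("ttt"), "AAA")
  expect_equal(codons_decoded_by("gct"), "AGC")
  expect_equal(codons_decoded_by(character()), character())
  expect_equal(codons_decoded_by(data.frame(anticodon = c("ttt", "ttt", "gct"))),
               c("AAA", "AGC"))
})

test_that("welch_t_test matches its frozen hand-derived values", {
  sym <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)
  expect_error(welch_t_test(c(0, 0), c(0, 0)), class = "acn_degenerate_error")
  expect_error(welch_t_test(1, c(1, 2)), class = "acn_argument_error")
})

test_that("welch_t_test is antisymmetric and reduces to the pooled t", {
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(8, 1)
    f <- welch_t_test(a, b); g <- welch_t_test(b, a)
    expect_equal(f$statistic, -g$statistic)
    expect_equal(f$p_value, g$p_value)
  }
  # equal sizes and equal variances: Welch t equals the pooled-variance t
  a <- c(1, 2, 4, 7)
  b <- a + 3  # same sample variance
  n <- length(a)
  sp2 <- (var(a) + var(b)) / 2
  pooled_t <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / n))
  w <- welch_t_test(a, b)
  expect_equal(w$statistic, pooled_t)
  expect_equal(w$df, 2 * n - 2)
})

test_that("paired_t_test matches its frozen hand-derived values", {
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               class = "acn_degenerate_error")
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$statistic, -1.0)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.422650, tolerance = 1e-6)
  z <- paired_t_test(c(1, 2), c(2, 1))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(paired_t_test(1:3, 1:4), class = "acn_argument_error")
})

test_that("both tests agree with the reference implementation", {
  set.seed(11)
  for (i in 1:15) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), sd = 2)
    w <- welch_t_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
    x <- rnorm(8); y <- rnorm(8)
    p <- paired_t_test(x, y)
    refp <- t.test(x, y, paired = TRUE)
    expect_equal(p$statistic, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(p$p_value, refp$p.value, tolerance = 1e-10)
  }
})
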