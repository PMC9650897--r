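test_that("max overlap matches the KLF4 cotarget geometry and identity cases", {
  # miR-128-3p vs miR-148a-3p 7mer-m8 site sequences
  res <- max_overlap("CACUGUG", "UGCACUG")
  expect_equal(res$k, 5L)
  expect_equal(res$merged, "UGCACUGUG")
  expect_equal(nchar(res$merged), 9L)
  # their 8mer sites cannot overlap at all
  expect_equal(max_overlap("CACUGUGA", "UGCACUGA")$k, 0L)
  expect_equal(max_overlap("CACUGUG", "CACUGUG")$k, 7L)
  expect_error(max_overlap("", "ACGU"), "non-empty")
})

test_that("max overlap is symmetric in k and agrees with the sliding oracle", {
  set.seed(8)
  for (st in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    s <- site_match(replicate(40, random_seed7()), st)$sequence
    for (i in 1:40) {
      s1 <- sample(s, 1)
      s2 <- sample(s, 1)
      k12 <- max_overlap(s1, s2)$k
      expect_identical(k12, max_overlap(s2, s1)$k)
      expect_identical(k12, oracle_max_overlap(s1, s2))
    }
  }
})

test_that("pair-overlap distribution equals exhaustive pair enumeration", {
  set.seed(12)
  seeds <- unique(replicate(10, random_seed7()))
  cat0 <- toy_catalog(seeds)
  dist <- pair_overlap_distribution(cat0, "7mer-m8")
  expect_equal(sum(dist$occurrence), 1)
  expect_equal(sum(dist$n_pairs), choose(length(seeds), 2))
  # brute force over all unordered pairs
  s <- site_match(seeds, "7mer-m8")$sequence
  ks <- c()
  for (i in seq_along(s)) for (j in seq_along(s)) {
    if (i < j) ks <- c(ks, oracle_max_overlap(s[i], s[j]))
  }
  expect_equal(dist$n_pairs, tabulate(ks + 1L, nbins = 8L))
  # permutation invariance
  dist2 <- pair_overlap_distribution(cat0[sample(nrow(cat0)), ], "7mer-m8")
  expect_equal(dist2$occurrence, dist$occurrence)
  expect_error(pair_overlap_distribution(toy_catalog("CACAGUG"), "7mer-m8"),
               "at least 2")
})

test_that("GC-matched random seeds preserve per-seed GC counts and determinism", {
  set.seed(3)
  seeds <- replicate(100, random_seed7())
  gc <- function(x) nchar(gsub("[^GC]", "", x))
  r1 <- gc_matched_random_seeds(seeds, rng_seed = 99)
  r2 <- gc_matched_random_seeds(seeds, rng_seed = 99)
  expect_identical(r1, r2)
  expect_equal(gc(r1), gc(seeds))           # per-seed GC preserved
  expect_equal(length(r1), length(seeds))
  expect_true(all(grepl("^[ACGU]{7}$", r1)))
  expect_equal(gc_matched_random_seeds("CACAGUG") |> gc(), 4L)
})

test_that("empirical p honours the add-one estimator and its bounds", {
  set.seed(21)
  seeds <- replicate(25, random_seed7())
  cat0 <- toy_catalog(unique(seeds))
  rt <- randomization_test(cat0, "7mer-m8", B = 50, rng_seed = 5)
  expect_length(rt$null_freqs, 50L)
  expect_equal(rt$p_emp,
               (1 + sum(rt$null_freqs >= rt$observed_freq)) / 51)
  expect_gte(rt$p_emp, 1 / 51)
  expect_lte(rt$p_emp, 1)
  expect_equal(rt$neg_log10_p, -log10(rt$p_emp))
  # zero observed frequency is never significant
  if (rt$observed_freq == 0) expect_equal(rt$p_emp, 1)
  # determinism under a fixed seed
  rt2 <- randomization_test(cat0, "7mer-m8", B = 50, rng_seed = 5)
  expect_identical(rt$null_freqs, rt2$null_freqs)
  expect_error(randomization_test(cat0, "7mer-m8", B = 0), "positive")
})

test_that("planted extensive pairs are detected against a strong null", {
  cfg <- sim_config(rng_seed = 31, n_mirnas = 40,
                    n_planted_extensive_pairs = 10, n_genes = 100)
  cat0 <- simulate_mirna_catalog(cfg)
  rt <- randomization_test(cat0, "7mer-m8", group = "broadly_conserved",
                           B = 200, rng_seed = 32)
  expect_equal(rt$p_emp, 1 / 201)  # observed exceeds every null
})

test_that("extensive pair calling recovers exactly the planted pairs", {
  cfg <- sim_config(rng_seed = 17, n_mirnas = 30,
                    n_planted_extensive_pairs = 5, n_genes = 100)
  cat0 <- simulate_mirna_catalog(cfg)
  truth <- attr(cat0, "planted_pairs")
  found <- extensive_pairs(cat0) |>
    dplyr::distinct(family_a, family_b)
  norm <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(norm(found$family_a, found$family_b),
                  norm(truth$family_a, truth$family_b))
  # unrelated homopolymer seeds share no overlap
  quiet_pairs <- suppressMessages(
    extensive_pairs(toy_catalog(c("AAAAAAA", "CCCCCCC")))
  )
  expect_equal(nrow(quiet_pairs), 0L)
})

test_that("cluster/multi-locus association matches exact Fisher enumeration", {
  # planted 2x2 [[8,2],[2,8]]
  cat0 <- toy_catalog(
    replicate(20, random_seed7()),
    in_cluster = rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 2, 8)),
    n_loci = rep(c(2L, 1L, 2L, 1L), c(8, 2, 2, 8))
  )
  pairs <- tibble::tibble(family_a = cat0$family_id[1:5],
                          family_b = cat0$family_id[6:10],
                          site_type = "7mer-m8", k = 6L)
  res <- mirna_gene_association(pairs, cat0)
  expect_equal(res$p_value[res$annotation == "cluster"],
               oracle_fisher_greater(8, 2, 2, 8), tolerance = 1e-10)
  expect_equal(res$p_value[res$annotation == "cluster"], 0.0115, tolerance = 1e-2)
  expect_equal(res$odds_ratio[res$annotation == "cluster"], 16)
  # balanced table: no association
  cat1 <- toy_catalog(
    replicate(20, random_seed7()),
    in_cluster = rep(c(TRUE, FALSE), 10)
  )
  pairs1 <- tibble::tibble(family_a = cat1$family_id[1:5],
                           family_b = cat1$family_id[6:10],
                           site_type = "7mer-m8", k = 6L)
  res1 <- suppressWarnings(mirna_gene_association(pairs1, cat1))
  expect_equal(res1$odds_ratio[res1$annotation == "cluster"], 1)
  expect_gt(res1$p_value[res1$annotation == "cluster"], 0.5)
  # empty margin: undefined OR, p = 1, warning
  cat2 <- toy_catalog(replicate(6, random_seed7()),
                      in_cluster = rep(FALSE, 6))
  expect_warning(expect_warning(  # one warning per degenerate annotation
    res2 <- mirna_gene_association(pairs1[0, ], cat2),
    "empty margin"), "empty margin")
  expect_true(is.na(res2$odds_ratio[res2$annotation == "cluster"]))
  expect_equal(res2$p_value[res2$annotation == "cluster"], 1)
})

test_that("planted cluster enrichment (OR = 4) is recovered across simulations", {
  # cluster probabilities 0.5 vs 0.2 plant a population odds ratio of 4;
  # the estimate should land in [2, 8] in at least 90% of simulations
  ors <- vapply(1:30, function(r) {
    cfg <- sim_config(rng_seed = 500 + r, n_mirnas = 200,
                      n_planted_extensive_pairs = 50, n_genes = 100,
                      cluster_prob = c(planted = 0.5, other = 0.2))
    cat0 <- simulate_mirna_catalog(cfg)
    res <- suppressMessages(mirna_gene_association(extensive_pairs(cat0), cat0))
    res$odds_ratio[res$annotation == "cluster"]
  }, numeric(1))
  expect_gte(sum(ors >= 2 & ors <= 8), 27L)
})
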