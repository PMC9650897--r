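test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_mirnas = 1), "n_mirnas")
  expect_error(sim_config(n_mirnas = 6, n_planted_extensive_pairs = 4),
               "infeasible")
  expect_error(sim_config(sigma = 0), "sigma")
  expect_error(sim_config(beta = c("8mer" = -0.1, "7mer-m8" = -0.4,
                                   "7mer-A1" = -0.35, "6mer" = -0.15)),
               "beta")
  expect_error(sim_config(w_shallow = 1.4), "probabilities")
  expect_error(sim_config(overlap_fraction = 0.6, neighborhood_fraction = 0.5),
               "< 1")
})

test_that("one seed fixes every generated table", {
  cfg <- sim_config(rng_seed = 5, n_mirnas = 16, n_planted_extensive_pairs = 3,
                    n_genes = 150)
  a1 <- simulate_mirna_catalog(cfg)
  a2 <- simulate_mirna_catalog(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_sites_and_conservation(cfg, a1)
  s2 <- simulate_sites_and_conservation(cfg, a1)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$presence, s2$presence)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  pp <- attr(a1, "planted_pairs")
  e1 <- simulate_expression(cfg, s1$sites, pp$family_a[1], pp$family_b[1])
  e2 <- simulate_expression(cfg, s1$sites, pp$family_a[1], pp$family_b[1])
  expect_identical(e1, e2)
  h1 <- simulate_hi(cfg, unique(s1$sites$gene_id))
  h2 <- simulate_hi(cfg, unique(s1$sites$gene_id))
  expect_identical(h1, h2)
  # a different seed changes the catalog
  expect_false(identical(
    a1$seed, simulate_mirna_catalog(cfg, rng_seed = 6)$seed
  ))
})

test_that("generated sites respect the site-table contract", {
  cfg <- sim_config(rng_seed = 13, n_mirnas = 20, n_planted_extensive_pairs = 4,
                    n_genes = 300)
  cat0 <- simulate_mirna_catalog(cfg)
  sim <- simulate_sites_and_conservation(cfg, cat0)
  s <- sim$sites
  expect_true(all(s$end - s$start == extensive_threshold(s$site_type) + 2L))
  expect_true(all(s$start >= 0))
  expect_false(anyDuplicated(s$site_id) > 0)
  # conserved flags agree with the BLS cutoffs on the generated tree
  calls <- classify_sites(s)
  expect_identical(calls$conserved, s$conserved)
  # species counts agree with the emitted presence vectors
  expect_equal(species_count(sim$presence)$n_species, s$n_species)
  # depth ranges: non-conserved below 20 species, conserved at or above
  expect_true(all(s$n_species[!s$conserved] <= 19))
  expect_true(all(s$n_species[s$conserved] >= 20))
})

test_that("planted cotarget fractions are recovered from the site table", {
  cfg <- sim_config(rng_seed = 29, n_mirnas = 30, n_planted_extensive_pairs = 10,
                    n_genes = 4000)
  cat0 <- simulate_mirna_catalog(cfg)
  sim <- simulate_sites_and_conservation(cfg, cat0)
  ann <- annotate_cotargets(sim$sites)
  dat <- dplyr::left_join(sim$sites, ann, by = "site_id") |>
    dplyr::filter(conserved)
  expect_equal(mean(dat$seed_overlap != "none"), cfg$overlap_fraction,
               tolerance = 0.01 / cfg$overlap_fraction)
  expect_equal(mean(dat$neighborhood != "none"), cfg$neighborhood_fraction,
               tolerance = 0.01 / cfg$neighborhood_fraction)
})

test_that("expression generator honours the additive model", {
  # noiseless limit: a single 7mer-m8 site yields exactly beta
  cfg <- sim_config(rng_seed = 3, n_mirnas = 4, n_planted_extensive_pairs = 1,
                    n_genes = 10, sigma = 1e-9)
  sites <- tibble::tibble(
    site_id = "s1", gene_id = "g00001", utr_id = "g00001:utr",
    start = 100L, end = 107L, family_id = "fam-001",
    site_type = "7mer-m8", conserved = TRUE
  )
  expr <- simulate_expression(cfg, sites, "fam-001", "fam-002",
                              genes = c("g00001", "g00002"))
  e <- function(g, cond) expr$log2fc[expr$gene_id == g & expr$condition == cond]
  expect_equal(e("g00001", "fam-001"), cfg$beta[["7mer-m8"]], tolerance = 1e-6)
  expect_equal(e("g00002", "fam-001"), 0, tolerance = 1e-6)
  # the double response sums the single responses when delta = 0
  expect_equal(e("g00001", "both"),
               e("g00001", "fam-001") + e("g00001", "fam-002"),
               tolerance = 1e-6)
  # fdr column is a valid probability
  expect_true(all(expr$fdr >= 0 & expr$fdr <= 1))
})

test_that("additivity test is calibrated on generator output with delta = 0", {
  cfg <- sim_config(rng_seed = 1, n_mirnas = 6, n_planted_extensive_pairs = 1,
                    n_genes = 120, sites_per_gene_mean = 1.5)
  cat0 <- simulate_mirna_catalog(cfg)
  sim <- simulate_sites_and_conservation(cfg, cat0)
  pp <- attr(cat0, "planted_pairs")
  ps <- vapply(1:100, function(r) {
    expr <- simulate_expression(cfg, sim$sites, pp$family_a[1], pp$family_b[1],
                                rng_seed = 7000 + r)
    wide <- tidyr::pivot_wider(expr, id_cols = "gene_id",
                               names_from = "condition", values_from = "log2fc")
    additivity_test(wide[[pp$family_a[1]]], wide[[pp$family_b[1]]],
                    wide[["both"]])$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.93)
})

test_that("haploinsufficiency generator calibrates at zero shift and clips to [0,1]", {
  cfg <- sim_config(rng_seed = 2)
  genes <- sprintf("g%03d", 1:200)
  # zero shift: the comparison p-value is approximately uniform
  cfg0 <- sim_config(rng_seed = 2, hi_shift = 0)
  gr <- tibble::tibble(gene_id = genes,
                       group = rep(c("conserved_overlap", "other"), each = 100))
  ps <- vapply(1:200, function(r) {
    hi <- simulate_hi(cfg0, genes, shifted_genes = genes[1:100],
                      rng_seed = 5000 + r)
    hi_comparison(gr, hi)$p_value
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  hi <- simulate_hi(cfg, genes, shifted_genes = genes[1:100])
  expect_true(all(hi$p_hi >= 0 & hi$p_hi <= 1))
})
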