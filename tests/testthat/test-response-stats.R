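make_expr <- function(gene_id, log2fc, fdr = 0.5, condition = "both") {
  tibble::tibble(gene_id = gene_id, condition = condition,
                 log2fc = log2fc, fdr = rep_len(fdr, length(gene_id)))
}

test_that("downregulation summary reproduces hand-computed 2x2 odds ratios", {
  genes <- sprintf("g%03d", 1:200)
  groups <- tibble::tibble(gene_id = genes,
                           group = rep(c("conserved_overlap", "8mer"), each = 100))
  # group A 30/100 down, reference 10/100 down
  down <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  expr <- make_expr(genes, log2fc = ifelse(down, -1, 0.1),
                    fdr = ifelse(down, 0.01, 0.5))
  res <- downregulation_summary(expr, groups, "both", reference = "8mer")
  a <- res[res$group == "conserved_overlap", ]
  expect_equal(a$fraction_down, 0.30)
  expect_equal(res$fraction_down[res$group == "8mer"], 0.10)
  expect_equal(a$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-10)
  expect_equal(a$odds_ratio, 3.857, tolerance = 1e-3)
  # identical groups give OR 1, and the OR inverts under group swap
  res_swap <- downregulation_summary(expr, groups, "both",
                                     reference = "conserved_overlap")
  expect_equal(res_swap$odds_ratio[res_swap$group == "8mer"],
               1 / a$odds_ratio, tolerance = 1e-10)
  expect_equal(res_swap$odds_ratio[res_swap$group == "conserved_overlap"], 1)
})

test_that("downregulation thresholds follow the FDR < 0.05 definition", {
  expr <- make_expr(c("g1", "g2", "g3", "g4"),
                    log2fc = c(-1, -1, 1, -1),
                    fdr = c(0.04, 0.06, 0.01, 0.05))
  groups <- tibble::tibble(gene_id = expr$gene_id, group = "8mer")
  res <- downregulation_summary(expr, groups, "both", reference = "8mer")
  # only g1 passes: negative FC with FDR strictly below 0.05
  expect_equal(res$n_down, 1L)
  res_lenient <- downregulation_summary(expr, groups, "both",
                                        fdr_threshold = 0.1, reference = "8mer")
  expect_equal(res_lenient$n_down, 3L)  # g1, g2 and g4 pass at FDR < 0.1
})

test_that("planted susceptibility of overlap targets yields OR > 1", {
  hits <- 0L
  for (r in 1:30) {
    withr::local_seed(900 + r)
    n <- 500
    genes <- sprintf("g%04d", 1:(2 * n))
    groups <- tibble::tibble(
      gene_id = genes,
      group = rep(c("conserved_overlap", "8mer"), each = n)
    )
    # overlap targets carry an extra susceptibility shift
    shift <- rep(c(-0.5, -0.15), each = n)
    fc <- shift + stats::rnorm(2 * n, 0, 0.25)
    p <- stats::p.adjust(2 * stats::pnorm(-abs(fc) / 0.25), "BH")
    expr <- make_expr(genes, fc, p)
    res <- suppressWarnings(
      downregulation_summary(expr, groups, "both", reference = "8mer")
    )
    if (res$odds_ratio[res$group == "conserved_overlap"] > 1) hits <- hits + 1L
  }
  expect_gte(hits, 29L)  # >= 95% of simulations
})

test_that("rank-sum p-values match exhaustive enumeration on small samples", {
  x <- c(-1, -2, -3)
  y <- c(0, 0.1, 0.2)
  expr <- make_expr(c("a1", "a2", "a3", "b1", "b2", "b3"), c(x, y))
  ft <- fc_shift_test(expr, c("a1", "a2", "a3"), c("b1", "b2", "b3"), "both")
  expect_equal(ft$p_value, 1 / 20)          # C(6,3) = 20 orderings
  expect_equal(ft$p_value, oracle_wilcox_less(x, y))
  # random no-tie cases against the enumeration oracle
  set.seed(61)
  for (i in 1:15) {
    xr <- round(stats::rnorm(sample(3:6, 1)), 4)
    yr <- round(stats::rnorm(sample(3:6, 1)), 4)
    er <- make_expr(c(sprintf("x%d", seq_along(xr)), sprintf("y%d", seq_along(yr))),
                    c(xr, yr))
    expect_equal(
      fc_shift_test(er, sprintf("x%d", seq_along(xr)),
                    sprintf("y%d", seq_along(yr)), "both")$p_value,
      oracle_wilcox_less(xr, yr), tolerance = 1e-10
    )
  }
  expect_error(fc_shift_test(expr, c("a1"), c("a1", "b1"), "both"), "disjoint")
})

test_that("site-type hierarchy orders the fold-change shifts", {
  cfg <- sim_config(rng_seed = 70, n_mirnas = 6, n_planted_extensive_pairs = 1,
                    n_genes = 3000, sites_per_gene_mean = 0.8)
  cat0 <- simulate_mirna_catalog(cfg)
  sim <- simulate_sites_and_conservation(cfg, cat0)
  fam <- attr(cat0, "planted_pairs")$family_a[1]
  fam_b <- attr(cat0, "planted_pairs")$family_b[1]
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  expr <- simulate_expression(cfg, sim$sites, fam, fam_b, genes = genes)
  e <- dplyr::filter(expr, condition == fam)
  # genes carrying exactly one site of the family, of the given type
  fam_sites <- dplyr::filter(sim$sites, family_id == fam)
  counts <- table(fam_sites$gene_id)
  single <- names(counts)[counts == 1]
  site_med <- function(st) {
    g <- fam_sites$gene_id[fam_sites$site_type == st &
                             fam_sites$gene_id %in% single]
    stats::median(e$log2fc[e$gene_id %in% g])
  }
  m8 <- site_med("8mer"); m7 <- site_med("7mer-m8"); m6 <- site_med("6mer")
  expect_lt(m8, m7)
  expect_lt(m7, m6)
  expect_lt(m6, 0)
})

test_that("log-additivity arithmetic and degenerate inputs behave", {
  res <- additivity_test(-0.5, -0.3, -0.8)
  expect_equal(res$pairs$expected, -0.8)
  expect_equal(res$pairs$difference, 0)
  ident <- additivity_test(c(-0.5, -0.2), c(-0.3, -0.1), c(-0.8, -0.3))
  expect_equal(ident$median_difference, 0)
  expect_equal(ident$p_value, 1)
  expect_error(additivity_test(1:3, 1:2, 1:3), "equal lengths")
})

test_that("additivity test is calibrated under delta = 0 and powered at delta = -0.5", {
  alpha <- 0.05
  nsim <- 500
  # type-I error under the purely additive model
  withr::local_seed(314)
  p0 <- replicate(nsim, {
    a <- stats::rnorm(20, -0.5, 0.1)
    b <- stats::rnorm(20, -0.3, 0.1)
    d <- a + b + stats::rnorm(20, 0, 0.1)
    additivity_test(a, b, d)$p_value
  })
  expect_gte(mean(p0 < alpha), alpha - 0.02)
  expect_lte(mean(p0 < alpha), alpha + 0.02)
  # power against a cooperative interaction delta = -0.5, sigma = 0.1, n = 20
  p1 <- replicate(100, {
    a <- stats::rnorm(20, -0.5, 0.1)
    b <- stats::rnorm(20, -0.3, 0.1)
    d <- a + b - 0.5 + stats::rnorm(20, 0, 0.1)
    additivity_test(a, b, d, alternative = "less")$p_value
  })
  expect_gte(mean(p1 < alpha), 0.9)
})

test_that("haploinsufficiency comparison is exact on small samples and powered", {
  groups <- tibble::tibble(gene_id = c("a1", "a2", "b1", "b2"),
                           group = rep(c("conserved_overlap", "other"), each = 2))
  hi <- tibble::tibble(gene_id = groups$gene_id, p_hi = c(0.9, 0.8, 0.1, 0.2))
  res <- hi_comparison(groups, hi)
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-10)  # C(4,2) = 6
  # unmapped genes are dropped with a notice
  expect_message(
    hi_comparison(dplyr::bind_rows(groups,
                                   tibble::tibble(gene_id = "zz", group = "other")),
                  hi),
    "missing"
  )
  expect_error(
    hi_comparison(tibble::tibble(gene_id = "q", group = "conserved_overlap"), hi),
    "no mapped genes"
  )
  # planted +0.2 shift at n = 200/group detected in >= 95% of simulations
  cfg <- sim_config(rng_seed = 1)
  hits <- 0L
  for (r in 1:30) {
    genes <- sprintf("g%03d", 1:400)
    hi_r <- simulate_hi(cfg, genes, shifted_genes = genes[1:200],
                        rng_seed = 4000 + r)
    gr <- tibble::tibble(gene_id = genes,
                         group = rep(c("conserved_overlap", "other"), each = 200))
    if (hi_comparison(gr, hi_r)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 29L)
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(SETA = universe[1:5])
  query <- c(universe[c(1, 2, 3)], universe[10])  # overlap 3 of query 4
  res <- gene_set_enrichment(query, sets, universe)
  expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(res$n_overlap, 3L)
  # random configurations against the enumeration oracle
  set.seed(91)
  for (i in 1:15) {
    N <- sample(10:25, 1)
    uni <- sprintf("u%02d", 1:N)
    st <- sample(uni, sample(2:(N - 2), 1))
    qu <- sample(uni, sample(2:(N - 2), 1))
    ov <- length(intersect(st, qu))
    expect_equal(
      gene_set_enrichment(qu, list(S = st), uni)$p_value,
      oracle_hyper_upper(ov, length(st), N, length(qu)),
      tolerance = 1e-12
    )
  }
  # disjoint query: overlap 0, p = 1 (tail includes the zero-overlap case)
  res0 <- gene_set_enrichment(universe[10:12], list(SETA = universe[1:5]), universe)
  expect_equal(res0$n_overlap, 0L)
  expect_equal(res0$p_value, 1)
  # query = set is the extremal overlap with the smallest possible p
  res1 <- gene_set_enrichment(universe[1:5], list(SETA = universe[1:5]), universe)
  expect_equal(res1$n_overlap, 5L)
  expect_equal(res1$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(gene_set_enrichment(character(0), sets, universe), "empty query")
  expect_error(gene_set_enrichment("g01", sets, character(0)), "empty universe")
})

test_that("enrichment q-values apply Benjamini-Hochberg across sets", {
  universe <- sprintf("g%02d", 1:30)
  sets <- list(A = universe[1:6], B = universe[7:12], C = universe[13:18])
  res <- gene_set_enrichment(universe[1:6], sets, universe)
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
})
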