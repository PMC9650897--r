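# Expression-response statistics over target groups, log-additivity,
# haploinsufficiency association, and gene-set enrichment.

# Wilcoxon rank-sum / signed-rank p-value with reproducible small-sample
# behaviour: exact distribution when the smaller sample has <= 10
# observations and there are no ties, otherwise the normal approximation
# with continuity (and tie) correction.
#' @keywords internal
#' @noRd
wilcox_p <- function(x, y, alternative, paired = FALSE) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty sample in rank test", call. = FALSE)
  }
  if (paired) {
    d <- x - y
    exact <- length(d) <= 10L && !any(d == 0) && !anyDuplicated(abs(d))
    suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                         exact = exact, correct = TRUE)$p.value
    )
  } else {
    exact <- min(length(x), length(y)) <= 10L && !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative,
                         exact = exact, correct = TRUE)$p.value
    )
  }
}

#' @keywords internal
#' @noRd
expr_condition <- function(expr, condition) {
  needed <- c("gene_id", "condition", "log2fc", "fdr")
  missing <- setdiff(needed, names(expr))
  if (length(missing) > 0L) {
    stop(sprintf("expression table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- dplyr::filter(expr, .data$condition == !!condition)
  if (nrow(out) == 0L) {
    stop(sprintf("no rows for condition '%s'", condition), call. = FALSE)
  }
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE)) {
    stop("fdr values must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Downregulation summary per target group
#'
#' For one transfection condition, counts significantly downregulated genes
#' (log2 fold change < 0 and FDR below threshold) in each target group, and
#' reports each group's odds ratio of downregulation against a pooled
#' reference group (by default the 8mer + 7mer targets, mirroring the
#' "other 8/7mer target" reference). A Haldane-Anscombe 0.5 correction is
#' applied when a 2x2 cell is zero. A one-tailed rank-sum p-value for the
#' group's fold changes being more negative than the reference is included.
#'
#' @param expr Long expression tibble: `gene_id`, `condition`, `log2fc`,
#'   `fdr` (see [read_expression_table()]).
#' @param groups Tibble with `gene_id` and `group` (e.g. [gene_groups()]
#'   filtered to one family).
#' @param condition Condition label to summarise.
#' @param fdr_threshold FDR cutoff defining downregulation (default 0.05;
#'   0.1 is the other threshold in common use).
#' @param reference Group labels pooled into the odds-ratio reference.
#' @return A tibble with one row per group: `group`, `n_genes`, `n_down`,
#'   `fraction_down`, `odds_ratio`, `wilcoxon_p`.
#' @export
downregulation_summary <- function(expr, groups, condition,
                                   fdr_threshold = 0.05,
                                   reference = c("8mer", "7mer")) {
  e <- expr_condition(expr, condition)
  dat <- dplyr::inner_join(groups, e, by = "gene_id") |>
    dplyr::mutate(down = .data$log2fc < 0 & .data$fdr < fdr_threshold)
  skipped <- setdiff(unique(as.character(groups$group)), unique(as.character(dat$group)))
  if (length(skipped) > 0L) {
    warning(sprintf("group(s) with no expression data skipped: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  ref <- dplyr::filter(dat, .data$group %in% reference)
  ref_down <- sum(ref$down)
  ref_n <- nrow(ref)
  dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_down = sum(.data$down),
      fraction_down = mean(.data$down),
      odds_ratio = haldane_or(sum(.data$down), dplyr::n() - sum(.data$down),
                              ref_down, ref_n - ref_down),
      wilcoxon_p = if (ref_n > 0L)
        wilcox_p(.data$log2fc, ref$log2fc, alternative = "less") else NA_real_,
      .groups = "drop"
    )
}

# odds ratio of (a/b) vs (c/d) with Haldane-Anscombe correction on zero cells
#' @keywords internal
#' @noRd
haldane_or <- function(a, b, c, d) {
  if (c + d == 0L) return(NA_real_)
  if (any(c(a, b, c, d) == 0L)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a / b) / (c / d)
}

#' Fold-change shift test of a target group against a background
#'
#' One-tailed Wilcoxon rank-sum test of whether a target group's log2 fold
#' changes are shifted downward relative to a background gene set (typically
#' genes with no sites), plus the empirical CDF curves of both sets.
#'
#' @param expr Long expression tibble.
#' @param group_genes,background_genes Disjoint character vectors of gene ids.
#' @param condition Condition label.
#' @return An object of class `"fc_shift_test"`: list with `p_value`,
#'   `n_group`, `n_background`, `median_group`, `median_background`,
#'   `condition`, and `curves` (a tibble of CDF coordinates per set).
#' @export
fc_shift_test <- function(expr, group_genes, background_genes, condition) {
  if (length(intersect(group_genes, background_genes)) > 0L) {
    stop("group and background gene sets must be disjoint", call. = FALSE)
  }
  e <- expr_condition(expr, condition)
  x <- e$log2fc[e$gene_id %in% group_genes]
  y <- e$log2fc[e$gene_id %in% background_genes]
  if (length(x) == 0L || length(y) == 0L) {
    stop("group or background has no expression data", call. = FALSE)
  }
  curves <- dplyr::bind_rows(
    tibble::tibble(set = "group", log2fc = sort(x),
                   cdf = seq_along(x) / length(x)),
    tibble::tibble(set = "background", log2fc = sort(y),
                   cdf = seq_along(y) / length(y))
  )
  structure(
    list(
      p_value = wilcox_p(x, y, alternative = "less"),
      n_group = length(x),
      n_background = length(y),
      median_group = stats::median(x),
      median_background = stats::median(y),
      condition = condition,
      curves = curves
    ),
    class = "fc_shift_test"
  )
}

#' @export
print.fc_shift_test <- function(x, ...) {
  cat(sprintf(
    "Fold-change shift test (%s)\n  group n = %d (median %.3f), background n = %d (median %.3f)\n  one-tailed rank-sum p = %.4g\n",
    x$condition, x$n_group, x$median_group, x$n_background,
    x$median_background, x$p_value
  ))
  invisible(x)
}

#' Log-additivity test of double-miRNA repression
#'
#' Under log-additivity, the expected double-transfection log2 fold change
#' is the sum of the two single-miRNA log2 fold changes. This test compares
#' observed doubles against that expectation with a paired Wilcoxon
#' signed-rank test; deviation indicates cooperativity (more negative than
#' expected) or competition (less negative).
#'
#' @param fc_single_a,fc_single_b,fc_double Equal-length paired vectors of
#'   log2 fold changes.
#' @param alternative `"two.sided"` (default), `"less"` (cooperativity:
#'   observed below expected), or `"greater"`.
#' @return An object of class `"additivity_test"`: list with `pairs` (tibble
#'   of expected/observed/difference), `n`, `median_difference`,
#'   `alternative`, `p_value`.
#' @export
additivity_test <- function(fc_single_a, fc_single_b, fc_double,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(fc_double)
  if (length(fc_single_a) != n || length(fc_single_b) != n) {
    stop("fc_single_a, fc_single_b and fc_double must have equal lengths",
         call. = FALSE)
  }
  if (n == 0L) stop("need at least one pair", call. = FALSE)
  expected <- fc_single_a + fc_single_b
  pairs <- tibble::tibble(
    expected = expected,
    observed = fc_double,
    difference = fc_double - expected
  )
  p <- if (all(pairs$difference == 0)) 1 else
    wilcox_p(fc_double, expected, alternative = alternative, paired = TRUE)
  structure(
    list(
      pairs = pairs,
      n = n,
      median_difference = stats::median(pairs$difference),
      alternative = alternative,
      p_value = p
    ),
    class = "additivity_test"
  )
}

#' @export
print.additivity_test <- function(x, ...) {
  cat(sprintf(
    "Log-additivity test (n = %d pairs, %s)\n  median observed - expected: %.4f log2 units\n  paired signed-rank p = %.4g\n",
    x$n, x$alternative, x$median_difference, x$p_value
  ))
  invisible(x)
}

#' Haploinsufficiency-probability comparison between target groups
#'
#' One-tailed Wilcoxon rank-sum tests of whether a focal target group
#' (e.g. conserved-overlap targets, or the deep conservation class) has
#' higher haploinsufficiency probabilities than each other group. Genes
#' absent from the probability table are dropped with a notice.
#'
#' @param groups Tibble with `gene_id` and `group`.
#' @param hi Tibble with `gene_id` and `p_hi` in `[0, 1]`.
#' @param focal Focal group label (default `"conserved_overlap"`).
#' @return A tibble with one row per comparison: `group_a` (focal),
#'   `group_b`, `n_a`, `n_b`, `median_a`, `median_b`, `p_value`.
#' @export
hi_comparison <- function(groups, hi, focal = "conserved_overlap") {
  if (any(hi$p_hi < 0 | hi$p_hi > 1, na.rm = TRUE)) {
    stop("p_hi must lie in [0, 1]", call. = FALSE)
  }
  dat <- dplyr::inner_join(groups, hi, by = "gene_id")
  n_drop <- nrow(groups) - nrow(dat)
  if (n_drop > 0L) {
    message(sprintf("%d gene(s) missing from the haploinsufficiency table dropped", n_drop))
  }
  a <- dat$p_hi[dat$group == focal]
  if (length(a) == 0L) {
    stop(sprintf("focal group '%s' has no mapped genes", focal), call. = FALSE)
  }
  others <- setdiff(unique(as.character(dat$group)), focal)
  purrr::map_dfr(others, function(g) {
    b <- dat$p_hi[dat$group == g]
    tibble::tibble(
      group_a = focal, group_b = g,
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), median_b = stats::median(b),
      p_value = wilcox_p(a, b, alternative = "greater")
    )
  })
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each annotated gene set, within a gene universe:
#' `p = P(X >= observed overlap)`. Sets are intersected with the universe;
#' p-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param query_genes Character vector of query genes (must be drawn from
#'   the universe; genes outside it are dropped with a notice).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector: the gene universe (e.g. all expressed
#'   genes).
#' @return A tibble with one row per set: `set_name`, `set_size`,
#'   `query_size`, `n_overlap`, `p_value`, `q_value`, `overlap_genes`
#'   (list-column).
#' @export
gene_set_enrichment <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    message(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query", call. = FALSE)
  if (length(gene_sets) == 0L) stop("no gene sets", call. = FALSE)
  res <- purrr::imap_dfr(gene_sets, function(genes, name) {
    set <- intersect(unique(genes), universe)
    ov <- intersect(set, query)
    p <- stats::phyper(length(ov) - 1L, length(set),
                       length(universe) - length(set), length(query),
                       lower.tail = FALSE)
    tibble::tibble(
      set_name = name,
      set_size = length(set),
      query_size = length(query),
      n_overlap = length(ov),
      p_value = p,
      overlap_genes = list(sort(ov))
    )
  })
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::relocate(res, "q_value", .after = "p_value") |>
    dplyr::arrange(.data$p_value)
}
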