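# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a seed-overlap randomization test
#'
#' One row per null randomization replicate, with the observed frequency
#' alongside for plotting.
#'
#' @param x An `overlap_test` object from [randomization_test()].
#' @param ... Unused.
#' @return A tibble: `replicate`, `null_freq`, `observed_freq`.
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(
    replicate = seq_along(x$null_freqs),
    null_freq = x$null_freqs,
    observed_freq = x$observed_freq
  )
}

#' Glance at a seed-overlap randomization test
#'
#' @inheritParams tidy.overlap_test
#' @return A one-row tibble: `group`, `site_type`, `n_families`, `n_pairs`,
#'   `observed_freq`, `null_mean`, `B`, `p_emp`, `neg_log10_p`.
#' @export
glance.overlap_test <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    site_type = x$site_type,
    n_families = x$n_families,
    n_pairs = x$n_pairs,
    observed_freq = x$observed_freq,
    null_mean = mean(x$null_freqs),
    B = x$B,
    p_emp = x$p_emp,
    neg_log10_p = x$neg_log10_p
  )
}

#' Tidy a log-additivity test
#'
#' @param x An `additivity_test` object.
#' @param ... Unused.
#' @return The per-pair tibble: `expected`, `observed`, `difference`.
#' @export
tidy.additivity_test <- function(x, ...) x$pairs

#' Glance at a log-additivity test
#'
#' @inheritParams tidy.additivity_test
#' @return A one-row tibble: `n`, `median_difference`, `alternative`,
#'   `p_value`.
#' @export
glance.additivity_test <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    median_difference = x$median_difference,
    alternative = x$alternative,
    p_value = x$p_value
  )
}

#' Tidy a fold-change shift test
#'
#' @param x An `fc_shift_test` object.
#' @param ... Unused.
#' @return The CDF-curve tibble: `set`, `log2fc`, `cdf`.
#' @export
tidy.fc_shift_test <- function(x, ...) x$curves

#' Glance at a fold-change shift test
#'
#' @inheritParams tidy.fc_shift_test
#' @return A one-row tibble of sample sizes, medians and the p-value.
#' @export
glance.fc_shift_test <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    n_group = x$n_group,
    n_background = x$n_background,
    median_group = x$median_group,
    median_background = x$median_background,
    p_value = x$p_value
  )
}
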