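# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a seed-overlap randomization test
#'
#' Density of the null extensive-overlap frequencies with the observed
#' frequency as a vertical line.
#'
#' @param object An `overlap_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_test <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$null_freq)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_freq,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "extensive-overlap frequency",
      y = "null density",
      title = sprintf("%s, %s: p = %.3g", object$group, object$site_type,
                      object$p_emp)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a log-additivity test
#'
#' Observed double-miRNA repression against the log2-additive expectation,
#' with the identity line.
#'
#' @param object An `additivity_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.additivity_test <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "expected log2 FC (additive)",
      y = "observed log2 FC (double)",
      title = sprintf("median difference %.3f, p = %.3g",
                      object$median_difference, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fold-change shift test
#'
#' Cumulative distributions of the target group and background log2 fold
#' changes.
#'
#' @param object An `fc_shift_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_shift_test <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$log2fc, y = .data$cdf,
                               colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "log2 fold change", y = "cumulative fraction",
      title = sprintf("%s: one-tailed p = %.3g", object$condition,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-species conservation profiles
#'
#' Fraction of sites present in each species of the divergence-ordered
#' panel, one curve per site class.
#'
#' @param profiles A tibble from [conservation_profile()], optionally with a
#'   `class` column when several profiles are bound together.
#' @return A ggplot.
#' @export
plot_conservation_profile <- function(profiles) {
  aes <- if ("class" %in% names(profiles)) {
    ggplot2::aes(x = .data$panel_rank, y = .data$fraction,
                 colour = .data$class, group = .data$class)
  } else {
    ggplot2::aes(x = .data$panel_rank, y = .data$fraction, group = 1)
  }
  ggplot2::ggplot(profiles, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "species (panel order, reference first)",
      y = "fraction of sites present"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise maximum-overlap distribution
#'
#' Relative occurrence of each maximum overlap length across all family
#' pairs, with the extensive-overlap region shaded.
#'
#' @param dist A tibble from [pair_overlap_distribution()].
#' @return A ggplot.
#' @export
plot_overlap_distribution <- function(dist) {
  L <- max(dist$k)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$k, y = .data$occurrence)) +
    ggplot2::annotate("rect", xmin = L - 2.5, xmax = L - 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "firebrick") +
    ggplot2::geom_col(width = 0.8, fill = "grey40") +
    ggplot2::labs(x = "maximum overlap (nt)", y = "relative occurrence",
                  title = unique(dist$site_type)) +
    ggplot2::theme_minimal()
}
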