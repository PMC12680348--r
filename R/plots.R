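#' Plot an ABC posterior for the DFE mean
#'
#' Histogram of accepted `a*b` values (log10 axis) with the point estimate
#' marked.
#'
#' @param object A `dfe_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfe_posterior <- function(object, ...) {
  dat <- dplyr::filter(object$accepted, .data$mean_s > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_s, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "accepted mean s (a·b)", y = "count",
                  title = paste("DFE posterior,", object$class_key)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery report
#'
#' Per-repeat point estimates of the DFE mean against the simulated truth.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = factor(.data$repeat_id), y = .data$mean_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$truth[["mean_s"]],
                        colour = "firebrick", linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ABC repeat", y = "inferred mean s",
                  title = "DFE recovery across repeats (dashed = truth)") +
    ggplot2::theme_minimal()
}

#' Plot a locus-count-weighted DFE CDF
#'
#' @param cdf Tibble from [weighted_dfe_cdf()] (optionally with a `group`
#'   column to overlay several classes).
#' @return A ggplot object.
#' @export
plot_dfe_cdf <- function(cdf) {
  aes <- if ("group" %in% names(cdf)) {
    ggplot2::aes(x = .data$s, y = .data$cdf, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$s, y = .data$cdf)
  }
  ggplot2::ggplot(cdf, aes) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "selection coefficient s", y = "cumulative fraction of loci") +
    ggplot2::theme_minimal()
}

#' Plot mutation-model acceptance proportions
#'
#' @param object A `mutmodel_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutmodel_fit <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$candidate,
                               y = .data$acceptance_proportion)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "candidate mutation model", y = "ABC acceptance proportion") +
    ggplot2::theme_minimal()
}
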