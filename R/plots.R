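# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage curve
#'
#' Mean essential-gene hit count against guides per gene, one line per
#' caller, with +-1 s.e.m. error bars.
#'
#' @param object A `coverage_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_curve
#' @export
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_hits,
                                       colour = .data$caller)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_hits - .data$sem,
                                          ymax = .data$mean_hits + .data$sem)) +
    ggplot2::labs(x = "sgRNAs per gene", y = "essential genes detected",
                  colour = "caller") +
    ggplot2::theme_minimal()
}

#' Plot a control-fold-change mixture fit
#'
#' Histogram of the control fold changes with the four fitted component
#' densities (scaled by their weights) overlaid.
#'
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) {
  comp <- dplyr::arrange(object$components, .data$role)
  grid <- seq(min(object$data) - 1, max(object$data) + 1, length.out = 400)
  dens <- purrr::pmap_dfr(comp, function(role, role_label, weight, mean, sd, ...) {
    tibble::tibble(x = grid, density = weight * dnorm(grid, mean, sd),
                   role_label = role_label)
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(data = tibble::tibble(fc = object$data),
                            ggplot2::aes(x = .data$fc, y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85", colour = "grey70") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$role_label)) +
    ggplot2::labs(x = "control log2 fold change", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot fold-change ECDFs for guide subsets
#'
#' Step ECDFs of each subset's log2 fold changes on the shared fold-change
#' axis. Depleted subsets rise early (left); [ecdf_auc()] summarises the
#' same separation as a single rank-scale area.
#'
#' @param fc A fold-change tibble for the whole screen.
#' @param subsets Named list of guide-id vectors.
#' @return A ggplot.
#' @export
plot_ecdf <- function(fc, subsets) {
  df <- purrr::imap_dfr(subsets, function(ids, nm) {
    tibble::tibble(fc = fc$fc[fc$sgrna %in% ids], subset = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc, colour = .data$subset)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "log2 fold change", y = "ECDF") +
    ggplot2::theme_minimal()
}
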