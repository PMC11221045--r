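#' Plot a benthoscape raster
#'
#' @param raster A [bentho_raster()].
#' @return A ggplot.
#' @export
plot_benthoscape <- function(raster) {
  cells <- raster_cells(raster)
  cells$class <- substrate_factor(cells$code)
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "substrate") +
    ggplot2::theme_minimal()
}

#' Boxplot of relative selection strengths across reruns
#'
#' One box per substrate class over the rerun RSS draws, with the no-
#' selection line at RSS = 1 dashed: boxes left of it indicate reduced
#' odds of selecting the substrate relative to the reference, boxes right
#' of it increased odds.
#'
#' @param x A [rsf_resample_fit()] result.
#' @return A ggplot.
#' @export
plot_rss <- function(x) {
  stopifnot(inherits(x, "bs_rsf"))
  draws <- x$coefficients
  draws$rss <- exp(draws$estimate)
  ggplot2::ggplot(draws, ggplot2::aes(.data$rss, .data$term)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = paste0("relative selection strength vs ",
                             x$reference),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bs_rsf <- function(object, ...) plot_rss(object)

#' Point estimates and intervals for iSSF terms
#'
#' @param x A [fit_issf()] result.
#' @param interval `"boot"` (percentile) or `"wald"`.
#' @return A ggplot.
#' @export
plot_issf <- function(x, interval = c("boot", "wald")) {
  stopifnot(inherits(x, "bs_issf"))
  interval <- match.arg(interval)
  est <- x$estimates
  lo <- est[[paste0("conf.low.", interval)]]
  hi <- est[[paste0("conf.high.", interval)]]
  d <- tibble::tibble(term = est$term, estimate = est$estimate,
                      lo = lo, hi = hi)
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo,
                                         xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bs_issf <- function(object, ...) plot_issf(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
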