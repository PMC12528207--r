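#' Plot an SM correlation fit
#'
#' Scatter of the per-period Gompertz parameter points (`alpha` on the
#' horizontal axis, `m0 = exp(ln_m0)` on a log-scaled vertical axis), the SM
#' regression line, and the two parallel band lines through the extreme
#' residuals. At any `alpha`, the vertical ratio between the band lines on
#' the intensity scale equals the fit's L2/L1 band ratio. Period labels are
#' drawn beside the points when available.
#'
#' @param object An [fit_sm()] result.
#' @param labels Draw period labels (default `TRUE` when present).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sm_fit
#' @export
autoplot.sm_fit <- function(object, labels = TRUE, ...) {
  d <- object$data
  ar <- range(d$alpha)
  grid <- tibble(alpha = seq(ar[1], ar[2], length.out = 50)) %>%
    mutate(
      center = exp(object$YA - object$A_years * .data$alpha),
      upper = .data$center * exp(object$r_max),
      lower = .data$center * exp(object$r_min)
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$center),
                       colour = "purple") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$upper),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$lower),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = exp(.data$ln_m0))) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = sprintf("Strehler-Mildvan correlation%s",
                      if (nzchar(object$population))
                        paste0(": ", object$population) else ""),
      subtitle = sprintf("A = %.1f years, R^2 = %.3f, L2/L1 = %.2f",
                         object$A_years, object$r2, object$band_ratio),
      x = expression(alpha ~ "(Gompertz slope, per year of age)"),
      y = expression(m[0] ~ "(log scale)")
    )
  if (labels && "period" %in% names(d) && any(nzchar(d$period))) {
    # ASCII hyphen in drawn labels: the pdf device cannot encode the en-dash
    d$.label <- gsub("–", "-", d$period)
    p <- p + ggplot2::geom_text(
      data = d,
      ggplot2::aes(y = exp(.data$ln_m0), label = .data$.label),
      size = 2, hjust = -0.1, vjust = -0.4, check_overlap = TRUE
    )
  }
  p
}

#' Write the SM correlation figure to a file
#'
#' @param fits Gompertz fit tibble (used to refit when `smfit` is `NULL`).
#' @param smfit An [fit_sm()] result; refitted from `fits` when `NULL`.
#' @param path Output figure path (format from extension, e.g. `.pdf`,
#'   `.png`).
#' @param ... Passed to [autoplot.sm_fit()].
#' @return Invisibly, `path`.
#' @export
plot_sm <- function(fits, smfit = NULL, path, ...) {
  if (is.null(smfit)) smfit <- fit_sm(fits)
  p <- autoplot(smfit, ...)
  ggplot2::ggsave(path, p, width = 7, height = 5)
  invisible(path)
}
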