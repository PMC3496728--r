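#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("Cosinor fit (%s, period %g h, n = %d)\n",
              x$method, x$period, x$n))
  cat(sprintf("  mesor %.4g  amplitude %.4g  acrophase %s\n",
              x$mesor, x$amplitude,
              if (is.na(x$acrophase)) "NA" else sprintf("ZT %.2f", x$acrophase)))
  cat(sprintf("  R2 %.4g  adj R2 %.4g  peak-to-trough %.4g\n",
              x$r2, x$r2_adj, x$amplitude_pt))
  if (!is.na(x$p_value)) cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Tidy a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return One-row tibble of parameter estimates.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble(
    mesor = x$mesor, amplitude = x$amplitude, acrophase = x$acrophase,
    period = x$period, peak_zt = x$peak_zt_continuous,
    peak_zt_grid = x$peak_zt_grid, amplitude_pt = x$amplitude_pt
  )
}

#' One-row model summary of a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit statistics.
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(
    r2 = x$r2, r2_adj = x$r2_adj, p_value = x$p_value, n = x$n,
    method = x$method, n_sims = x$n_sims, top_k = x$top_k, seed = x$seed
  )
}

#' Plot a cosinor fit over its data
#'
#' Observed points with the fitted cosine evaluated on a fine hour grid.
#'
#' @param object A `cosinor_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  obs <- tibble(zt = object$zt, y = object$y)
  grid <- tibble(zt = seq(min(object$zt), max(object$zt), length.out = 200))
  grid$y <- cosine_predict(grid$zt, object$mesor, object$amplitude,
                           object$acrophase %||% 0, object$period)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$zt, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "Zeitgeber time (h)", y = "standardized expression",
      title = sprintf("Cosinor fit (R2 = %.2f, adj R2 = %.2f)",
                      object$r2, object$r2_adj)
    ) +
    ggplot2::theme_minimal()
}

#' Plot aggregated expression time courses
#'
#' Mean z-scored expression with standard-error bars across colonies, one
#' facet per gene — the standard clock-gene time-course figure.
#'
#' @param data Aggregate tibble from [aggregate_colonies()].
#' @param genes Optional character vector restricting the genes shown.
#' @return A ggplot.
#' @export
plot_expression <- function(data, genes = NULL) {
  if (!is.null(genes)) data <- filter(data, .data$gene %in% genes)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$zt, y = .data$mean_z)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$se_z,
                   ymax = .data$mean_z + .data$se_z),
      width = 0.8, colour = "grey50"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "Zeitgeber time (h)",
                  y = "relative expression (z-score)") +
    ggplot2::theme_minimal()
}
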