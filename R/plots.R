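#' Plot a normalized confusion matrix
#'
#' @param object A `decode_result`.
#' @param ... Unused.
#' @return A ggplot: row-normalized confusion heat map (rows = true class).
#' @export
autoplot.decode_result <- function(object, ...) {
  nc <- normalize_confusion(object$confusion)
  df <- tibble::as_tibble(as.data.frame(as.table(nc)))
  names(df) <- c("true", "predicted", "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$proportion)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = paste0("Confusion: ", object$unit),
                  x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot a maximum-statistic null distribution
#'
#' @param object A `wm_null`.
#' @param observed Optional observed group-mean accuracy to mark.
#' @param ... Unused.
#' @return A ggplot histogram of the per-permutation family maxima.
#' @export
autoplot.wm_null <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$max_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", color = "white") +
    ggplot2::labs(x = "family-wise maximum group-mean accuracy",
                  y = "permutations",
                  title = sprintf("Max-statistic null (%d permutations, %d units)",
                                  object$n_perm, object$n_units)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, color = "firebrick",
                                 linetype = 2)
  }
  p
}

#' Plot family-analysis decoding accuracies
#'
#' Units ordered by observed accuracy; significant units highlighted, with
#' the null's critical value (1 - alpha quantile) as a reference line.
#'
#' @param object A `wm_family_result`.
#' @param top Show at most this many units (largest accuracies).
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.wm_family_result <- function(object, top = 50, ...) {
  df <- dplyr::arrange(object$report, dplyr::desc(.data$observed)) |>
    utils::head(top) |>
    dplyr::mutate(unit = factor(.data$unit, levels = rev(.data$unit)))
  crit <- unname(stats::quantile(object$null$max_stats, 1 - object$alpha,
                                 type = 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$unit,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = crit, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1 / 6, linetype = 3, color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "group-mean decoding accuracy", y = NULL,
                  title = sprintf("%s family (%d units): %d significant at alpha = %g",
                                  object$mode, nrow(object$report),
                                  sum(object$report$significant),
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the spectrotemporal envelope of a ripple stimulus
#'
#' Shows the analytic envelope `s(g, t)` of a [ripple_spec()] over time and
#' log-frequency: the drifting diagonal ridges whose slope is set by the
#' ripple velocity and density.
#'
#' @param spec A [ripple_spec()].
#' @param n_t,n_g Grid resolution.
#' @return A ggplot raster.
#' @export
plot_ripple_envelope <- function(spec, n_t = 200, n_g = 100) {
  stopifnot(inherits(spec, "ripple_spec"))
  grid <- tidyr::crossing(
    t = seq(0, spec$duration, length.out = n_t),
    g = seq(0, log2(spec$f_hi / spec$f0), length.out = n_g)
  )
  grid$s <- spec$base + spec$depth *
    cos(2 * pi * (spec$omega * grid$t + spec$Omega * grid$g) + spec$phase)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$g, fill = .data$s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "octaves above f0", fill = "s(g, t)",
                  title = sprintf("Moving ripple: omega = %g cyc/s, Omega = %g cyc/oct",
                                  spec$omega, spec$Omega)) +
    ggplot2::theme_minimal()
}
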