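#' Plot a psi-moment parameter sweep
#'
#' Line plot of `E[Psi]` and `V[Psi]` from a [psi_moments_sweep()] result
#' against one swept parameter, optionally colored by a second.
#'
#' @param sweep A tibble from [psi_moments_sweep()].
#' @param x Name of the swept parameter column (string).
#' @param color Optional name of a grouping column.
#' @return A ggplot object.
#' @examples
#' sw <- psi_moments_sweep(
#'   tidyr::crossing(N_A = 400, N_B = 600, N_C = 1000,
#'                   t = c(10, 80, 120), s = seq(0, 200, by = 10)),
#'   family = "founder")
#' plot_psi_sweep(sw, x = "s", color = "t")
#' @export
plot_psi_sweep <- function(sweep, x, color = NULL) {
  long <- tidyr::pivot_longer(
    sweep, cols = c("mean", "variance"),
    names_to = "moment", values_to = "value")
  long$moment <- factor(long$moment, levels = c("mean", "variance"),
                        labels = c("E[Ψ]", "V[Ψ]"))
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data[[x]], y = .data$value)
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$value,
                 color = factor(.data[[color]]))
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(y = NULL, color = color) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Plot a Monte Carlo psi-moment estimate against the closed forms
#'
#' Point-and-error-bar plot of the Monte Carlo estimates (plus/minus two
#' bootstrap standard errors) with the closed-form values overlaid.
#'
#' @param object A `psi_mc` from [estimate_psi_moments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psi_mc
#' @export
autoplot.psi_mc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$std.error,
      ymax = .data$estimate + 2 * .data$std.error)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$closed_form),
                        shape = 4, size = 3, color = "red") +
    ggplot2::labs(x = NULL, y = "estimate",
                  subtitle = "crosses: closed-form values") +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap distribution of mean psi
#'
#' Histogram of the per-replicate mean psi with the median and central 95%
#' interval marked.
#'
#' @param object A `psi_bootstrap` from [bootstrap_loci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psi_bootstrap
#' @export
autoplot.psi_bootstrap <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = .data$mean_psi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = s$median_mean, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(s$mean_lo95, s$mean_hi95),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap replicate mean ψ", y = "replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
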