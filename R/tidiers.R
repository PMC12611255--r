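#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Monte Carlo psi-moment estimate
#'
#' @param x A `psi_mc` from [estimate_psi_moments()].
#' @param ... Unused.
#' @return A tibble with one row per estimated moment: `term`, `estimate`,
#'   `std.error`, the matching `closed_form` value, and the z-score of their
#'   difference.
#' @method tidy psi_mc
#' @export
tidy.psi_mc <- function(x, ...) {
  out <- x$estimates
  out$closed_form <- unname(unlist(x$closed_form)[out$term])
  out$z <- (out$estimate - out$closed_form) / out$std.error
  out
}

#' @rdname tidy.psi_mc
#' @method glance psi_mc
#' @export
glance.psi_mc <- function(x, ...) {
  e <- stats::setNames(x$estimates$estimate, x$estimates$term)
  tibble::tibble(mean = e[["mean"]], variance = e[["variance"]],
                 n = x$n, n_boot = x$n_boot, estimator = x$estimator,
                 family = class(x$model)[1])
}

#' Tidy a psi locus bootstrap
#'
#' @param x A `psi_bootstrap` from [bootstrap_loci()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per summarized statistic
#'   (`mean_psi`, `var_psi`) giving the bootstrap `median`, `conf.low` and
#'   `conf.high` (central 95% interval). `glance()`: a one-row tibble with
#'   the medians and run settings.
#' @method tidy psi_bootstrap
#' @export
tidy.psi_bootstrap <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    term = c("mean_psi", "var_psi"),
    median = c(s$median_mean, s$median_var),
    conf.low = c(s$mean_lo95, s$var_lo95),
    conf.high = c(s$mean_hi95, s$var_hi95))
}

#' @rdname tidy.psi_bootstrap
#' @method glance psi_bootstrap
#' @export
glance.psi_bootstrap <- function(x, ...) {
  dplyr::bind_cols(x$summary[, c("median_mean", "median_var")],
                   tibble::tibble(num_replicates = x$num_replicates,
                                  num_quartets = x$num_quartets,
                                  mode = x$mode))
}
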