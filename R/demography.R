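#' Demographic models for a two-population split
#'
#' Constructors for the four parameterizations of an ancestral population C
#' of diploid size `N_C` splitting, `t` generations before the present, into
#' descendant populations A and B. All sizes are numbers of diploid
#' individuals (real-valued; `2N` lineages per population) and all times are
#' in generations. The models differ only in what happens to population A
#' (and, for the growth model, B) after the split:
#'
#' * `split_model()` — constant sizes `N_A`, `N_B`.
#' * `growth_model()` — exponential growth at per-generation rates `r_A`,
#'   `r_B`, so that the size of A at `tau` generations before the present is
#'   `N_A0 * exp(-r_A * tau)`. Either the rates or the sizes at the split
#'   (`N_At`, `N_Bt`) may be supplied; rates are canonical internally.
#' * `bottleneck_model()` — population A passes through a bottleneck of
#'   constant diploid size `N_b` lasting `t_b` generations immediately after
#'   the split (i.e. on the time interval `(t - t_b, t]` before present).
#' * `founder_model()` — an instantaneous bottleneck: at the split, lineages
#'   in A experience a burst of coalescence equivalent to `s` additional
#'   generations of drift at size `N_A`, with no mutation during the burst.
#'
#' @param N_A,N_B Present-day diploid sizes of populations A and B.
#' @param N_C Diploid size of the ancestral population.
#' @param t Split time, in generations before the present (`t >= 0`).
#' @param N_A0,N_B0 Present-day sizes for the growth model.
#' @param N_At,N_Bt Sizes immediately after the split (growth model); used to
#'   derive the growth rates when `r_A`/`r_B` are not given.
#' @param r_A,r_B Exponential growth rates per generation; positive rates
#'   mean the population grows forward in time.
#' @param N_b Bottleneck diploid size (bottleneck model).
#' @param t_b Bottleneck duration in generations, `0 <= t_b <= t`.
#' @param s Instantaneous-bottleneck strength, in pseudo-generations of drift
#'   at size `N_A` (`s >= 0`).
#'
#' @return An object of class `coalpsi_model` (subclass `split_model`,
#'   `growth_model`, `bottleneck_model` or `founder_model`): a validated
#'   named list of parameters.
#' @examples
#' split_model(N_A = 400, N_B = 600, N_C = 1000, t = 100)
#' founder_model(N_A = 400, N_B = 600, N_C = 1000, t = 80, s = 20)
#' growth_model(N_A0 = 1224378, N_B0 = 3589770, N_C = 1e6, t = 168490,
#'              N_At = 16550, r_B = 0)
#' @name demographic_models
NULL

new_model <- function(family, fields) {
  structure(fields, class = c(family, "coalpsi_model"))
}

#' @rdname demographic_models
#' @export
split_model <- function(N_A, N_B, N_C, t) {
  validate_model(new_model("split_model",
    list(N_A = N_A, N_B = N_B, N_C = N_C, t = t)))
}

#' @rdname demographic_models
#' @export
growth_model <- function(N_A0, N_B0, N_C, t,
                         N_At = NULL, N_Bt = NULL,
                         r_A = NULL, r_B = NULL) {
  if (is.null(r_A) && is.null(N_At))
    stop("growth_model: supply either `r_A` or `N_At`", call. = FALSE)
  if (is.null(r_B) && is.null(N_Bt))
    stop("growth_model: supply either `r_B` or `N_Bt`", call. = FALSE)
  derive <- function(rate, N_t, N_0, who) {
    if (!is.null(rate) && !is.null(N_t)) {
      # both given: they must agree through the size-rate relation
      implied <- growth_rate_from_sizes(N_t, N_0, t)
      if (abs(implied - rate) > 1e-9 * max(1, abs(rate)))
        stop(sprintf("growth_model: `r_%s` inconsistent with sizes (given %g, implied %g)",
                     who, rate, implied), call. = FALSE)
      rate
    } else if (!is.null(rate)) rate else growth_rate_from_sizes(N_t, N_0, t)
  }
  r_A <- derive(r_A, N_At, N_A0, "A")
  r_B <- derive(r_B, N_Bt, N_B0, "B")
  validate_model(new_model("growth_model",
    list(N_A0 = N_A0, N_B0 = N_B0, N_C = N_C, t = t,
         r_A = r_A, r_B = r_B,
         N_At = N_A0 * exp(-r_A * t), N_Bt = N_B0 * exp(-r_B * t))))
}

#' @rdname demographic_models
#' @export
bottleneck_model <- function(N_A, N_b, t_b, N_B, N_C, t) {
  validate_model(new_model("bottleneck_model",
    list(N_A = N_A, N_b = N_b, t_b = t_b, N_B = N_B, N_C = N_C, t = t)))
}

#' @rdname demographic_models
#' @export
founder_model <- function(N_A, N_B, N_C, t, s) {
  validate_model(new_model("founder_model",
    list(N_A = N_A, N_B = N_B, N_C = N_C, t = t, s = s)))
}

#' Validate a demographic model
#'
#' Checks the type invariants of a demographic model (positive sizes,
#' non-negative times, `t_b <= t`, `s >= 0`) and returns the model unchanged
#' if they all hold. Degenerate-but-legal settings (`t = 0`, `s = 0`,
#' `t_b = 0`) pass.
#'
#' @param model A `coalpsi_model`.
#' @return The validated model, invisibly identical to the input.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "coalpsi_model"))
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in intersect(names(model), c("N_A", "N_B", "N_C", "N_b", "N_A0", "N_B0")))
    chk(num1(model[[f]]) && model[[f]] > 0, sprintf("%s must be a positive number", f))
  chk(num1(model$t) && model$t >= 0, "t must be a non-negative number")
  if (!is.null(model$s))
    chk(num1(model$s) && model$s >= 0, "s must be a non-negative number")
  if (!is.null(model$t_b)) {
    chk(num1(model$t_b) && model$t_b >= 0, "t_b must be a non-negative number")
    chk(num1(model$t_b) && num1(model$t) && model$t_b <= model$t,
        "t_b must not exceed t")
  }
  for (f in intersect(names(model), c("r_A", "r_B")))
    chk(num1(model[[f]]), sprintf("%s must be a finite number", f))
  if (length(bad))
    stop("invalid demographic model: ", paste(bad, collapse = "; "), call. = FALSE)
  model
}

#' @export
print.coalpsi_model <- function(x, ...) {
  fam <- sub("_model$", "", class(x)[1])
  cat(sprintf("<%s demography>\n", fam))
  shown <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", names(shown), " = ", format(unlist(shown), digits = 8),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Growth rate implied by sizes at the ends of an interval
#'
#' Per-generation exponential growth rate of a population that had diploid
#' size `N_t` at the start of an interval (the split, `t` generations ago)
#' and `N_0` at its end (the present): `r = -log(N_t / N_0) / t`. Positive
#' when the population grows forward in time.
#'
#' @param N_t Size at the split (start of growth).
#' @param N_0 Present-day size.
#' @param t Interval length in generations, `t > 0`.
#' @return The growth rate per generation.
#' @examples
#' growth_rate_from_sizes(16550, 1224378, 168490)
#' @export
growth_rate_from_sizes <- function(N_t, N_0, t) {
  if (!is.numeric(N_t) || !is.numeric(N_0) || any(N_t <= 0) || any(N_0 <= 0))
    stop("growth_rate_from_sizes: sizes must be positive", call. = FALSE)
  if (any(t == 0 & N_t != N_0))
    stop("growth_rate_from_sizes: rate undefined for t = 0 with unequal sizes",
         call. = FALSE)
  ifelse(t == 0, 0, -log(N_t / N_0) / t)
}

#' Rescaled coalescent time under exponential growth
#'
#' For a pair of lineages, the coalescent in a population with size
#' `N_0 * exp(-r * tau)` at `tau` generations before present is the coalescent
#' in a constant population of size `N_0` with time rescaled by
#' `T = (exp(r * t) - 1) / r`. Continuous at `r = 0`, where the value is
#' exactly `t`; evaluated with `expm1()` and a series fallback so that small
#' `|r * t|` does not lose precision.
#'
#' @param r Growth rate per generation (any sign).
#' @param t Duration in generations, `t >= 0`.
#' @return The rescaled duration (same units as `t`).
#' @examples
#' rescaled_time(0, 100)          # exactly 100
#' rescaled_time(2.554e-5, 168490)
#' @export
rescaled_time <- function(r, t) {
  stopifnot(is.numeric(r), is.numeric(t), all(t >= 0))
  x <- r * t
  out <- ifelse(abs(x) < 1e-8,
                t * (1 + x / 2 + x * x / 6),
                expm1(x) / r)
  out[t == 0] <- 0
  out
}

#' Autosomal-equivalent size of an X-linked population size
#'
#' X-chromosomal analyses count `3N/2` lineages in a population of `N`
#' diploid individuals rather than `2N`; an X-linked effective size is
#' converted to its autosomal-equivalent diploid size by multiplying by 3/4.
#'
#' @param N Reported X-linked diploid size, `N > 0`.
#' @return `3 * N / 4`.
#' @examples
#' x_chromosome_rescale(4786360)
#' @export
x_chromosome_rescale <- function(N) {
  if (!is.numeric(N) || any(N <= 0))
    stop("x_chromosome_rescale: N must be positive", call. = FALSE)
  3 * N / 4
}

#' Read or write a demographic model as a YAML config
#'
#' Models serialize to a flat key-value YAML mapping with a `family` key
#' (`split`, `growth`, `bottleneck` or `founder`) plus the model's parameter
#' fields, named exactly as in the constructors.
#'
#' @param model A `coalpsi_model`.
#' @param path File path to write to / read from.
#' @return `write_model_yaml()` returns `path` invisibly;
#'   `read_model_yaml()` returns the reconstructed, validated model.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "coalpsi_model"))
  fam <- sub("_model$", "", class(model)[1])
  yaml::write_yaml(c(list(family = fam), unclass(model)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  fam <- match.arg(cfg$family, c("split", "growth", "bottleneck", "founder"))
  cfg$family <- NULL
  switch(fam,
    split = split_model(cfg$N_A, cfg$N_B, cfg$N_C, cfg$t),
    growth = growth_model(cfg$N_A0, cfg$N_B0, cfg$N_C, cfg$t,
                          r_A = cfg$r_A, r_B = cfg$r_B),
    bottleneck = bottleneck_model(cfg$N_A, cfg$N_b, cfg$t_b,
                                  cfg$N_B, cfg$N_C, cfg$t),
    founder = founder_model(cfg$N_A, cfg$N_B, cfg$N_C, cfg$t, cfg$s))
}

# Cumulative drift (in coalescent units of pairwise coalescence intensity)
# accumulated by a pair of lineages in each descendant population between the
# present and entry into the ancestral population. Split across population A's
# ordinary epoch and its bottleneck/burst component because the cherry-location
# refinements of the topology probabilities need them separately.
drift_components <- function(model) {
  UseMethod("drift_components")
}

#' @export
drift_components.split_model <- function(model) {
  list(dA_main = model$t / (2 * model$N_A), dA_bot = 0,
       dB = model$t / (2 * model$N_B))
}

#' @export
drift_components.growth_model <- function(model) {
  list(dA_main = rescaled_time(model$r_A, model$t) / (2 * model$N_A0),
       dA_bot = 0,
       dB = rescaled_time(model$r_B, model$t) / (2 * model$N_B0))
}

#' @export
drift_components.bottleneck_model <- function(model) {
  list(dA_main = (model$t - model$t_b) / (2 * model$N_A),
       dA_bot = model$t_b / (2 * model$N_b),
       dB = model$t / (2 * model$N_B))
}

#' @export
drift_components.founder_model <- function(model) {
  list(dA_main = model$t / (2 * model$N_A),
       dA_bot = model$s / (2 * model$N_A),
       dB = model$t / (2 * model$N_B))
}

# A <-> B parameter swap; used by antisymmetry tests and sanity checks.
# The bottleneck/founder families are asymmetric (only A has a bottleneck),
# so swapping is only defined for split and growth models.
swap_populations <- function(model) {
  if (inherits(model, "split_model"))
    return(split_model(model$N_B, model$N_A, model$N_C, model$t))
  if (inherits(model, "growth_model"))
    return(growth_model(model$N_B0, model$N_A0, model$N_C, model$t,
                        r_A = model$r_B, r_B = model$r_A))
  stop("swap_populations: only split and growth models are A/B-symmetric families",
       call. = FALSE)
}
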