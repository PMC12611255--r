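#' Genealogy topology probabilities for a two-population sample of 2 + 2
#'
#' For two lineages sampled in each of populations A and B, six labeled tree
#' topologies are distinguishable when lineages within a population are
#' exchangeable: alpha (a cherry in each population), beta and gamma
#' (caterpillars whose first cherry is (B,B) resp. (A,A)), delta (two
#' mixed A-B cherries), and epsilon / zeta (caterpillars whose mixed first
#' cherry is joined by a B resp. an A lineage). The beta and gamma
#' probabilities are refined by where the same-population cherry coalesces:
#' in the descendant population (`p_beta_B`, `p_gamma_A`), during population
#' A's bottleneck or founder burst (`p_gamma_bot`; zero for the split and
#' growth models), or in the ancestral population (`p_beta_C`, `p_gamma_C`).
#'
#' @param model A validated demographic model
#'   (see [demographic_models]).
#' @return A one-row tibble with columns `p_alpha`, `p_beta_B`, `p_beta_C`,
#'   `p_beta`, `p_gamma_A`, `p_gamma_bot`, `p_gamma_C`, `p_gamma`, `p_delta`,
#'   `p_epsilon`, `p_zeta`. The nine refined probabilities sum to one with
#'   `p_delta = p_epsilon = p_zeta`.
#' @examples
#' topology_probabilities(split_model(400, 600, 1000, t = 0))
#' @export
topology_probabilities <- function(model) {
  d <- drift_components(validate_model(model))
  sA_main <- exp(-d$dA_main)           # A pair survives A's ordinary epoch
  sA <- exp(-(d$dA_main + d$dA_bot))   # ... and the bottleneck/burst
  sB <- exp(-d$dB)                     # B pair survives population B
  p_beta_B <- 2 / 3 * sA * (1 - sB)
  p_gamma_A <- 2 / 3 * (1 - sA_main) * sB
  p_gamma_bot <- 2 / 3 * sA_main * (1 - exp(-d$dA_bot)) * sB
  p_beta_C <- sA * sB / 9
  p_gamma_C <- sA * sB / 9
  p_delta <- 2 / 9 * sA * sB
  p_beta <- p_beta_B + p_beta_C
  p_gamma <- p_gamma_A + p_gamma_bot + p_gamma_C
  tibble::tibble(
    p_alpha = 1 - (p_beta + p_gamma + 3 * p_delta),
    p_beta_B = p_beta_B, p_beta_C = p_beta_C, p_beta = p_beta,
    p_gamma_A = p_gamma_A, p_gamma_bot = p_gamma_bot, p_gamma_C = p_gamma_C,
    p_gamma = p_gamma,
    p_delta = p_delta, p_epsilon = p_delta, p_zeta = p_delta)
}

#' Expected lengths of shared-capable branches
#'
#' Branches ancestral to lineages from both populations can only exist in the
#' ancestral population C, so their expected lengths are those of a
#' single-population coalescent of diploid size `N_C`: the two-lineage
#' coalescence time `E[T2] = 2 N_C` and the three-lineage first-coalescence
#' time `E[T3] = 2 N_C / 3`.
#'
#' @param N_C Ancestral diploid population size.
#' @return A one-row tibble with the expected lengths (in generations) of
#'   the shared-capable branches of each topology: `E_b_beta`, `E_b_gamma`
#'   (each `2 N_C`), `E_b_eps1`, `E_b_zeta1` (each `2 N_C / 3`), `E_b_eps2`,
#'   `E_b_zeta2` (each `2 N_C`), and `E_b_delta_sum` (`4 N_C + 2 N_C / 3`,
#'   the two mixed-cherry branches of delta together).
#' @export
branch_length_expectations <- function(N_C) {
  stopifnot(is.numeric(N_C), N_C > 0)
  T2 <- 2 * N_C
  T3 <- 2 * N_C / 3
  tibble::tibble(
    E_b_beta = T2, E_b_gamma = T2,
    E_b_eps1 = T3, E_b_eps2 = T2,
    E_b_zeta1 = T3, E_b_zeta2 = T2,
    E_b_delta_sum = 2 * T2 + T3)
}

#' Shared entries of the expected joint site frequency spectrum
#'
#' Computes weights proportional to the probabilities that a random SNP on
#' the 2 + 2 genealogy is of shared type (i derived copies in the A sample,
#' j in the B sample, for ij in 11, 12, 21), by combining topology
#' probabilities with the expected lengths of shared-capable branches, and
#' the conditional type probabilities given that a SNP is shared. The scaled
#' mutation rate cancels in the conditionals because every shared-capable
#' branch lies in the ancestral population; the conditionals are therefore
#' also independent of `N_C`.
#'
#' @inheritParams topology_probabilities
#' @return A one-row tibble with columns `s11`, `s12`, `s21` (weights, in
#'   units of expected branch generations) and `cond11`, `cond12`, `cond21`
#'   (conditional probabilities summing to one).
#' @examples
#' shared_sfs(founder_model(400, 600, 1000, t = 80, s = 20))
#' @export
shared_sfs <- function(model) {
  p <- topology_probabilities(model)
  b <- branch_length_expectations(model$N_C)
  s12 <- p$p_beta * b$E_b_beta + p$p_epsilon * b$E_b_eps2
  s21 <- p$p_gamma * b$E_b_gamma + p$p_zeta * b$E_b_zeta2
  s11 <- p$p_delta * b$E_b_delta_sum + p$p_epsilon * b$E_b_eps1 +
    p$p_zeta * b$E_b_zeta1
  tot <- s11 + s12 + s21
  if (!is.finite(tot) || tot <= 0)
    stop("shared_sfs: no shared-capable branch length under these parameters",
         call. = FALSE)
  tibble::tibble(s11 = s11, s12 = s12, s21 = s21,
                 cond11 = s11 / tot, cond12 = s12 / tot, cond21 = s21 / tot)
}

#' Moments of the single-SNP directionality index Psi
#'
#' Expectation, second moment and variance of the directionality index Psi
#' for a single shared SNP in a sample of two lineages per population. The
#' default route evaluates the closed forms common to all four demographies:
#' with `dA` and `dB` the cumulative pairwise-coalescence intensities
#' ("drift") accumulated by the A and B pairs before entering the ancestral
#' population,
#' \deqn{E[\Psi] = \tanh((d_A - d_B)/2), \qquad
#'       E[\Psi^2] = 1 - 1/(e^{d_A} + e^{d_B}),}
#' and `V = E[Psi^2] - E[Psi]^2`. The alternative `method = "sfs"` route goes
#' through the topology probabilities and shared-SFS conditionals; the two
#' agree to floating-point accuracy and serve as mutual checks. Exponentials
#' are evaluated in max-shifted (log-sum-exp) form so that extreme drift
#' saturates gracefully (`mean -> +-1`, finite variance) instead of
#' overflowing.
#'
#' @inheritParams topology_probabilities
#' @param method `"closed_form"` (default) or `"sfs"`.
#' @return A one-row tibble with columns `mean`, `second_moment`, `variance`.
#' @examples
#' psi_moments(bottleneck_model(N_A = 1075000, N_b = 2200, t_b = 3400,
#'                              N_B = 8603000, N_C = 1e6, t = 158000))
#' @export
psi_moments <- function(model, method = c("closed_form", "sfs")) {
  method <- match.arg(method)
  if (method == "sfs") {
    s <- shared_sfs(model)
    m <- s$cond21 - s$cond12
    m2 <- s$cond21 + s$cond12
    return(tibble::tibble(mean = m, second_moment = m2, variance = m2 - m^2))
  }
  d <- drift_components(validate_model(model))
  dA <- d$dA_main + d$dA_bot
  dB <- d$dB
  m <- max(dA, dB)
  # E[Psi^2] = 1 - 1/(e^dA + e^dB), shifted by the larger exponent
  denom1 <- exp(dA - m) + exp(dB - m)
  second <- 1 - exp(-m) / denom1
  # V[Psi] = (4 e^(dA+dB) - e^dA - e^dB) / (e^dA + e^dB)^2, shifted by 2m
  variance <- (4 * exp(-abs(dA - dB)) - exp(dA - 2 * m) - exp(dB - 2 * m)) /
    denom1^2
  tibble::tibble(mean = tanh((dA - dB) / 2),
                 second_moment = second,
                 variance = variance)
}

#' Distribution of Psi for a single shared SNP
#'
#' Psi conditional on a single shared SNP is a three-point random variable:
#' +1 for a type-21 SNP, 0 for type 11, and -1 for type 12, with the
#' conditional type probabilities from [shared_sfs()]. All odd moments equal
#' the mean and all even moments equal the second moment.
#'
#' @inheritParams topology_probabilities
#' @return A tibble with columns `value` (1, 0, -1) and `probability`.
#' @export
psi_distribution <- function(model) {
  s <- shared_sfs(model)
  tibble::tibble(value = c(1, 0, -1),
                 probability = c(s$cond21, s$cond11, s$cond12))
}

#' Expected total length of shared-capable branches
#'
#' The expected genealogical branch length on which a mutation would create
#' a shared SNP, in units of `2 N_C` generations:
#' `E[L] = p_beta + p_gamma + (7/3) p_delta + (4/3) p_epsilon +
#' (4/3) p_zeta`. For every family this reduces to the closed form
#' `(2/3) (exp(-dA) + exp(-dB))` in terms of the cumulative drift of each
#' pair; both routes are available and agree to floating-point accuracy.
#'
#' @inheritParams psi_moments
#' @param method `"topologies"` (default, the generic branch inventory) or
#'   `"closed_form"`.
#' @return The expected length `E[L]` as a number (units of `2 N_C`
#'   generations).
#' @examples
#' expected_shared_branch_length(founder_model(400, 600, 1000, t = 0, s = 0))
#' # 4/3
#' @export
expected_shared_branch_length <- function(model,
                                          method = c("topologies", "closed_form")) {
  method <- match.arg(method)
  if (method == "closed_form") {
    d <- drift_components(validate_model(model))
    return(2 / 3 * (exp(-(d$dA_main + d$dA_bot)) + exp(-d$dB)))
  }
  p <- topology_probabilities(model)
  p$p_beta + p$p_gamma + 7 / 3 * p$p_delta + 4 / 3 * p$p_epsilon +
    4 / 3 * p$p_zeta
}

#' Expected number of shared SNPs
#'
#' Under infinitely-many-sites mutation at rate `mu` per site per generation,
#' the expected number of shared SNPs across `num_sites` unlinked sites is
#' `num_sites * 2 * N_C * mu * E[L]`: linear in both the ancestral size and
#' the mutation rate. The ancestral size thus affects empirical psi only
#' through the number of usable shared SNPs, not through the moments of Psi.
#'
#' @inheritParams psi_moments
#' @param mu Mutation rate per site per generation (`mu >= 0`).
#' @param num_sites Number of sites (default 1).
#' @return Expected shared-SNP count (a number).
#' @export
expected_shared_snp_count <- function(model, mu, num_sites = 1) {
  stopifnot(is.numeric(mu), all(mu >= 0), is.numeric(num_sites),
            all(num_sites >= 0))
  num_sites * 2 * model$N_C * mu * expected_shared_branch_length(model)
}

#' Sampling distribution of the many-SNP mean of psi
#'
#' For `n` independent shared SNPs the mean of the per-SNP psi values is
#' asymptotically Gaussian with mean `E[Psi]` and variance `V[Psi] / n`.
#'
#' @inheritParams psi_moments
#' @param n Number of shared SNPs (positive integer).
#' @return A one-row tibble with columns `n`, `mean`, `variance_of_mean`.
#' @export
sample_distribution <- function(model, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("sample_distribution: n must be a positive integer", call. = FALSE)
  mom <- psi_moments(model)
  tibble::tibble(n = n, mean = mom$mean, variance_of_mean = mom$variance / n)
}

#' Evaluate Psi moments over a grid of parameter sets
#'
#' Maps the rows of a parameter data frame through a model constructor and
#' [psi_moments()], returning the input with `mean`, `second_moment` and
#' `variance` columns appended. Column names must match the constructor
#' arguments of the chosen family.
#'
#' @param params A data frame of model parameters, one parameter set per row.
#' @param family One of `"split"`, `"growth"`, `"bottleneck"`, `"founder"`.
#' @return `params` as a tibble with the three moment columns appended.
#' @examples
#' library(tibble)
#' psi_moments_sweep(
#'   tibble(N_A = 400, N_B = 600, N_C = 1000, t = 80, s = c(0, 10, 20)),
#'   family = "founder")
#' @export
psi_moments_sweep <- function(params,
                              family = c("split", "growth", "bottleneck",
                                         "founder")) {
  family <- match.arg(family)
  ctor <- switch(family, split = split_model, growth = growth_model,
                 bottleneck = bottleneck_model, founder = founder_model)
  moments <- purrr::pmap(params, function(...) {
    psi_moments(do.call(ctor, list(...)))
  })
  dplyr::bind_cols(tibble::as_tibble(params), dplyr::bind_rows(moments))
}
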