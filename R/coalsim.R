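#' Simulate one genealogy of a 2 + 2 sample under the structured coalescent
#'
#' Samples, pastwards, the genealogy of two lineages from population A and
#' two from population B under a demographic model. Within-population
#' coalescence times are drawn by inverting the cumulative pairwise
#' coalescence intensity of each population's size history (so exponential
#' growth uses the exact time rescaling, and a bottleneck switches A's size
#' to `N_b` on `(t - t_b, t]`). Under the founder model, A's surviving pair
#' coalesces at time `t` with probability `1 - exp(-s / (2 N_A))` — a burst
#' of `s` pseudo-generations of drift contributing zero branch length. All
#' remaining lineages then enter the ancestral population and coalesce as a
#' standard constant-size coalescent of size `N_C`.
#'
#' @inheritParams topology_probabilities
#' @param seed Optional integer seed; if `NULL`, the current RNG state is
#'   used (and advanced).
#' @return An object of class `coal_genealogy`: leaf nodes 1-4 are `A_1`,
#'   `A_2`, `B_1`, `B_2`; internal nodes 5-7 are created in merge order
#'   (node 7 is the root). Components: `time` (node heights in generations),
#'   `parent`, `leaves` (list of descendant leaf sets), `epoch` (for each
#'   internal node, one of `"A"`, `"bottleneck"`, `"burst"`, `"B"`, `"C"`).
#' @examples
#' g <- simulate_genealogy(split_model(400, 600, 1000, t = 100), seed = 1)
#' classify_topology(g)
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  validate_model(model)
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_genealogy(model)))

  tA <- coal_time_within_A(model, stats::rexp(1))
  tB <- coal_time_within_B(model, stats::rexp(1))

  time <- c(0, 0, 0, 0, NA, NA, NA)
  parent <- rep(NA_integer_, 7)
  leaves <- c(as.list(1:4), vector("list", 3))
  epoch <- rep(NA_character_, 7)

  nxt <- 5L
  merge_nodes <- function(i, j, at, ep) {
    time[nxt] <<- at
    leaves[[nxt]] <<- sort(c(leaves[[i]], leaves[[j]]))
    epoch[nxt] <<- ep
    parent[c(i, j)] <<- nxt
    nxt <<- nxt + 1L
  }

  # lineages entering the ancestral population, with their entry events first
  pend <- list()
  if (is.finite(tA$time)) {
    merge_nodes(1L, 2L, tA$time, tA$epoch)
    pend <- c(pend, list(nxt - 1L))
  } else pend <- c(pend, list(1L, 2L))
  if (is.finite(tB$time)) {
    merge_nodes(3L, 4L, tB$time, tB$epoch)
    pend <- c(pend, list(nxt - 1L))
  } else pend <- c(pend, list(3L, 4L))

  # order events by time so node ids are in merge order
  if (is.finite(tA$time) && is.finite(tB$time) && tB$time < tA$time) {
    # redo with B's cherry first
    time[5:7] <- NA; parent[] <- NA_integer_; leaves[5:7] <- list(NULL)
    nxt <- 5L
    merge_nodes(3L, 4L, tB$time, tB$epoch)
    merge_nodes(1L, 2L, tA$time, tA$epoch)
    pend <- list(6L, 5L)
  }

  active <- unlist(pend)
  now <- model$t
  while (length(active) > 1L) {
    k <- length(active)
    now <- now + stats::rexp(1, rate = k * (k - 1) / 2 / (2 * model$N_C))
    pair <- sample(k, 2)
    merge_nodes(active[pair[1]], active[pair[2]], now, "C")
    active <- c(active[-pair], nxt - 1L)
  }
  structure(list(time = time, parent = parent, leaves = leaves,
                 epoch = epoch, model = model),
            class = "coal_genealogy")
}

# Time (and epoch) at which the two A lineages coalesce within population A,
# by inverting the cumulative drift at an Exp(1) exposure; time = Inf means
# the pair survives into the ancestral population.
coal_time_within_A <- function(model, E) {
  if (inherits(model, "split_model")) {
    T <- 2 * model$N_A * E
    if (T <= model$t) return(list(time = T, epoch = "A"))
  } else if (inherits(model, "growth_model")) {
    T <- invert_rescaled_time(model$r_A, 2 * model$N_A0 * E)
    if (T <= model$t) return(list(time = T, epoch = "A"))
  } else if (inherits(model, "bottleneck_model")) {
    d1 <- (model$t - model$t_b) / (2 * model$N_A)
    if (E <= d1) return(list(time = 2 * model$N_A * E, epoch = "A"))
    if (E <= d1 + model$t_b / (2 * model$N_b))
      return(list(time = (model$t - model$t_b) + (E - d1) * 2 * model$N_b,
                  epoch = "bottleneck"))
  } else if (inherits(model, "founder_model")) {
    d1 <- model$t / (2 * model$N_A)
    if (E <= d1) return(list(time = 2 * model$N_A * E, epoch = "A"))
    if (E <= d1 + model$s / (2 * model$N_A))
      return(list(time = model$t, epoch = "burst"))
  }
  list(time = Inf, epoch = NA_character_)
}

coal_time_within_B <- function(model, E) {
  if (inherits(model, "growth_model")) {
    T <- invert_rescaled_time(model$r_B, 2 * model$N_B0 * E)
  } else {
    T <- 2 * model$N_B * E
  }
  if (T <= model$t) list(time = T, epoch = "B") else list(time = Inf, epoch = NA)
}

# Inverse of rescaled_time(): the real time T at which the rescaled clock
# reaches `target`; Inf when a declining (pastwards-growing) population never
# accumulates that much drift.
invert_rescaled_time <- function(r, target) {
  if (abs(r) < 1e-14) return(target)
  x <- r * target
  if (x <= -1) return(Inf)
  log1p(x) / r
}

#' Classify a genealogy into the six labeled topologies
#'
#' Maps a simulated genealogy to its topology label: `alpha` (same-population
#' cherries in both A and B), `beta_B`/`beta_C` (B cherry, in population B or
#' the ancestral population), `gamma_A`/`gamma_bot`/`gamma_C` (A cherry, in
#' A, in the bottleneck or founder burst, or in the ancestral population),
#' `delta` (two mixed cherries), `epsilon` (mixed cherry joined by a B
#' lineage), or `zeta` (mixed cherry joined by an A lineage).
#'
#' @param g A `coal_genealogy` from [simulate_genealogy()].
#' @return A length-one character label.
#' @export
classify_topology <- function(g) {
  stopifnot(inherits(g, "coal_genealogy"))
  comp <- genealogy_compositions(g)
  has <- function(a, b) which(comp[, 1] == a & comp[, 2] == b)
  iA <- has(2, 0); iB <- has(0, 2)
  if (length(iA) && length(iB)) return("alpha")
  if (length(iB)) {
    return(if (identical(g$epoch[iB + 4L], "B")) "beta_B" else "beta_C")
  }
  if (length(iA)) {
    ep <- g$epoch[iA + 4L]
    return(switch(ep, A = "gamma_A", bottleneck = "gamma_bot",
                  burst = "gamma_bot", C = "gamma_C",
                  stop("classify_topology: malformed genealogy", call. = FALSE)))
  }
  if (length(has(1, 2))) return("epsilon")
  if (length(has(2, 1))) return("zeta")
  if (sum(comp[, 1] == 1 & comp[, 2] == 1) == 2) return("delta")
  stop("classify_topology: malformed genealogy", call. = FALSE)
}

# (nA, nB) descendant-sample composition of the three internal nodes
# (rows: nodes 5, 6, 7)
genealogy_compositions <- function(g) {
  t(vapply(g$leaves[5:7], function(lv) {
    c(sum(lv <= 2), sum(lv >= 3))
  }, integer(2)))
}

#' Shared-capable branch lengths of a genealogy
#'
#' Total branch length (in generations) ancestral to exactly one A and one B
#' sampled lineage (`L11`), one A and two B (`L12`), and two A and one B
#' (`L21`). A mutation on such a branch produces a shared SNP of the
#' corresponding type. These branches only exist between an inter-population
#' coalescence and the next event, hence always inside the ancestral
#' population; they are zero for topology `alpha`.
#'
#' @inheritParams classify_topology
#' @return A one-row tibble with columns `L11`, `L12`, `L21`,
#'   `L_shared_total`.
#' @export
shared_branch_lengths <- function(g) {
  stopifnot(inherits(g, "coal_genealogy"))
  comp <- genealogy_compositions(g)
  L <- c(`11` = 0, `12` = 0, `21` = 0)
  for (i in 1:2) {  # nodes 5 and 6; the root (7) has no branch above it
    node <- i + 4L
    key <- paste0(comp[i, 1], comp[i, 2])
    if (key %in% names(L))
      L[key] <- L[key] + g$time[g$parent[node]] - g$time[node]
  }
  tibble::tibble(L11 = L[["11"]], L12 = L[["12"]], L21 = L[["21"]],
                 L_shared_total = sum(L))
}

#' Simulate many genealogies at once (vectorized)
#'
#' Draws `n` independent genealogies of the 2 + 2 sample and returns, per
#' replicate, the topology label and the shared-capable branch lengths. This
#' is the same process as [simulate_genealogy()], expressed through
#' vectorized draws: within-population coalescence indicators come from
#' Exp(1) exposures against each population's cumulative drift, the merge
#' order among lineages entering the ancestral population from uniform
#' draws over equally likely pairs, and the in-C inter-event times from
#' exponential waiting times with rates `k (k - 1) / 2` per `2 N_C`
#' generations.
#'
#' @inheritParams topology_probabilities
#' @param n Number of replicate genealogies.
#' @param seed Optional integer seed.
#' @return A tibble with `n` rows and columns `topology` (refined label),
#'   `L11`, `L12`, `L21`.
#' @export
simulate_genealogies <- function(model, n, seed = NULL) {
  validate_model(model)
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_genealogies(model, n)))
  d <- drift_components(model)
  EA <- stats::rexp(n)
  EB <- stats::rexp(n)
  coalA_main <- EA <= d$dA_main
  coalA_bot <- !coalA_main & EA <= d$dA_main + d$dA_bot
  coalA <- coalA_main | coalA_bot
  coalB <- EB <= d$dB

  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  topo <- character(n)

  both <- coalA & coalB
  topo[both] <- "alpha"

  onlyA <- coalA & !coalB
  topo[onlyA] <- ifelse(u1[onlyA] < 2 / 3,
                        ifelse(coalA_bot[onlyA], "gamma_bot", "gamma_A"),
                        "alpha")
  onlyB <- !coalA & coalB
  topo[onlyB] <- ifelse(u1[onlyB] < 2 / 3, "beta_B", "alpha")

  none <- !coalA & !coalB
  # first in-C merge: (A,A) w.p. 1/6, (B,B) 1/6, mixed 4/6
  first_aa <- none & u1 < 1 / 6
  first_bb <- none & u1 >= 1 / 6 & u1 < 2 / 6
  first_mix <- none & u1 >= 2 / 6
  topo[first_aa] <- ifelse(u2[first_aa] < 2 / 3, "gamma_C", "alpha")
  topo[first_bb] <- ifelse(u2[first_bb] < 2 / 3, "beta_C", "alpha")
  topo[first_mix] <- ifelse(u2[first_mix] < 1 / 3, "zeta",
                            ifelse(u2[first_mix] < 2 / 3, "epsilon", "delta"))

  T2 <- stats::rexp(n, rate = 1 / (2 * model$N_C))
  T3 <- stats::rexp(n, rate = 3 / (2 * model$N_C))
  L11 <- L12 <- L21 <- numeric(n)
  base <- sub("_.*", "", topo)
  L12[base == "beta"] <- T2[base == "beta"]
  L21[base == "gamma"] <- T2[base == "gamma"]
  L11[topo == "delta"] <- T3[topo == "delta"] + 2 * T2[topo == "delta"]
  L11[topo == "epsilon"] <- T3[topo == "epsilon"]
  L12[topo == "epsilon"] <- T2[topo == "epsilon"]
  L11[topo == "zeta"] <- T3[topo == "zeta"]
  L21[topo == "zeta"] <- T2[topo == "zeta"]

  tibble::tibble(topology = topo, L11 = L11, L12 = L12, L21 = L21)
}

#' Monte Carlo topology frequencies
#'
#' Relative frequencies of the nine refined topology labels over simulated
#' genealogies, with binomial standard errors; the Monte Carlo counterpart
#' of [topology_probabilities()].
#'
#' @inheritParams simulate_genealogies
#' @return A tibble with columns `topology`, `count`, `frequency`, `se`.
#' @export
estimate_topology_frequencies <- function(model, n = 2e5, seed = NULL) {
  sims <- simulate_genealogies(model, n, seed = seed)
  labels <- c("alpha", "beta_B", "beta_C", "gamma_A", "gamma_bot", "gamma_C",
              "delta", "epsilon", "zeta")
  counts <- table(factor(sims$topology, levels = labels))
  freq <- as.numeric(counts) / n
  tibble::tibble(topology = labels, count = as.integer(counts),
                 frequency = freq, se = sqrt(freq * (1 - freq) / n))
}

#' Monte Carlo estimate of the moments of Psi
#'
#' Estimates `E[Psi]`, `E[Psi^2]` and `V[Psi]` from simulated genealogies as
#' ratios of Monte Carlo means of shared-capable branch lengths:
#' `mean = (mean L21 - mean L12) / (mean L11 + mean L12 + mean L21)`, and
#' analogously with `L21 + L12` in the numerator for the second moment. The
#' ratio of means is the consistent estimator of the single-SNP moments
#' (each moment is a ratio of expectations); the mean of per-tree ratios,
#' available as `estimator = "per_tree"`, is biased and provided only for
#' comparison. Standard errors come from a nonparametric bootstrap over
#' replicate genealogies.
#'
#' @inheritParams simulate_genealogies
#' @param n Number of replicate genealogies (at least 1000).
#' @param n_boot Bootstrap resamples for standard errors (default 200).
#' @param estimator `"ratio_of_means"` (default) or `"per_tree"`.
#' @return An object of class `psi_mc`; see [tidy.psi_mc()]. Components
#'   include `estimates` (tibble with `term`, `estimate`, `std.error`),
#'   `n`, and the closed-form moments for the same model.
#' @export
estimate_psi_moments <- function(model, n = 2e5, seed = NULL, n_boot = 200,
                                 estimator = c("ratio_of_means", "per_tree")) {
  estimator <- match.arg(estimator)
  if (n < 1000) stop("estimate_psi_moments: use at least 1000 replicates",
                     call. = FALSE)
  if (!is.null(seed))
    return(withr::with_seed(
      seed, estimate_psi_moments(model, n, NULL, n_boot, estimator)))

  sims <- simulate_genealogies(model, n)
  if (all(sims$L11 + sims$L12 + sims$L21 == 0))
    stop(paste("estimate_psi_moments: no genealogy produced shared-capable",
               "branches; sharing is astronomically rare under these",
               "parameters - increase n or reconsider the model"),
         call. = FALSE)

  stat <- function(idx) {
    m11 <- mean(sims$L11[idx]); m12 <- mean(sims$L12[idx])
    m21 <- mean(sims$L21[idx])
    tot <- m11 + m12 + m21
    if (estimator == "per_tree") {
      sh <- sims[idx, ]
      sh <- sh[sh$L11 + sh$L12 + sh$L21 > 0, ]
      mu <- mean((sh$L21 - sh$L12) / (sh$L11 + sh$L12 + sh$L21))
      m2 <- mean((sh$L21 + sh$L12) / (sh$L11 + sh$L12 + sh$L21))
    } else {
      mu <- (m21 - m12) / tot
      m2 <- (m21 + m12) / tot
    }
    c(mean = mu, second_moment = m2, variance = m2 - mu^2)
  }
  est <- stat(seq_len(n))
  boot <- vapply(seq_len(n_boot),
                 function(b) stat(sample.int(n, n, replace = TRUE)),
                 numeric(3))
  se <- apply(boot, 1, stats::sd)
  structure(list(
    estimates = tibble::tibble(term = names(est), estimate = unname(est),
                               std.error = unname(se)),
    n = n, n_boot = n_boot, estimator = estimator, model = model,
    closed_form = psi_moments(model)),
    class = "psi_mc")
}

#' @export
print.psi_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo Psi moments (%s, %d genealogies, %s estimator)\n",
              class(x$model)[1], x$n, x$estimator))
  cf <- unlist(x$closed_form)[x$estimates$term]
  out <- x$estimates
  out$closed_form <- unname(cf)
  out$z <- (out$estimate - out$closed_form) / out$std.error
  print(as.data.frame(out), digits = 4, row.names = FALSE)
  invisible(x)
}
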