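test_that("simulated genealogies are well-formed and deterministic under a seed", {
  m <- founder_model(400, 600, 1000, t = 80, s = 20)
  for (r in 1:20) {
    g <- simulate_genealogy(m, seed = 900 + r)
    node_times <- g$time[5:7]
    expect_length(node_times, 3)
    expect_true(all(is.finite(node_times)))
    expect_true(all(diff(sort(node_times)) >= 0))
    comp <- coalpsi:::genealogy_compositions(g)
    mixed <- comp[, 1] >= 1 & comp[, 2] >= 1
    expect_true(all(g$time[5:7][mixed] >= m$t))  # inter-population merges in C
    expect_equal(comp[3, ], c(2L, 2L))           # root is ancestral to all
  }
  expect_identical(simulate_genealogy(m, seed = 5),
                   simulate_genealogy(m, seed = 5))
})

test_that("topologies classify by cherry composition and location", {
  # both cherries within their populations
  g_alpha <- make_genealogy(list(c(1, 2), c(3, 4), c(5, 6)),
                            times = c(10, 20, 150), epochs = c("A", "B", "C"))
  expect_equal(classify_topology(g_alpha), "alpha")
  # B cherry in B, A lineage joins in C
  g_beta <- make_genealogy(list(c(3, 4), c(5, 1), c(6, 2)),
                           times = c(20, 120, 180), epochs = c("B", "C", "C"))
  expect_equal(classify_topology(g_beta), "beta_B")
  # A cherry in the founder burst
  g_gbot <- make_genealogy(list(c(1, 2), c(5, 3), c(6, 4)),
                           times = c(80, 120, 180),
                           epochs = c("burst", "C", "C"))
  expect_equal(classify_topology(g_gbot), "gamma_bot")
  # all merges in C
  g_eps <- make_genealogy(list(c(1, 3), c(5, 4), c(6, 2)),
                          times = c(100, 130, 200), epochs = c("C", "C", "C"))
  expect_equal(classify_topology(g_eps), "epsilon")
  g_zeta <- make_genealogy(list(c(1, 3), c(5, 2), c(6, 4)),
                           times = c(100, 130, 200), epochs = c("C", "C", "C"))
  expect_equal(classify_topology(g_zeta), "zeta")
  g_delta <- make_genealogy(list(c(1, 3), c(2, 4), c(5, 6)),
                            times = c(100, 130, 200), epochs = c("C", "C", "C"))
  expect_equal(classify_topology(g_delta), "delta")
})

test_that("shared branch lengths accumulate by descendant class", {
  g_alpha <- make_genealogy(list(c(1, 2), c(3, 4), c(5, 6)),
                            times = c(10, 20, 150), epochs = c("A", "B", "C"))
  expect_equal(unlist(shared_branch_lengths(g_alpha)),
               c(L11 = 0, L12 = 0, L21 = 0, L_shared_total = 0))
  # beta: the (1,2)-class branch runs from the mixed merge to the root
  g_beta <- make_genealogy(list(c(3, 4), c(5, 1), c(6, 2)),
                           times = c(20, 120, 180), epochs = c("B", "C", "C"))
  sb <- shared_branch_lengths(g_beta)
  expect_equal(sb$L12, 60)
  expect_equal(sb$L11, 0)
  expect_equal(sb$L21, 0)
  # epsilon: (1,1) cherry branch then a (1,2) branch
  g_eps <- make_genealogy(list(c(1, 3), c(5, 4), c(6, 2)),
                          times = c(100, 130, 200), epochs = c("C", "C", "C"))
  se <- shared_branch_lengths(g_eps)
  expect_equal(se$L11, 30)
  expect_equal(se$L12, 70)
})

test_that("ancestral-population-only demography gives the exchangeable topology frequencies", {
  freq <- estimate_topology_frequencies(split_model(400, 600, 1000, t = 0),
                                        n = 1e5, seed = 1)
  theory <- c(alpha = 1 / 9, beta_B = 0, beta_C = 1 / 9, gamma_A = 0,
              gamma_bot = 0, gamma_C = 1 / 9, delta = 2 / 9,
              epsilon = 2 / 9, zeta = 2 / 9)
  for (i in seq_len(nrow(freq))) {
    th <- theory[[freq$topology[i]]]
    se <- sqrt(th * (1 - th) / 1e5)
    expect_lt(abs(freq$frequency[i] - th), max(4 * se, 1e-9))
  }
})

test_that("sequential and vectorized simulators agree with the closed-form topology law", {
  m <- founder_model(400, 600, 1000, t = 80, s = 20)
  p <- topology_probabilities(m)
  theory <- c(alpha = p$p_alpha, beta_B = p$p_beta_B, beta_C = p$p_beta_C,
              gamma_A = p$p_gamma_A, gamma_bot = p$p_gamma_bot,
              gamma_C = p$p_gamma_C, delta = p$p_delta,
              epsilon = p$p_epsilon, zeta = p$p_zeta)
  # vectorized
  freq <- estimate_topology_frequencies(m, n = 1e5, seed = 2)
  for (i in seq_len(nrow(freq))) {
    th <- theory[[freq$topology[i]]]
    expect_lt(abs(freq$frequency[i] - th),
              4 * sqrt(th * (1 - th) / 1e5) + 1e-9)
  }
  # sequential (event-by-event) simulator, smaller sample
  n_seq <- 2e4
  labs <- withr::with_seed(77, vapply(seq_len(n_seq), function(i) {
    classify_topology(simulate_genealogy(m))
  }, character(1)))
  tab <- table(factor(labs, levels = names(theory))) / n_seq
  for (nm in names(theory)) {
    expect_lt(abs(tab[[nm]] - theory[[nm]]),
              4 * sqrt(theory[[nm]] * (1 - theory[[nm]]) / n_seq) + 1e-9)
  }
})

test_that("large bursts force the A cherry below the split", {
  freq <- estimate_topology_frequencies(
    founder_model(400, 600, 1000, t = 10, s = 1e6), n = 2e4, seed = 3)
  a_cherry_early <- sum(freq$frequency[freq$topology %in%
                                         c("gamma_A", "gamma_bot", "alpha")])
  expect_gt(a_cherry_early, 0.995)
})

test_that("an infinitely weak bottleneck adds no drift in population A", {
  # N_b -> infinity freezes coalescence during the bottleneck window, so A
  # accumulates only (t - t_b)/(2 N_A) of drift: the topology distribution
  # matches a plain split whose A size is inflated to t/(t - t_b) times N_A
  p_split <- topology_probabilities(split_model(400 * 100 / 50, 600, 1000,
                                                t = 100))
  freq <- estimate_topology_frequencies(
    bottleneck_model(400, N_b = 1e12, t_b = 50, N_B = 600, N_C = 1000,
                     t = 100), n = 1e5, seed = 4)
  theory <- c(alpha = p_split$p_alpha, beta_B = p_split$p_beta_B,
              beta_C = p_split$p_beta_C, gamma_A = p_split$p_gamma_A,
              gamma_bot = 0, gamma_C = p_split$p_gamma_C,
              delta = p_split$p_delta, epsilon = p_split$p_epsilon,
              zeta = p_split$p_zeta)
  for (i in seq_len(nrow(freq))) {
    th <- theory[[freq$topology[i]]]
    expect_lt(abs(freq$frequency[i] - th),
              4 * sqrt(th * (1 - th) / 1e5) + 1e-9)
  }
})

test_that("Monte Carlo psi moments match the closed forms and ignore N_C", {
  m <- founder_model(400, 600, 1000, t = 80, s = 20)
  est <- estimate_psi_moments(m, n = 2e5, seed = 10)
  td <- tidy(est)
  expect_true(all(abs(td$z) < 4))
  # symmetric split: mean within 4 SE of zero
  sym <- estimate_psi_moments(split_model(500, 500, 1000, t = 100),
                              n = 2e5, seed = 11)
  ts <- tidy(sym)
  mean_row <- ts[ts$term == "mean", ]
  expect_lt(abs(mean_row$estimate), 4 * mean_row$std.error)
  # ancestral size only scales branch lengths, not the moment estimates
  lo <- tidy(estimate_psi_moments(founder_model(400, 600, 500, 80, 20),
                                  n = 2e5, seed = 12))
  hi <- tidy(estimate_psi_moments(founder_model(400, 600, 2000, 80, 20),
                                  n = 2e5, seed = 13))
  for (term in c("mean", "variance")) {
    a <- lo[lo$term == term, ]; b <- hi[hi$term == term, ]
    expect_lt(abs(a$estimate - b$estimate),
              4 * sqrt(a$std.error^2 + b$std.error^2))
  }
  expect_error(estimate_psi_moments(m, n = 10), "1000")
})

test_that("mirror-image demographies give mirror-image estimates", {
  m <- split_model(300, 900, 1000, t = 150)
  a <- tidy(estimate_psi_moments(m, n = 1e5, seed = 20))
  b <- tidy(estimate_psi_moments(coalpsi:::swap_populations(m),
                                 n = 1e5, seed = 21))
  am <- a[a$term == "mean", ]; bm <- b[b$term == "mean", ]
  expect_lt(abs(am$estimate + bm$estimate),
            4 * sqrt(am$std.error^2 + bm$std.error^2))
})

test_that("shared branch lengths are exchangeable under a symmetric split", {
  sims <- simulate_genealogies(split_model(500, 500, 1000, t = 120),
                               n = 2e5, seed = 30)
  se <- sqrt((stats::var(sims$L12) + stats::var(sims$L21)) / 2e5)
  expect_lt(abs(mean(sims$L12) - mean(sims$L21)), 4 * se)
})

test_that("synthetic alignments respect the mutation model and the seed contract", {
  m <- founder_model(400, 600, 1000, t = 80, s = 20)
  # no mutation: identical sequences, downstream finds nothing usable
  ls0 <- simulate_alignments(m, mu = 0, num_loci = 3, locus_length = 100,
                             seed = 1)
  expect_true(all(vapply(ls0$loci, function(x) all(x == "A"), logical(1))))
  q0 <- quartet_resample(ls0, num_quartets = 5, seed = 1)
  expect_true(all(q0$n_shared == 0))
  expect_true(all(is.na(q0$psi)))
  # byte-identical FASTA under a fixed seed; stable under num_loci extension
  ls1 <- simulate_alignments(m, mu = 5e-6, num_loci = 4, locus_length = 300,
                             seed = 42)
  ls2 <- simulate_alignments(m, mu = 5e-6, num_loci = 6, locus_length = 300,
                             seed = 42)
  expect_identical(ls1$loci, ls2$loci[1:4])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_locus_set(ls1, d1)
  write_locus_set(simulate_alignments(m, mu = 5e-6, num_loci = 4,
                                      locus_length = 300, seed = 42), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # outgroup carries the ancestral base everywhere by default
  expect_true(all(vapply(ls1$loci, function(x) all(x["OUT", ] == "A"),
                         logical(1))))
  # impossible density errors out with advice
  expect_error(simulate_alignments(m, mu = 1, num_loci = 1, locus_length = 2,
                                   seed = 1), "longer")
})

test_that("shared-site counts in alignments match the expected shared-SNP count", {
  m <- founder_model(400, 600, 1000, t = 80, s = 20)
  mu <- 5e-6; L <- 400; n_loci <- 400
  ls <- simulate_alignments(m, mu = mu, num_loci = n_loci, locus_length = L,
                            seed = 7)
  per_locus <- vapply(names(ls$loci), function(id) {
    aln <- ls$loci[[id]]
    cnt <- classify_sites(aln[1:4, ], aln[5, ])
    cnt$n11 + cnt$n12 + cnt$n21
  }, numeric(1))
  expected <- expected_shared_snp_count(m, mu, num_sites = L)
  se <- stats::sd(per_locus) / sqrt(n_loci)
  expect_lt(abs(mean(per_locus) - expected), 4 * se)
})
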