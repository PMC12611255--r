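# random-but-reproducible model generators used across property tests;
# sizes and times span the regimes the closed forms are used in (moderate
# drift, so Monte Carlo comparisons have usable signal)

random_model <- function(family, rng = NULL) {
  draw <- function() {
    N_A <- runif(1, 200, 2000)
    N_B <- runif(1, 200, 2000)
    N_C <- runif(1, 300, 3000)
    t <- runif(1, 10, 500)
    switch(family,
      split = split_model(N_A, N_B, N_C, t),
      growth = growth_model(N_A, N_B, N_C, t,
                            r_A = runif(1, -0.004, 0.004),
                            r_B = runif(1, -0.004, 0.004)),
      bottleneck = bottleneck_model(N_A, N_b = runif(1, 20, 500),
                                    t_b = runif(1, 0, 1) * t,
                                    N_B = N_B, N_C = N_C, t = t),
      founder = founder_model(N_A, N_B, N_C, t, s = runif(1, 0, 200)))
  }
  if (is.null(rng)) draw() else withr::with_seed(rng, draw())
}

model_families <- c("split", "growth", "bottleneck", "founder")

# hand-built genealogy objects for unit tests of classification
make_genealogy <- function(merges, times, epochs) {
  # merges: list of length-2 integer vectors of node ids merged, in order
  leaves <- c(as.list(1:4), vector("list", 3))
  parent <- rep(NA_integer_, 7)
  time <- c(0, 0, 0, 0, times)
  for (i in seq_along(merges)) {
    node <- 4L + i
    leaves[[node]] <- sort(unlist(leaves[merges[[i]]]))
    parent[merges[[i]]] <- node
  }
  structure(list(time = time, parent = parent, leaves = leaves,
                 epoch = c(rep(NA, 4), epochs), model = NULL),
            class = "coal_genealogy")
}
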