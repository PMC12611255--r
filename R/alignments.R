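#' Simulate synthetic locus alignments under a demographic model
#'
#' Generates unlinked loci, each from one independent simulated genealogy of
#' the 2 + 2 sample, with mutations dropped on every branch as a Poisson
#' process at rate `mu` per site per generation (expected
#' `mu * locus_length * branch length` mutations per branch). Each mutation
#' occupies its own site (infinitely-many-sites: sites are drawn without
#' replacement from the locus positions), the ancestral base is `A` and the
#' derived base `T`. Each locus yields five aligned haploid sequences: the
#' four ingroup samples `A_1`, `A_2`, `B_1`, `B_2` and an outgroup `OUT`
#' carrying the ancestral state at every site. An optional
#' `outgroup_divergence` (expected substitutions per site on the outgroup
#' lineage) overwrites outgroup bases with `G` at random sites to exercise
#' the downstream multi-allelic filter; the default of 0 keeps the fixture
#' exactly polarizable.
#'
#' A single `seed` drives one child seed per locus, so earlier loci are
#' reproduced byte-identically when `num_loci` changes.
#'
#' @inheritParams topology_probabilities
#' @param mu Mutation rate per site per generation.
#' @param num_loci Number of unlinked loci.
#' @param locus_length Number of sites per locus.
#' @param seed Integer seed (required: fixtures are a determinism contract).
#' @param outgroup_divergence Expected outgroup substitutions per site
#'   (default 0).
#' @return An object of class `locus_set`: a list with `loci` (per-locus
#'   5 x `locus_length` character matrices, rows `A_1`, `A_2`, `B_1`, `B_2`,
#'   `OUT`), `manifest` (tibble with per-locus id, child seed and true
#'   mutation count), `model`, `mu`, `locus_length`, `seed`.
#' @examples
#' ls <- simulate_alignments(founder_model(400, 600, 1000, t = 80, s = 20),
#'                           mu = 5e-6, num_loci = 3, locus_length = 200,
#'                           seed = 1)
#' ls$manifest
#' @export
simulate_alignments <- function(model, mu, num_loci, locus_length, seed,
                                outgroup_divergence = 0) {
  validate_model(model)
  stopifnot(is.numeric(mu), mu >= 0, num_loci >= 1, locus_length >= 1)
  seeds <- vapply(seq_len(num_loci), function(i) child_seed(seed, i), double(1))
  loci <- vector("list", num_loci)
  nmut <- integer(num_loci)
  for (i in seq_len(num_loci)) {
    loci[[i]] <- withr::with_seed(seeds[i], simulate_locus(
      model, mu, locus_length, outgroup_divergence))
    nmut[i] <- attr(loci[[i]], "n_mutations")
    attr(loci[[i]], "n_mutations") <- NULL
  }
  ids <- sprintf("locus_%04d", seq_len(num_loci))
  names(loci) <- ids
  structure(list(
    loci = loci,
    manifest = tibble::tibble(locus_id = ids, child_seed = seeds,
                              n_mutations = nmut),
    model = model, mu = mu, locus_length = locus_length, seed = seed,
    outgroup_divergence = outgroup_divergence),
    class = "locus_set")
}

# deterministic child stream: one seed per locus, independent of num_loci
child_seed <- function(seed, i) {
  (as.double(seed) + 48271 * as.double(i)) %% 2147483647
}

simulate_locus <- function(model, mu, locus_length, outgroup_divergence) {
  g <- simulate_genealogy(model)
  aln <- matrix("A", nrow = 5, ncol = locus_length,
                dimnames = list(c("A_1", "A_2", "B_1", "B_2", "OUT"), NULL))
  # branch above each non-root node; mutations there are shared by its leaves
  blen <- g$time[g$parent[1:6]] - g$time[1:6]
  k <- stats::rpois(6, mu * locus_length * blen)
  total <- sum(k)
  if (total > locus_length)
    stop(paste("simulate_locus: more mutations than sites; use a longer",
               "locus or a smaller mu"), call. = FALSE)
  if (total > 0) {
    sites <- sample.int(locus_length, total)
    pos <- 0L
    for (node in 1:6) {
      if (k[node] == 0) next
      carrier <- g$leaves[[node]]
      aln[carrier, sites[pos + seq_len(k[node])]] <- "T"
      pos <- pos + k[node]
    }
  }
  if (outgroup_divergence > 0) {
    n_out <- stats::rpois(1, outgroup_divergence * locus_length)
    if (n_out > 0)
      aln["OUT", sample.int(locus_length, min(n_out, locus_length))] <- "G"
  }
  attr(aln, "n_mutations") <- total
  aln
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("<locus_set: %d loci x %d sites, %s model, mu = %g, seed = %s>\n",
              length(x$loci), x$locus_length, class(x$model)[1], x$mu,
              format(x$seed)))
  cat(sprintf("  total mutations: %d\n", sum(x$manifest$n_mutations)))
  invisible(x)
}

#' Write a locus set to FASTA files with a manifest and population map
#'
#' Writes one uncompressed FASTA file per locus (`<locus_id>.fasta`,
#' sequence ids `A_1`, `A_2`, `B_1`, `B_2`, `OUT`), a two-column population
#' map `popmap.tsv` (sequence id, role in `popA`/`popB`/`outgroup`), and a
#' YAML `manifest.yaml` recording the seed, model parameters, and per-locus
#' true mutation counts.
#'
#' @param x A `locus_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus_set <- function(x, dir) {
  stopifnot(inherits(x, "locus_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(x$loci)) {
    seqs <- apply(x$loci[[id]], 1, paste0, collapse = "")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(dir, paste0(id, ".fasta")))
  }
  utils::write.table(
    data.frame(id = c("A_1", "A_2", "B_1", "B_2", "OUT"),
               role = c("popA", "popA", "popB", "popB", "outgroup")),
    file.path(dir, "popmap.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(
    seed = x$seed, mu = x$mu, locus_length = x$locus_length,
    outgroup_divergence = x$outgroup_divergence,
    family = sub("_model$", "", class(x$model)[1]),
    model = unclass(x$model),
    loci = stats::setNames(as.list(x$manifest$n_mutations),
                           x$manifest$locus_id)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
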