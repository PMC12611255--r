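#' Load per-locus alignments and a population map
#'
#' Reads a directory of per-locus FASTA files (one multiple sequence
#' alignment per locus; equal-length sequences including exactly one
#' outgroup) together with a two-column population map (sequence id, role in
#' `popA` / `popB` / `outgroup`, no header). Sequence ids missing from a
#' locus are allowed; quartets involving them simply skip that locus.
#'
#' @param dir Directory containing `*.fasta` / `*.fa` files.
#' @param popmap Path to the population map (default `popmap.tsv` in `dir`).
#' @return An object of class `locus_alignments`: list with `alignments`
#'   (named list of character matrices, rows named by sequence id), `popA`,
#'   `popB` (character vectors of labels) and `outgroup` (single label).
#' @export
read_locus_alignments <- function(dir, popmap = file.path(dir, "popmap.tsv")) {
  files <- list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  if (!length(files))
    stop("read_locus_alignments: no FASTA files in ", dir, call. = FALSE)
  aln <- lapply(files, function(f) {
    as.matrix(Biostrings::readDNAStringSet(f))
  })
  names(aln) <- sub("\\.(fasta|fa)$", "", basename(files))
  pm <- utils::read.table(popmap, header = FALSE, sep = "\t",
                          col.names = c("id", "role"),
                          colClasses = "character")
  new_locus_alignments(aln, pm$id[pm$role == "popA"],
                       pm$id[pm$role == "popB"],
                       pm$id[pm$role == "outgroup"])
}

new_locus_alignments <- function(alignments, popA, popB, outgroup) {
  if (length(outgroup) != 1)
    stop("locus_alignments: exactly one outgroup sequence is required",
         call. = FALSE)
  if (length(popA) < 2 || length(popB) < 2)
    stop("locus_alignments: at least two sequence labels per ingroup population",
         call. = FALSE)
  structure(list(alignments = alignments, popA = popA, popB = popB,
                 outgroup = outgroup),
            class = "locus_alignments")
}

#' Convert a simulated locus set into the empirical-pipeline input format
#'
#' @param x A `locus_set` from [simulate_alignments()].
#' @return A `locus_alignments` object (see [read_locus_alignments()]).
#' @export
as_locus_alignments <- function(x) {
  stopifnot(inherits(x, "locus_set"))
  new_locus_alignments(x$loci, c("A_1", "A_2"), c("B_1", "B_2"), "OUT")
}

#' @export
print.locus_alignments <- function(x, ...) {
  cat(sprintf("<locus_alignments: %d loci; popA: %d, popB: %d, outgroup: %s>\n",
              length(x$alignments), length(x$popA), length(x$popB),
              x$outgroup))
  invisible(x)
}

#' Classify alignment sites of a quartet against an outgroup
#'
#' Applies the site filters to an alignment of four ingroup sequences (two
#' per population) plus one outgroup, site by site: (1) discard sites where
#' any of the five characters is a gap or ambiguity code; (2) discard
#' invariable sites and sites with three or more distinct bases among the
#' five sequences; (3) polarize the remaining biallelic sites with the
#' outgroup base as the ancestral state; (4) keep only shared sites — the
#' derived allele present in at least one copy in each population and the
#' pooled ingroup polymorphic (which excludes derived-copy counts of 0 in
#' either population and the (2,2) configuration). Kept sites are tallied by
#' type: `n11`, `n12`, `n21` count sites with (1,1), (1,2) and (2,1) derived
#' copies in the (A, B) samples.
#'
#' @param quartet Four ingroup sequences, in order `A_1`, `A_2`, `B_1`,
#'   `B_2`: a character vector of four equal-length strings or a
#'   4-row character matrix of single bases.
#' @param outgroup The outgroup sequence (string or character vector of
#'   bases) of the same aligned length.
#' @return A one-row tibble with columns `n11`, `n12`, `n21`,
#'   `n_discarded_gap`, `n_discarded_invariant_or_multiallelic`,
#'   `n_discarded_not_shared`; the six columns sum to the aligned length.
#' @examples
#' classify_sites(c("TCAT", "TGAT", "TGAT", "AGGT"), "ACAC")
#' @export
classify_sites <- function(quartet, outgroup) {
  m <- rbind(as_base_matrix(quartet, 4), as_base_matrix(outgroup, 1))
  types <- site_types(m)
  tibble::tibble(
    n11 = sum(types == 11L), n12 = sum(types == 12L),
    n21 = sum(types == 21L),
    n_discarded_gap = sum(types == -1L),
    n_discarded_invariant_or_multiallelic = sum(types == -2L),
    n_discarded_not_shared = sum(types == -3L))
}

as_base_matrix <- function(x, nrow_expected) {
  if (is.matrix(x)) m <- x
  else {
    if (!is.character(x)) stop("sequences must be character", call. = FALSE)
    if (length(x) > 1 && all(nchar(x) == 1) && nrow_expected == 1)
      m <- matrix(x, nrow = 1)
    else {
      if (length(unique(nchar(x))) != 1)
        stop("classify_sites: sequences have unequal aligned lengths",
             call. = FALSE)
      m <- do.call(rbind, strsplit(x, ""))
    }
  }
  if (nrow(m) != nrow_expected)
    stop(sprintf("expected %d sequence(s), got %d", nrow_expected, nrow(m)),
         call. = FALSE)
  if (ncol(m) == 0) stop("classify_sites: empty alignment", call. = FALSE)
  m
}

# Per-site type codes for a 5-row base matrix (A_1, A_2, B_1, B_2, OUT):
# 11/12/21 for kept shared sites; -1 gap/ambiguity, -2 invariant or >= 3
# alleles, -3 biallelic but not shared. Ambiguity codes (N, IUPAC) count as
# gaps; gaps are never counted as alleles, so the gap filter commutes with
# the allele-count filter.
site_types <- function(m) {
  stopifnot(nrow(m) == 5)
  M <- toupper(m)
  L <- ncol(M)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(M == b), numeric(L))
  if (L == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, bases))
  valid <- rowSums(counts) == 5
  n_alleles <- rowSums(counts > 0)
  biallelic <- valid & n_alleles == 2L

  anc <- M[5, ]
  dA <- (M[1, ] != anc) + (M[2, ] != anc)
  dB <- (M[3, ] != anc) + (M[4, ] != anc)
  shared <- biallelic & dA >= 1 & dB >= 1 & !(dA == 2 & dB == 2)

  out <- integer(L)
  out[!valid] <- -1L
  out[valid & !biallelic] <- -2L
  out[biallelic & !shared] <- -3L
  out[shared] <- as.integer(10 * dA[shared] + dB[shared])
  out
}

#' psi from shared-site type counts
#'
#' The two-lineage-per-population form of the directionality index:
#' `psi = (n21 - n12) / (n11 + n12 + n21)`. A zero denominator (no shared
#' sites) returns `NA`, which is a distinct signal from a psi of 0.
#'
#' @param counts A data frame with columns `n11`, `n12`, `n21` (e.g. from
#'   [classify_sites()]); vectorized over rows.
#' @return A numeric vector of psi values in `[-1, 1]`, `NA` where no site
#'   was shared.
#' @examples
#' psi_from_counts(data.frame(n11 = 4, n12 = 1, n21 = 3))  # 0.25
#' @export
psi_from_counts <- function(counts) {
  tot <- counts$n11 + counts$n12 + counts$n21
  ifelse(tot >= 1, (counts$n21 - counts$n12) / tot, NA_real_)
}

#' psi from per-site derived-allele frequencies
#'
#' The general definition of the directionality index: the mean over shared
#' SNPs of the difference in derived-allele frequency,
#' `mean(f_A - f_B)`. For a quartet (frequencies in 0, 1/2, 1) this equals
#' [psi_from_counts()] exactly.
#'
#' @param sites A data frame with columns `fA` and `fB`, the derived-allele
#'   frequencies of each shared SNP in populations A and B.
#' @return The psi value, or `NA` if `sites` has no rows.
#' @export
psi_general <- function(sites) {
  stopifnot(all(c("fA", "fB") %in% names(sites)))
  if (nrow(sites) == 0) return(NA_real_)
  stopifnot(all(sites$fA >= 0 & sites$fA <= 1),
            all(sites$fB >= 0 & sites$fB <= 1))
  mean(sites$fA - sites$fB)
}

# shared-site counts for one quartet of labels across all usable loci;
# memoized per label combination in `cache` (an environment) since quartets
# are drawn with replacement. Returns c(n11, n12, n21).
quartet_counts <- function(loci, a, b, cache = NULL) {
  key <- paste(c(sort(a), sort(b)), collapse = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  tot <- c(n11 = 0, n12 = 0, n21 = 0)
  want <- c(a, b, loci$outgroup)
  for (aln in loci$alignments) {
    if (!all(want %in% rownames(aln))) next
    types <- site_types(aln[want, , drop = FALSE])
    tot <- tot + c(sum(types == 11L), sum(types == 12L), sum(types == 21L))
  }
  if (!is.null(cache)) cache[[key]] <- tot
  tot
}

#' Resample quartets of sequences and compute psi per quartet
#'
#' Draws `num_quartets` sets of four sequence labels — two distinct labels
#' from population A and two from population B, sets drawn with replacement
#' across quartets — and computes psi for each from the sites shared across
#' all loci containing that quartet plus the outgroup. In `"single_site"`
#' mode (the default), one site is sampled uniformly from the quartet's
#' pooled set of shared sites and psi is its per-site value (+1 for type 21,
#' 0 for 11, -1 for 12); in `"all_sites"` mode, psi is computed from the
#' total counts. Quartets with no shared site are skipped (recorded in the
#' `n_shared` column as 0 and `psi` as `NA`) unless `on_empty = "redraw"`.
#'
#' @param loci A `locus_alignments` object (or a `locus_set`, converted
#'   automatically).
#' @param num_quartets Number of quartets to draw.
#' @param mode `"single_site"` or `"all_sites"`.
#' @param seed Optional integer seed.
#' @param on_empty `"skip"` (default) or `"redraw"` (redraw a quartet with
#'   shared sites, up to 100 attempts).
#' @return A tibble with one row per quartet: labels `a1`, `a2`, `b1`, `b2`,
#'   counts `n11`, `n12`, `n21`, `n_shared`, and `psi`.
#' @export
quartet_resample <- function(loci, num_quartets,
                             mode = c("single_site", "all_sites"),
                             seed = NULL, on_empty = c("skip", "redraw")) {
  mode <- match.arg(mode)
  on_empty <- match.arg(on_empty)
  if (inherits(loci, "locus_set")) loci <- as_locus_alignments(loci)
  stopifnot(inherits(loci, "locus_alignments"))
  if (!is.null(seed))
    return(withr::with_seed(
      seed, quartet_resample(loci, num_quartets, mode, NULL, on_empty)))
  if (num_quartets == 0)
    return(tibble::tibble(a1 = character(), a2 = character(),
                          b1 = character(), b2 = character(),
                          n11 = integer(), n12 = integer(), n21 = integer(),
                          n_shared = integer(), psi = numeric()))
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", num_quartets)
  for (q in seq_len(num_quartets)) {
    for (attempt in seq_len(100L)) {
      a <- sample(loci$popA, 2)
      b <- sample(loci$popB, 2)
      cnt <- quartet_counts(loci, a, b, cache)
      tot <- sum(cnt)
      if (tot > 0 || on_empty == "skip") break
    }
    psi <- if (tot == 0) NA_real_
    else if (mode == "all_sites") (cnt[["n21"]] - cnt[["n12"]]) / tot
    else {
      # one site uniformly from the pooled shared sites = a draw of its type
      type <- sample(c(0, -1, 1), 1, prob = cnt / tot)
      type
    }
    rows[[q]] <- tibble::tibble(
      a1 = a[1], a2 = a[2], b1 = b[1], b2 = b[2],
      n11 = unname(cnt["n11"]), n12 = unname(cnt["n12"]),
      n21 = unname(cnt["n21"]), n_shared = tot, psi = psi)
  }
  dplyr::bind_rows(rows)
}

#' Bootstrap psi over loci
#'
#' Nonparametric bootstrap of the quartet-resampling procedure over loci: in
#' each replicate, loci are resampled with replacement (same count as the
#' input), `num_quartets` quartets are drawn and psi computed per quartet,
#' and the mean and variance of psi across the replicate's successful
#' quartets are recorded. The summary reports the median and the central
#' 95% interval of the replicate means and of the replicate variances.
#'
#' @inheritParams quartet_resample
#' @param num_replicates Number of bootstrap replicates.
#' @param seed Integer seed (one child seed is derived per replicate).
#' @return An object of class `psi_bootstrap`: list with `replicates` (a
#'   tibble with `replicate`, `mean_psi`, `var_psi`, `n_quartets_used`),
#'   `summary` (one-row tibble with medians and 95% interval bounds),
#'   `num_replicates`, `num_quartets`, `mode`, `seed`.
#' @export
bootstrap_loci <- function(loci, num_replicates, num_quartets,
                           mode = c("single_site", "all_sites"),
                           seed = 1, on_empty = c("skip", "redraw")) {
  mode <- match.arg(mode)
  on_empty <- match.arg(on_empty)
  if (inherits(loci, "locus_set")) loci <- as_locus_alignments(loci)
  stopifnot(inherits(loci, "locus_alignments"))
  if (length(loci$alignments) < 1)
    stop("bootstrap_loci: at least one locus is required", call. = FALSE)
  n_loci <- length(loci$alignments)
  reps <- vector("list", num_replicates)
  for (r in seq_len(num_replicates)) {
    rep_seed <- child_seed(seed, r)
    res <- withr::with_seed(rep_seed, {
      pick <- sample.int(n_loci, n_loci, replace = TRUE)
      boot <- loci
      boot$alignments <- loci$alignments[pick]
      quartet_resample(boot, num_quartets, mode, NULL, on_empty)
    })
    ok <- !is.na(res$psi)
    reps[[r]] <- tibble::tibble(
      replicate = r,
      mean_psi = if (any(ok)) mean(res$psi[ok]) else NA_real_,
      var_psi = if (sum(ok) > 1) stats::var(res$psi[ok]) else NA_real_,
      n_quartets_used = sum(ok))
  }
  replicates <- dplyr::bind_rows(reps)
  qs <- function(x, p) unname(stats::quantile(x, p, na.rm = TRUE, type = 7))
  summary <- tibble::tibble(
    median_mean = stats::median(replicates$mean_psi, na.rm = TRUE),
    mean_lo95 = qs(replicates$mean_psi, 0.025),
    mean_hi95 = qs(replicates$mean_psi, 0.975),
    median_var = stats::median(replicates$var_psi, na.rm = TRUE),
    var_lo95 = qs(replicates$var_psi, 0.025),
    var_hi95 = qs(replicates$var_psi, 0.975))
  structure(list(replicates = replicates, summary = summary,
                 num_replicates = num_replicates,
                 num_quartets = num_quartets, mode = mode, seed = seed),
            class = "psi_bootstrap")
}

#' @export
print.psi_bootstrap <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Locus bootstrap of psi (%d replicates x %d quartets, %s mode, seed %s)\n",
              x$num_replicates, x$num_quartets, x$mode, format(x$seed)))
  cat(sprintf("  mean psi: median %.4f, 95%% interval (%.4f, %.4f)\n",
              s$median_mean, s$mean_lo95, s$mean_hi95))
  cat(sprintf("  var  psi: median %.4f, 95%% interval (%.4f, %.4f)\n",
              s$median_var, s$var_lo95, s$var_hi95))
  invisible(x)
}

#' Write per-quartet and bootstrap results to files
#'
#' Writes the per-replicate table as TSV and the summary as JSON-like YAML.
#'
#' @param x A `psi_bootstrap`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bootstrap <- function(x, dir) {
  stopifnot(inherits(x, "psi_bootstrap"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$replicates, file.path(dir, "replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(as.list(x$summary),
                     list(num_replicates = x$num_replicates,
                          num_quartets = x$num_quartets,
                          mode = x$mode, seed = x$seed)),
                   file.path(dir, "summary.yaml"))
  invisible(dir)
}
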