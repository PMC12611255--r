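---
title: "Coalescent theory of the psi directionality index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent theory of the psi directionality index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalpsi)
```

## The statistic

The directionality index ψ compares two populations through the SNPs they
share. A SNP is *shared* when its derived allele is present in at least one
copy in each population and the pooled sample is polymorphic. In its general
form, ψ(A, B) is the mean over shared SNPs of the difference in
derived-allele frequency, f<sub>A</sub> − f<sub>B</sub>. Because founder
events and bottlenecks push surviving shared alleles to higher frequencies,
the population that has experienced more drift — typically the one further
from the origin of a range expansion — shows the higher frequencies, and ψ
is signed: ψ(A, B) = −ψ(B, A), positive when A has drifted more.

With one diploid individual (two lineages) sampled per population, every
shared SNP has derived-copy counts (i, j) ∈ {(1,1), (1,2), (2,1)} and ψ
reduces to the count form

ψ(A, B) = (n<sub>21</sub> − n<sub>12</sub>) / (n<sub>11</sub> + n<sub>12</sub> + n<sub>21</sub>),

implemented in `psi_from_counts()`. (For a 2 + 2 sample the count form is
exactly twice the frequency form `psi_general()`: a type-21 site has
f<sub>A</sub> − f<sub>B</sub> = 1/2 but contributes +1 to the count form.
Both are exposed; the count form is what the single-SNP theory below refers
to.)

The package treats the single-shared-SNP index Ψ as a random variable of
the coalescent: conditional on a demography, a random genealogy of the four
sampled lineages is drawn, a random mutation falls on it, and Ψ takes the
value +1, 0 or −1 according to the SNP type. All theory is for this 2 + 2
sample; larger samples are out of scope.

## Demographies and their drift parameterization

Four parameterizations of an ancestral population C splitting into A and B
at time `t` (generations before present, diploid sizes throughout) are
provided by `split_model()`, `growth_model()`, `bottleneck_model()` and
`founder_model()`. All four reduce, for the quantities the package
computes, to two numbers: the cumulative pairwise-coalescence intensity
("drift") accumulated by the pair of lineages in each descendant
population before entering C,

* split: d<sub>A</sub> = t/(2N<sub>A</sub>),
* growth: d<sub>A</sub> = t<sub>A</sub>/(2N<sub>A,0</sub>) with the
  rescaled time t<sub>A</sub> = (e<sup>r<sub>A</sub>t</sup> − 1)/r<sub>A</sub>,
* bottleneck: d<sub>A</sub> = (t − t<sub>b</sub>)/(2N<sub>A</sub>) + t<sub>b</sub>/(2N<sub>b</sub>),
* founder: d<sub>A</sub> = (t + s)/(2N<sub>A</sub>), where the burst
  strength `s` acts as pseudo-generations of drift at size N<sub>A</sub>
  with no mutation,

and analogously d<sub>B</sub>. A pair survives its population with
probability e<sup>−d</sup>; the three within-C coalescence orders then have
the exchangeable-coalescent probabilities, which yields the probabilities
of the six labeled topologies (`topology_probabilities()`), refined by
where the same-population cherry coalesced (in the descendant population,
in the bottleneck/burst, or in C). Shared-capable branches exist only
inside C, so their expected lengths are single-population quantities in
N<sub>C</sub> (`branch_length_expectations()`), and the scaled mutation
rate cancels from all conditional probabilities. This is why E[Ψ] and V[Ψ]
are independent of N<sub>C</sub>, while the *number* of shared SNPs —
E[n] = 2N<sub>C</sub>μ·E[L] per site, `expected_shared_snp_count()` —
is linear in it.

## Closed forms and the two computation routes

Combining topologies and branch lengths gives the shared joint-SFS weights
(`shared_sfs()`), and from them the moments:

* E[Ψ] = tanh((d<sub>A</sub> − d<sub>B</sub>)/2)
* E[Ψ²] = 1 − 1/(e<sup>d<sub>A</sub></sup> + e<sup>d<sub>B</sub></sup>)
* V[Ψ] = E[Ψ²] − E[Ψ]²

`psi_moments()` implements this closed form directly and, as
`method = "sfs"`, the generic route through `topology_probabilities()` and
`shared_sfs()`. Both routes are maintained deliberately: their agreement
(to 1 × 10⁻¹⁰ relative, a standing test) catches transcription errors in
either. Odd moments of Ψ equal the mean and even moments the second moment,
by the three-point distribution (`psi_distribution()`).

### Numerical choices

* `rescaled_time()` uses `expm1()` and switches to the series
  t(1 + rt/2 + (rt)²/6) for |rt| < 10⁻⁸, so the r → 0 limit is exact and
  one-sided growth is just `r_B = 0` — no separate formula.
* The mean is evaluated as a `tanh` of drift differences, never as a ratio
  of exponentials; the second moment and variance are evaluated in
  max-shifted (log-sum-exp) form. Drift terms in the hundreds (t ≫ N)
  therefore saturate gracefully (mean → ±1, variance finite) instead of
  overflowing.
* Four-decimal display in `drosophila_table1()` truncates toward zero
  rather than rounding. The reference values that function compares against
  were printed under that convention: the full-precision growth-model means
  0.5165689 and 0.4912543 appear there as 0.5165 and 0.4912.

### A note on the bottleneck variance reference value

For the prolonged-bottleneck demography of Li & Stephan (2006),
`drosophila_table1()` reports V[Ψ] = 0.5442 while the reference value
published with that comparison is 0.5372. The package's value follows from
the formulas above with
d<sub>A</sub> = (t − t<sub>b</sub>)/(2N<sub>A</sub>) + t<sub>b</sub>/(2N<sub>b</sub>);
the reference value corresponds to attaching the bottleneck factor
e<sup>t<sub>b</sub>/(2N<sub>b</sub>)</sup> to the B-side exponential
instead. Three independent checks support the implemented form: it is the
algebraic consequence of the topology probabilities and branch lengths
(the `method = "sfs"` route agrees to 10⁻¹⁰); it satisfies the reduction
identities (N<sub>b</sub> = N<sub>A</sub> or t<sub>b</sub> = 0 recovers the
plain split, as does s = 0 for the founder model, whose published variance
*does* attach the burst to the A side); and a 3 × 10⁵-replicate
event-by-event simulation of the same demography gives
E[Ψ²] = 0.7009 ± 0.0013, matching the implemented 0.70027 and excluding
the alternative 0.69327 by more than five standard errors. The
`drosophila_table1()` pass flag honestly reports the mismatch.

## The Monte Carlo simulator

`simulate_genealogy()` draws one genealogy event by event: within-population
coalescence times by inverting each population's cumulative drift against
an Exp(1) exposure (piecewise for the bottleneck, `log1p` inversion for
growth), the founder burst applied at t⁻ (pastwards: after A's ordinary
epoch, before entry into C) as a coalescence with probability
1 − e<sup>−s/(2N_A)</sup> and zero duration, and a standard constant-size
coalescent in C. `simulate_genealogies()` expresses the same process
through vectorized draws and is what the estimators use;
`classify_topology()` and `shared_branch_lengths()` operate on single
genealogies.

`estimate_psi_moments()` estimates each moment as a **ratio of Monte Carlo
means** of shared-capable branch lengths — consistent, because each moment
is a ratio of expectations. The mean of per-tree ratios conditions on each
tree's own shared content and is biased; it is available behind
`estimator = "per_tree"` for comparison only. Standard errors come from a
nonparametric bootstrap over replicate genealogies (default 200 resamples).
Throughout the test suite, closed forms and Monte Carlo are compared at
four standard errors with 2 × 10⁵ replicates per parameter set — sizes
chosen so that each comparison has roughly per-mille resolution while a
full sweep over ten random parameter sets per family runs in a couple of
minutes.

## Synthetic data: what it emulates and what it does not

`simulate_alignments()` generates unlinked loci, one independent genealogy
each, with infinitely-many-sites mutation: mutations fall on every branch
as a Poisson process with expectation μ · locus length · branch length,
each on its own site (ancestral base `A`, derived `T`), and the outgroup
sequence carries the ancestral state everywhere. One seed drives a child
seed per locus, so extending `num_loci` reproduces earlier loci
byte-identically.

The generator emulates exactly the assumptions of the theory: free
recombination between loci and none within (one genealogy per locus),
single-mutation SNPs, a perfectly informative outgroup, two haploid
sequences per population. It does **not** emulate recombination within
loci, sequencing or alignment error, base-composition realism, back or
parallel mutation, outgroup divergence (unless `outgroup_divergence > 0`
is set to exercise the multi-allelic filter), or sample sizes beyond
2 + 2. Passing end-to-end tests therefore show that the pipeline is a
correct estimator *under the model's assumptions*; they do not validate
robustness to the realities of sequence data.

## The empirical pipeline

`classify_sites()` applies, per site of a quartet-plus-outgroup alignment:
gap/ambiguity discard (IUPAC ambiguity codes are treated as gaps — a
conservative choice that prevents phantom alleles; gaps are never counted
as alleles, so this filter commutes with the allele-count filter),
invariant and ≥3-allele discard, outgroup polarization, and the shared-site
criterion. A site whose outgroup base is absent from a polymorphic ingroup
has three states among the five sequences and falls to the ≥3-allele rule.

`quartet_resample()` draws sets of two distinct labels per population
(distinct *labels*, not necessarily distinct haplotypes), with replacement
across quartets, and computes ψ per quartet either from one site sampled
uniformly from the quartet's pooled shared sites across loci
(`"single_site"`, the default — the mode whose across-quartet variance
estimates V[Ψ]) or from the total counts (`"all_sites"`, the estimator
field studies usually report). Quartets with no shared site are skipped
and reported with `psi = NA` (an explicit diagnostic, distinct from
ψ = 0); `on_empty = "redraw"` redraws instead. `bootstrap_loci()` wraps
this in a bootstrap over loci (resampling loci with replacement, same
count as input) and summarizes replicate means and variances by their
medians and central 95% intervals. All resampling is seeded and
deterministic; per-replicate child seeds make replicate r independent of
how many replicates follow it.

The full-scale protocol used for the *D. melanogaster* Out-of-Africa
comparison — 1,000 quartets, single-site mode, 1,000 locus bootstraps over
229 X-chromosomal loci with a *D. simulans* outgroup — is the default of
the `psi` subcommand of the `exec/coalpsi` script. The sequence data are a
public archive download (ENA AJ568984–AJ571588 and AM000058–AM003900,
aligned per locus, e.g. with MUSCLE) and are not bundled; the test suite
runs the identical procedure at reduced scale on simulated fixtures.
X-linked effective sizes are converted to autosomal-equivalent diploid
sizes by `x_chromosome_rescale()` (×3/4); the sizes embedded in
`drosophila_oof_models()` are already on that scale.

## Known limitations

* Two populations, two lineages each; no migration or admixture after the
  split; no serial-founder chains.
* Non-shared joint-SFS entries (s<sub>01</sub>, s<sub>10</sub>, …) are not
  computed — they cancel from ψ.
* The locus bootstrap treats loci as exchangeable; within-locus genealogical
  correlation makes single-site draws from the same locus positively
  correlated, which widens the across-quartet spread relative to the iid
  theory (the tests allow for this explicitly).
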