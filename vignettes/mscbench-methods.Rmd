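---
title: "Models, conventions and design choices in mscbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in mscbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscbench)
```

## The problem

Under the multispecies coalescent (MSC), each locus has its own gene tree
embedded in a shared species tree: within every species-tree branch, gene
lineages coalesce backwards in time at rate $1/(2N_e)$ per pair, where $N_e$
is the branch's effective population size. When branches are short in
coalescent units $\tau/(2N_e)$, lineages frequently fail to coalesce before
the next divergence (incomplete lineage sorting) and gene trees disagree
with the species tree and with each other. Fully Bayesian MSC inference
handles this correctly but at a steep and growing MCMC cost, while
concatenation (a single tree for all loci) is fast but biased exactly where
ILS is strong. This package provides the simulation, scoring and scaling
machinery to quantify that trade-off, with every step runnable on one CPU.

## Tree model and conventions

All trees are rooted `ape::phylo` objects. Node heights are measured from
the leaves upward: tips of an ultrametric tree sit at height 0, the root at
the tree height, and a branch length is the parent height minus the child
height. Ultrametricity is checked with a tolerance of $10^{-6}$ relative to
tree height, since serialized trees lose precision; non-ultrametric Newick
input is accepted with a warning and rejected only by operations that
require ultrametricity.

The clade set of a tree contains one clade per node *except the root*:
singleton tip clades included, the full leaf set excluded, because the
rooted branch score sums lengths of branches extending rootward from each
clade's MRCA and the root has no such branch. A consequence worth knowing:
on identical topologies the RBS equals the sum of all pendant and internal
branch-length differences.

Species trees carry one $N_e$ per branch *including* a root (origin)
branch. The origin branch has an $N_e$ but no length, so it is excluded
from branch-length means while still governing coalescence above the root.

When MCMC chains are combined after a resume, the first state of the
resumed log duplicates the last state of the previous one; `combine_traces()`
drops the duplicate boundary state. This trimming rule is our convention —
reference protocols do not state one.

## Simulators (the stated world)

**Yule / birth–death species trees.** `simulate_yule()` uses the backward
construction: while $j$ lineages exist the inter-speciation time is
$\mathrm{Exp}(j\lambda)$ and a uniform pair joins, giving
$E[\text{root height}] = (H_n - 1)/\lambda$ and mean branch length
$1/(2\lambda)$. `calibrated_birth_rate()` inverts the first identity so a
target expected root height $R$ can be dialled in.
`simulate_birth_death()` runs the process forward from one origin lineage
and stops the first time the extant count reaches $n$, extended by the
exponential waiting time to the next event (which makes the $\mu = 0$ case
agree exactly, in distribution, with the Yule construction); histories that
die out are rejected and redrawn, and extinct lineages are pruned. We chose
forward-plus-rejection over conditioned inverse-CDF sampling because the
designs name the process, not the sampler, and rejection is cheap at these
rates ($\lambda = 1$, $\mu = 0.2$).

**Gene trees.** `simulate_gene_tree()` runs a per-branch exponential-time
coalescent with constant $N_e$ within each branch (no growth models), in
the same nominal units as the species tree, so coalescent branch lengths
are exactly $\tau/(2N_e)$. Gene copies are labelled `<species>_<index>` and
the copy-to-species map is derived from labels. Every simulated tree is
checkable against the nesting invariant (gene coalescence no lower than
species divergence) via `check_msc_nesting()`.

**Sequences.** `simulate_alignment()` draws the root sequence from the
stationary frequencies and evolves sites down each branch through
$\exp(Q \cdot \text{rate} \cdot \tau \cdot r_{\text{site}})$. $Q$ is
normalized to unit expected rate at stationarity so that branch length
times clock rate is in expected substitutions per site. Between-site rate
variation uses a discrete gamma with 4 categories by default (category
rates are the means of equal-probability quantile bins, so they average
exactly 1); the category count is a configuration knob because the
reference designs leave it unstated. There is no invariant-sites category.
Between-locus rate variation is either log-uniform on
$(\mu_0/F, \mu_0 F)$ with the first locus pinned at $\mu_0$ (spread factor
$F = 3$ gives a factor 9 between extremes), or i.i.d. gamma.

**Experiment defaults.** `experiment_config()` pins the three designs:
rapid birth–death radiations with HKY $\kappa = 4$, equal frequencies,
clock 0.01, 200-site loci (`exp1`); Yule trees calibrated to
$R \in \{1/2, \dots, 16\}$ with constant $N_e \in \{1/4, 1/2, 1\}$, JC,
1000-site loci, $F = 3$ (`exp2`); and empirically derived shallow/deep
GTR+$\Gamma$ designs with gamma(shape 2) per-branch population sizes and
gamma per-locus clock rates (`exp3-*`). The deep design's locus lengths are
drawn uniformly from the integers 110–3511 because only the range of the
original empirical lengths is available; the shallow design fixes 64 nt.
The `exp1` default constant $N_e = 0.004$ (4 in units of millions, for
rates per million years) is our choice of a realistic vertebrate-scale
population size producing appreciable ILS on $\lambda = 1$ trees; the
reference design does not print its value.

**Seeds.** All randomness flows from one master seed through hierarchical
substreams (`substream_seed()`): species trees depend on (seed, replicate)
only, loci on (seed, replicate, locus). Two consequences are contractual:
`exp2` regenerates gene trees for each locus-count setting while reusing
the same species trees, and the other designs make smaller locus draws
exact prefixes of larger ones, mirroring the subsetting protocol.

## Metrics and aggregation

`rbs()` implements the clade-union sum with the missing-clade-is-zero
convention, so polytomous estimates are handled naturally: an absent clade
contributes the other tree's branch length. `relative_error()` averages RBS
over posterior samples as drawn — duplicate topologies are *not* collapsed
— and normalizes by the true tree length, making errors comparable across
tree sizes and units. `rooted_rf()` is the clade symmetric difference;
`pendant_edge_bias()` is the mean of per-tip length ratios minus one
(mean-of-ratios rather than ratio-of-means, chosen so that "pendant edges
on average 4.5x the truth" reads as a bias of 350%). `summarize_errors()`
provides the 25%-trimmed mean (dropping `floor(n * trim)` per tail) with a
seeded percentile bootstrap of 1000 resamples; medians are also exposed
since both appear in this literature.

## Scaling analysis

`ess()` estimates the autocorrelation time Tracer-style: empirical ACF,
truncated by the initial-positive-sequence rule (stop at the first
negative paired sum), maximum lag $N/3$, ESS capped at $N$. The reference
tooling never defines its estimator; this is the ecosystem standard. The
burn-in fraction applied before ESS-based filtering defaults to 10% and is
configurable, again because the protocols leave it unstated.

`fit_loglog()` is OLS of $\log Y$ on $\log n_l$, $n$, $n_i$ — natural logs
throughout, a choice verified by the fact that reported (slope, intercept)
pairs reproduce their own worked predictions only under natural log.
`find_crossover()` smooths log error ratio against log coalescent branch
length with degree-1 tricube local regression (span 0.75 by default) and
locates the ratio-1 crossing by bisection on the smoothed curve; when the
curve never crosses, `NA` is the explicit no-crossover signal.

## The surrogate estimator, and what green tests do not establish

Running real Bayesian inference is out of scope (the reference studies
consumed cluster-years). `surrogate_estimate()` fabricates a
pseudo-posterior by perturbing the true species tree: multiplicative
lognormal jitter of node heights with $\sigma = \text{noise}/\sqrt{n_l}$
and an NNI topology move with probability shrinking the same way, plus
white-noise trace columns so the ESS filter is exercisable. By
construction error declines in $n_l$ roughly as a power law — that is the
point: it makes the *evaluation machinery* testable end to end
(simulation, scoring, filtering, aggregation, regression, crossover).

A green end-to-end test therefore establishes that the pipeline measures
and models error correctly — not that any real inference method follows
the recovered exponent, and not that the published regression
coefficients are reproduced; those are treated as printed inputs to the
downstream arithmetic, which *is* recomputed exactly. Likewise the
surrogate's traces are white noise, so the ESS filter's discard behaviour
on real, sticky MCMC traces is tested separately on constructed
autocorrelated series.

## Numerical choices and degenerate inputs

- Gamma-distributed $N_e$ with shape 2 has a reciprocal with infinite
  variance, so sample means of coalescent branch lengths under the
  empirical designs replicate printed values only in order of magnitude;
  tests assert exactly that and no more.
- Constant trace series make the autocorrelation (and ESS) undefined:
  error, not 0 or $N$.
- A locus with no variable sites makes mutations-per-variable-site
  undefined: reported as `NA`, not 0.
- Zero-length branches are accepted in input trees; duplicate clades then
  have their rootward lengths summed in the RBS bookkeeping.
- The Benjamini–Hochberg correction in `residual_correlations()` is scaled
  to the stated family size of 48 tests even when fewer statistics are
  supplied, matching the published procedure.
- Tip-to-root "node counts" for tree asymmetry are edge counts on the
  path (population variance); the alternative including-the-root reading
  shifts every depth by one and leaves the variance unchanged, so the
  ambiguity is harmless.

## Known limitations

No migration, hybridization or within-locus recombination; strict clocks
only (no relaxed clocks); no codon or amino-acid models; no time-varying
speciation rates or sampling fractions; unrooted-tree metrics are out of
scope. The pipeline exports bundles for external inference tools and reads
their logs, but never runs them.
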