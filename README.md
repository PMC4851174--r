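# mscbench

Simulation machinery and scaling analysis for fully Bayesian species tree
estimation under the multispecies coalescent (MSC).

Bayesian MSC methods (the *BEAST family) estimate a species tree jointly
with per-locus gene trees, but their MCMC cost grows steeply with the number
of loci. This package re-creates the simulation-study machinery needed to
study that trade-off on a desk: it simulates species trees, MSC gene trees
and sequence alignments under three published experimental designs, computes
the species-tree accuracy metrics and tree/alignment statistics used to
evaluate such methods, and fits and evaluates the power-law scaling models
that relate MCMC performance and statistical accuracy to the number of loci.
It is aimed at phylogeneticists planning multilocus studies and at method
developers who need a reproducible accuracy/performance testbed. External
Bayesian inference is an interface (NEXUS tree logs, tab-separated traces),
never a dependency: a surrogate pseudo-posterior estimator makes the whole
evaluation loop runnable without any MCMC.

## The quantities at the core

**Rooted branch score (RBS).** For rooted trees T1, T2 with clade sets C1,
C2 and b(c) the length of the branch rootward of clade c (0 if c is absent):

    RBS(T1, T2) = sum over c in C1 U C2 of | b1(c) - b2(c) |

**Relative species tree error** for a posterior sample of k trees:

    eT = (1/k) * sum_i RBS(T_true, T_i) / L_true

with L_true the total branch length of the true tree. The **error ratio**
eTa/eTb compares two methods; values below 1 favour method a.

**Power-law scaling.** Performance responses Y (ESS per hour, ESS per
million states, relative error) follow

    log(Y) = beta1 log(nl) + beta2 n + beta3 ni + alpha

in natural logs, where nl is the number of loci, n the number of species and
ni the individuals sampled per species. `fit_loglog()` estimates the
coefficients; `powerlaw_predict()`, `powerlaw_extrapolate()`, `workload()`
and `error_reduction()` turn fitted or reported coefficients into study-design
predictions.

**Coalescent branch lengths.** For a Yule tree with expected root height R
and n species, the expected mean branch length in coalescent units of
tau/(2 Ne) is

    b = (1/4) * R / (H_n - 1) * (1/Ne)

(`expected_mean_branch_length()`), which locates a study system relative to
the coalescent/concatenation crossover zone.

## Worked example

```r
library(mscbench)

# an 8-species shallow radiation: roughly where does it sit relative to the
# coalescent/concatenation crossover?
expected_mean_branch_length(R = 0.01315, n = 8, Ne = 1 / 302.05)
#> [1] 0.5780396
```

A mean branch length of about 0.58 coalescent units is short: incomplete
lineage sorting is severe and a full MSC method is expected to beat
concatenation for such a system.

```r
# predicted relative species tree error at 256 loci (5 species, 2
# individuals) from a fitted natural-log power law, and its extrapolation
err256 <- powerlaw_predict(power_law(-0.435, -0.889), 256)
err256
#> [1] 0.0368407
powerlaw_extrapolate(err256, 256, 1024, -0.435)
#> [1] 0.02015727
error_reduction(16, -0.433)
#> [1] 69.89657
```

Quadrupling 256 loci to 1024 roughly halves the remaining error, and a
16-fold locus increase cuts error by about 70% — but the MCMC chain length
needed grows by a factor of 16^1.87, about 180.

```r
# end to end at desk scale: simulate, estimate with the surrogate, score
cfg <- experiment_config("exp1", n = 5, ni = 2, nl = 16, replicates = 1,
                         seed = 7)
b <- generate(cfg)[[1]]
set.seed(1)
post <- surrogate_estimate(b, noise = 0.5, k = 100)
relative_error(b$species_tree, post)
#> [1] 0.167446
```

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study's structure at desk
scale and write tables under `results/`:

1. `01_simulate.R` — birth-death/MSC/HKY replicate bundles and per-replicate
   tree/alignment statistics;
2. `02_scaling.R` — surrogate posteriors across locus counts, ESS-based
   replicate filtering, per-condition error summaries and the log-log error
   fit;
3. `03_worked_predictions.R` — the downstream arithmetic on reported scaling
   coefficients (predictions, workloads, error reductions);
4. `04_crossover.R` — the coalescent-vs-concatenation error-ratio crossover
   in coalescent units;
5. `05_posthoc.R` — Spearman correlations of residual error with the
   replicate statistics (Benjamini-Hochberg at the 48-test family size).

Run them in order with `Rscript analysis/01_simulate.R` etc. after
installing the package.

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package, the worked
closed-form quantities: the expected coalescent mean branch length for the
shallow 8-species system and the two power-law point predictions at 256
loci (relative species tree error; ESS per million states). Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/mscbench-methods.Rmd` documents the models, their assumptions,
the tunable parameters and defaults, what the synthetic-data generators do
and do not emulate, and the numerical conventions.
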