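# Orchestration of the three simulation experiments at desk scale: replicate
# bundle generation with hierarchical seed substreams, ESS-based replicate
# filtering, a surrogate (pseudo-posterior) estimator so the evaluation loop
# runs without any external Bayesian inference, and per-condition
# aggregation.
#
# External inference is an interface, not a dependency: bundles are exported
# as Newick/FASTA and posteriors imported as NEXUS tree logs plus TSV traces;
# no inference tool is ever invoked.

#' Experiment configuration
#'
#' Defaults encode the three simulation designs: `exp1` - rapidly speciating
#' birth-death trees (lambda = 1, mu = 0.2), HKY kappa = 4 with equal base
#' frequencies, strict clock at 0.01 substitutions/site/My, 200-site loci;
#' `exp2` - Yule trees calibrated to an expected root height R with constant
#' population size, JC, 1000-site loci, log-uniform between-locus rate
#' variation with spread factor F = 3 around mu0 = 0.01; `exp3-shallow` /
#' `exp3-deep` - Yule trees with empirically derived birth rates, gamma
#' (shape 2) per-branch population sizes, GTR+Gamma sequences and gamma
#' per-locus clock rates (shallow: 64 nt loci; deep: locus lengths drawn
#' uniformly from 110-3511 nt).
#'
#' @param experiment one of "exp1", "exp2", "exp3-shallow", "exp3-deep"
#' @param n number of species
#' @param ni individuals (gene copies) per species
#' @param nl number of loci per replicate bundle
#' @param replicates number of replicates
#' @param seed master seed; all randomness flows from it through
#'   per-replicate and per-locus substreams
#' @param R expected root height (exp2 calibration)
#' @param Ne constant population size (exp2)
#' @param ... overrides for any default field
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(experiment = c("exp1", "exp2", "exp3-shallow",
                                             "exp3-deep"),
                              n = NULL, ni = NULL, nl = NULL,
                              replicates = NULL, seed = 1,
                              R = 1, Ne = 0.5, ...) {
  experiment <- match.arg(experiment)
  cfg <- switch(experiment,
    "exp1" = list(
      n = 5, ni = 2, nl = 256, replicates = 100,
      speciation = list(model = "birth-death", lambda = 1, mu = 0.2),
      population = population_model("constant", value = 0.004),
      substitution = substitution_model("HKY", kappa = 4),
      clock = clock_model("fixed", mu0 = 0.01),
      ns = 200
    ),
    "exp2" = list(
      n = 5, ni = 1, nl = 4, replicates = 100,
      speciation = list(model = "yule", R = R),
      population = population_model("constant", value = Ne),
      substitution = substitution_model("JC"),
      clock = clock_model("log-uniform-locus", mu0 = 0.01, F = 3),
      ns = 1000
    ),
    "exp3-shallow" = list(
      n = 8, ni = 2, nl = 4096, replicates = 100,
      speciation = list(model = "yule", lambda = 125.3),
      population = population_model("gamma", shape = 2, mean = 6.35e-3),
      substitution = substitution_model(
        "GTR", freq = c(0.290, 0.212, 0.204, 0.294),
        rates = c(0.367, 0.940, 0.246, 0.305, 1.000, 0.353),
        gamma_shape = 0.0383),
      clock = clock_model("gamma-locus", shape = 6.22, scale = 0.173),
      ns = 64
    ),
    "exp3-deep" = list(
      n = 12, ni = 2, nl = 512, replicates = 100,
      speciation = list(model = "yule", lambda = 20.7),
      population = population_model("gamma", shape = 2, mean = 1.53e-4),
      substitution = substitution_model(
        "GTR", freq = c(0.266, 0.240, 0.263, 0.231),
        rates = c(0.152, 0.694, 0.100, 0.155, 1.000, 0.127),
        gamma_shape = 0.233),
      clock = clock_model("gamma-locus", shape = 5.15, scale = 0.195),
      ns = c(110, 3511) # per-locus lengths sampled uniformly from this range
    ))
  cfg$experiment <- experiment
  cfg$seed <- seed
  if (!is.null(n)) cfg$n <- n
  if (!is.null(ni)) cfg$ni <- ni
  if (!is.null(nl)) cfg$nl <- nl
  if (!is.null(replicates)) cfg$replicates <- replicates
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  stopifnot(cfg$replicates >= 1, all(cfg$nl >= 1), cfg$n >= 2, cfg$ni >= 1)
  structure(cfg, class = "experiment_config")
}

# substream key for the species tree of replicate r: never depends on nl, so
# the experiment-2 reuse rule (one set of species trees regardless of nl)
# holds automatically
.species_seed <- function(cfg, r) substream_seed(cfg$seed, r, 0L)

# substream key for locus j of replicate r: exp2 regenerates gene trees and
# sequences for each value of nl; the other designs share a fixed locus pool
# so larger-nl bundles are supersets of smaller ones
.locus_seed <- function(cfg, r, j) {
  if (cfg$experiment == "exp2") {
    substream_seed(cfg$seed, r, 1L, cfg$nl, j)
  } else {
    substream_seed(cfg$seed, r, 1L, j)
  }
}

#' Generate replicate bundles for an experiment
#'
#' Fully deterministic given the configuration seed. Each bundle holds the
#' true species tree (with per-branch Ne), the per-locus gene trees and,
#' unless `sim_alignments = FALSE`, the per-locus alignments with their clock
#' rates.
#'
#' @param config an [experiment_config()]
#' @param sim_alignments simulate sequences (set FALSE for tree-only studies)
#' @return list of `replicate_bundle` objects of length `config$replicates`
#' @export
generate <- function(config, sim_alignments = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  lapply(seq_len(config$replicates), function(r) {
    sp <- with_substream(.species_seed(config, r), {
      tr <- if (config$speciation$model == "birth-death") {
        simulate_birth_death(config$n, config$speciation$lambda,
                             config$speciation$mu)
      } else {
        lam <- if (!is.null(config$speciation$lambda)) {
          config$speciation$lambda
        } else {
          calibrated_birth_rate(config$n, config$speciation$R)
        }
        simulate_yule(config$n, lam)
      }
      assign_population_sizes(tr, config$population)
    })
    loci <- lapply(seq_len(config$nl), function(j) {
      with_substream(.locus_seed(config, r, j), {
        gt <- simulate_gene_tree(sp, config$ni)
        al <- NULL
        if (sim_alignments) {
          rate <- .locus_rate(config, j)
          ns_j <- if (length(config$ns) == 2 &&
                      config$experiment == "exp3-deep") {
            sample(seq(config$ns[1], config$ns[2]), 1)
          } else {
            config$ns
          }
          al <- simulate_alignment(gt, config$substitution, rate, ns_j)
        }
        list(gene_tree = gt, alignment = al)
      })
    })
    gene_trees <- lapply(loci, `[[`, "gene_tree")
    alignments <- if (sim_alignments) {
      lapply(loci, `[[`, "alignment")
    } else {
      NULL
    }
    structure(list(species_tree = sp, gene_trees = gene_trees,
                   alignments = alignments, replicate = r,
                   config = config,
                   seed_path = c(config$seed, r)),
              class = "replicate_bundle")
  })
}

# per-locus clock rate drawn inside the locus substream; the first locus of
# the log-uniform design is fixed at mu0
.locus_rate <- function(config, j) {
  clock <- config$clock
  switch(clock$kind,
    "fixed" = clock$mu0,
    "log-uniform-locus" = {
      if (j == 1 || clock$F == 1) {
        clock$mu0
      } else {
        exp(stats::runif(1, log(clock$mu0 / clock$F),
                         log(clock$mu0 * clock$F)))
      }
    },
    "gamma-locus" = stats::rgamma(1, shape = clock$shape, scale = clock$scale)
  )
}

#' @export
print.replicate_bundle <- function(x, ...) {
  cat("replicate_bundle:", x$config$experiment, "replicate", x$replicate,
      "-", ape::Ntip(x$species_tree), "species,",
      length(x$gene_trees), "loci\n")
  invisible(x)
}

#' Filter replicates by ESS threshold
#'
#' A replicate is kept if and only if the ESS of both the log posterior and
#' the species tree age is at least the threshold. Discarded replicates are
#' returned with reasons. (ESS-rate summaries use all replicates; error
#' summaries use only the kept ones.)
#'
#' @param posteriors list of [posterior_sample()] objects whose traces contain
#'   columns `posterior` and `species_tree_height`
#' @param threshold minimum ESS (200 in the reference protocol)
#' @param burnin_frac fraction of each trace discarded as burn-in before ESS
#'   estimation
#' @return list with `kept` (indices) and `discarded` (data frame of index,
#'   reason)
#' @export
filter_replicates <- function(posteriors, threshold = 200,
                              burnin_frac = 0.1) {
  needed <- c("posterior", "species_tree_height")
  kept <- integer(0)
  disc_idx <- integer(0)
  disc_reason <- character(0)
  for (i in seq_along(posteriors)) {
    trace <- posteriors[[i]]$trace
    if (is.null(trace) || !all(needed %in% names(trace))) {
      stop("trace of posterior ", i, " lacks required columns: ",
           paste(setdiff(needed, names(trace)), collapse = ", "))
    }
    drop_n <- floor(nrow(trace) * burnin_frac)
    if (drop_n > 0) trace <- trace[-seq_len(drop_n), , drop = FALSE]
    e <- vapply(needed, function(cn) ess(trace[[cn]]), 0)
    if (all(e >= threshold)) {
      kept <- c(kept, i)
    } else {
      low <- needed[e < threshold]
      disc_idx <- c(disc_idx, i)
      disc_reason <- c(disc_reason,
                       paste0("ESS(", low, ")=", round(e[e < threshold], 1),
                              collapse = "; "))
    }
  }
  list(kept = kept,
       discarded = data.frame(index = disc_idx, reason = disc_reason))
}

#' Surrogate pseudo-posterior estimator
#'
#' Stands in for external Bayesian inference so the evaluation loop is
#' testable end to end. Each sample perturbs the true species tree: internal
#' node heights are jittered multiplicatively (lognormal with
#' sigma = noise / sqrt(nl)) and the topology is rearranged by a
#' nearest-neighbor interchange with probability min(1, noise / sqrt(nl)),
#' both shrinking as loci accumulate, so by construction the relative species
#' tree error decreases in nl. Trace columns (`posterior`, white noise, and
#' `species_tree_height`, the sampled root heights) are fabricated so the ESS
#' filter can be exercised.
#'
#' @param bundle a `replicate_bundle`
#' @param noise perturbation scale (0 gives exact copies of the truth)
#' @param k number of pseudo-posterior samples
#' @return a [posterior_sample()]
#' @export
surrogate_estimate <- function(bundle, noise = 0.3, k = 100) {
  stopifnot(inherits(bundle, "replicate_bundle"), k >= 1, noise >= 0)
  truth <- bundle$species_tree
  nl <- length(bundle$gene_trees)
  sigma <- noise / sqrt(nl)
  p_nni <- min(1, noise / sqrt(nl))
  trees <- lapply(seq_len(k), function(i) {
    perturb_tree(truth, sigma, p_nni)
  })
  trace <- data.frame(
    state = seq_len(k),
    posterior = stats::rnorm(k),
    species_tree_height = vapply(trees, tree_height, 0) *
      exp(stats::rnorm(k, 0, 1e-6))
  )
  posterior_sample(trees, trace)
}

#' Perturb an ultrametric tree (heights and topology)
#'
#' Multiplicative lognormal jitter of internal node heights with a repair
#' pass keeping every parent above its children, plus an optional random
#' nearest-neighbor interchange.
#'
#' @param tree an ultrametric `phylo`
#' @param sigma lognormal sigma for height jitter
#' @param p_nni probability of one NNI rearrangement
#' @return a perturbed ultrametric `phylo`
#' @export
perturb_tree <- function(tree, sigma = 0.1, p_nni = 0) {
  ntip <- ape::Ntip(tree)
  out <- tree
  out$Ne <- NULL
  if (p_nni > 0 && ntip >= 3 && stats::runif(1) < p_nni) {
    out <- .random_nni(out)
  }
  h <- node_heights(out)
  internal <- seq.int(ntip + 1L, ntip + out$Nnode)
  if (sigma > 0) {
    h[internal] <- h[internal] * exp(stats::rnorm(length(internal), 0, sigma))
  }
  # repair: parents stay strictly above children (postorder sweep)
  po <- ape::reorder.phylo(out, "postorder")
  for (kk in seq_len(nrow(po$edge))) {
    p <- po$edge[kk, 1]; ch <- po$edge[kk, 2]
    if (h[p] <= h[ch]) h[p] <- h[ch] * (1 + 1e-9) + 1e-12
  }
  set_node_heights(out, h)
}

# swap a random internal (non-root) node's child with its sibling
.random_nni <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  if (!length(internal)) return(tree)
  v <- internal[sample.int(length(internal), 1)]
  parent <- tree$edge[match(v, tree$edge[, 2]), 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  c_node <- sibs[sibs != v][1]
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  b_node <- kids[sample.int(length(kids), 1)]
  # swap parents of b (child of v) and c (sibling of v)
  tree$edge[tree$edge[, 2] == b_node, 1] <- parent
  tree$edge[tree$edge[, 2] == c_node, 1] <- v
  ape::reorder.phylo(tree, "cladewise")
}

#' Aggregate per-replicate metrics by condition
#'
#' Medians, trimmed means and bootstrap confidence intervals per
#' (n, ni, nl) condition, with the number of contributing replicates
#' reported per condition. Empty conditions (all replicates filtered out)
#' yield a flagged row rather than a silent drop.
#'
#' @param metrics data frame with columns `n`, `ni`, `nl`, a value column,
#'   and optionally a logical `kept` column (filtered replicates are excluded
#'   from the summaries but still counted)
#' @param value name of the value column to summarize
#' @param trim trim fraction for the trimmed mean
#' @param boot_reps bootstrap resamples for the confidence interval
#' @return data frame, one row per condition
#' @export
aggregate_conditions <- function(metrics, value = "eT", trim = 0.25,
                                 boot_reps = 1000) {
  stopifnot(all(c("n", "ni", "nl", value) %in% names(metrics)))
  keys <- interaction(metrics$n, metrics$ni, metrics$nl, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(metrics)), keys), function(idx) {
    sub <- metrics[idx, , drop = FALSE]
    use <- if ("kept" %in% names(sub)) sub[[value]][sub$kept] else sub[[value]]
    base <- data.frame(n = sub$n[1], ni = sub$ni[1], nl = sub$nl[1],
                       n_total = nrow(sub), n_used = length(use))
    if (!length(use)) {
      cbind(base, median = NA_real_, trimmed_mean = NA_real_,
            ci_lower = NA_real_, ci_upper = NA_real_, flagged = TRUE)
    } else {
      s <- summarize_errors(use, trim = trim, boot_reps = boot_reps)
      cbind(base, median = stats::median(use), trimmed_mean = s$point,
            ci_lower = s$lower, ci_upper = s$upper, flagged = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$n, out$ni, out$nl), ]
}
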