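# Species-tree accuracy metrics: rooted branch score (RBS), relative species
# tree error, error ratio, rooted Robinson-Foulds distance, pendant-edge
# bias, and trimmed-mean/bootstrap aggregation.

.check_same_leaves <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) {
    stop("trees must share an identical leaf-label set")
  }
}

#' Rooted branch score between two trees
#'
#' The sum, over the union of monophyletic clades present in either tree, of
#' absolute differences in the length of the branch extending rootward from
#' each clade's MRCA. A clade missing from one tree contributes that branch
#' length with zero on the other side, so topological error is weighted by
#' the true or estimated branch length. Tip (singleton) clades are included;
#' the root clade has no rootward branch and is excluded.
#'
#' @param t1,t2 rooted `phylo` trees over the same leaf set
#' @return nonnegative distance in branch-length units
#' @export
rbs <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  b1 <- clade_lengths(t1)
  b2 <- clade_lengths(t2)
  keys <- union(names(b1), names(b2))
  v1 <- ifelse(keys %in% names(b1), b1[keys], 0)
  v2 <- ifelse(keys %in% names(b2), b2[keys], 0)
  sum(abs(v1 - v2))
}

#' Relative species tree error
#'
#' The mean RBS between the true tree and each of the k posterior samples,
#' normalized by the total branch length of the true tree. Duplicate
#' topologies in the posterior are averaged as drawn, not collapsed.
#'
#' @param true_tree the true `phylo` species tree
#' @param posterior a [posterior_sample()] or list of `phylo` trees
#' @return nonnegative dimensionless error
#' @export
relative_error <- function(true_tree, posterior) {
  trees <- if (inherits(posterior, "posterior_sample")) {
    posterior$trees
  } else {
    posterior
  }
  stopifnot(length(trees) >= 1)
  l_true <- sum(true_tree$edge.length)
  if (l_true <= 0) stop("true tree has zero total branch length")
  mean(vapply(trees, function(tr) rbs(true_tree, tr), 0)) / l_true
}

#' Species tree error ratio
#'
#' Ratio of relative species tree errors of two methods on the same true
#' tree; the normalizations by true tree length cancel. Values below 1 mean
#' lower error for method a.
#'
#' @param eA relative error of method a
#' @param eB relative error of method b (> 0)
#' @return eA / eB
#' @export
error_ratio <- function(eA, eB) {
  if (eB == 0) stop("undefined error ratio: denominator error is zero")
  eA / eB
}

#' Rooted Robinson-Foulds distance
#'
#' Size of the symmetric difference of the clade sets of the two trees.
#' Singleton clades are present in both trees and cancel, so this equals the
#' count over internal (non-root) clades.
#'
#' @param t1,t2 rooted `phylo` trees over the same leaf set
#' @return nonnegative integer; at most 2 (n - 2) for binary rooted trees
#' @export
rooted_rf <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  k1 <- vapply(clades(t1), paste, "", collapse = "|")
  k2 <- vapply(clades(t2), paste, "", collapse = "|")
  k1 <- unique(k1)
  k2 <- unique(k2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Pendant-edge length bias
#'
#' Mean over tips of (estimated pendant length / true pendant length - 1),
#' expressed in percent. Estimated pendant edges that are on average 4.5x the
#' true length give a bias of 350%.
#'
#' @param estimated,truth rooted `phylo` trees over the same leaf set
#' @return bias in percent
#' @export
pendant_edge_bias <- function(estimated, truth) {
  .check_same_leaves(estimated, truth)
  pend <- function(tree) {
    idx <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
    stats::setNames(tree$edge.length[idx], tree$tip.label)
  }
  p_true <- pend(truth)
  if (any(p_true <= 0)) stop("true pendant lengths must all be positive")
  p_est <- pend(estimated)[names(p_true)]
  100 * mean(p_est / p_true - 1)
}

#' Trimmed-mean (or median) summary with a bootstrap confidence interval
#'
#' Symmetric trimmed mean dropping `floor(n * trim)` values from each tail
#' (trim 0 is the ordinary mean), with a percentile bootstrap 95% confidence
#' interval of the same statistic.
#'
#' @param values numeric vector
#' @param trim trim fraction in [0, 0.5)
#' @param boot_reps number of bootstrap resamples
#' @param conf confidence level
#' @param statistic "trimmed_mean" or "median"
#' @return list with `point`, `lower`, `upper`, `trim`, `n`
#' @export
summarize_errors <- function(values, trim = 0.25, boot_reps = 1000,
                             conf = 0.95, statistic = c("trimmed_mean",
                                                        "median")) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) >= 1, trim >= 0, trim < 0.5)
  n <- length(values)
  if (statistic == "trimmed_mean" && n - 2 * floor(n * trim) < 1) {
    stop("too few values remain after trimming")
  }
  stat <- if (statistic == "median") {
    function(x) stats::median(x)
  } else {
    function(x) mean(x, trim = trim)
  }
  point <- stat(values)
  boots <- vapply(seq_len(boot_reps), function(i) {
    stat(values[sample.int(n, n, replace = TRUE)])
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(point = point, lower = ci[1], upper = ci[2], trim = trim, n = n)
}
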