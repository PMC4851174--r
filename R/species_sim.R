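# Species tree simulation: Yule and birth-death models conditioned on tip
# count, per-branch effective population sizes, and expected branch lengths in
# coalescent units.

#' Yule birth rate calibrated to an expected root height
#'
#' Under the pure-birth Yule model the expected root height of an n-tip tree
#' is (H_n - 1) / lambda, where H_n is the n-th harmonic number. The birth
#' rate that yields expected root height R is therefore
#' lambda = (1/R) * sum_{k=2}^{n} 1/k.
#'
#' @param n number of extant species (>= 2)
#' @param R expected root height (time units)
#' @return birth rate lambda
#' @export
calibrated_birth_rate <- function(n, R) {
  if (n < 2) stop("n must be at least 2")
  stopifnot(R > 0)
  sum(1 / seq(2, n)) / R
}

#' Simulate a Yule species tree conditioned on tip count
#'
#' Backward construction: while j lineages exist the inter-speciation waiting
#' time is Exponential(j * lambda) and the joined pair is chosen uniformly.
#' The expected root height is (H_n - 1) / lambda and the expected mean branch
#' length is 1 / (2 lambda).
#'
#' @param n number of extant species (>= 2)
#' @param lambda birth rate (> 0)
#' @param labels optional tip labels; default `sp1..spn`
#' @return an ultrametric `phylo` tree with n tips
#' @export
simulate_yule <- function(n, lambda, labels = paste0("sp", seq_len(n))) {
  stopifnot(n >= 2, lambda > 0)
  b <- new_lineage_builder(labels)
  active <- seq_len(n)
  h <- 0
  for (j in seq(n, 2)) {
    h <- h + stats::rexp(1, rate = j * lambda)
    pair <- sample(length(active), 2)
    id <- merge_lineages(b, active[pair[1]], active[pair[2]], h)
    active <- c(active[-pair], id)
  }
  finalize_lineage_tree(b, active)
}

#' Simulate a birth-death species tree conditioned on tip count
#'
#' Forward simulation from a single origin lineage with per-lineage speciation
#' rate lambda and extinction rate mu, rejected until exactly n lineages
#' survive at the stopping condition (the first time the extant count reaches
#' n, extended by the exponential waiting time to the next event). Extinct
#' lineages are pruned, returning the reconstructed tree of the n extant
#' species. With mu = 0 the distribution reduces exactly to the Yule model
#' conditioned on n.
#'
#' @param n number of extant species (>= 2)
#' @param lambda speciation rate (> 0)
#' @param mu extinction rate (0 <= mu < lambda)
#' @param max_attempts rejection budget before a simulation error
#' @return an ultrametric `phylo` tree with n tips labelled `sp1..spn`
#' @export
simulate_birth_death <- function(n, lambda, mu = 0, max_attempts = 1e6) {
  stopifnot(n >= 2, lambda > 0, mu >= 0, mu < lambda)
  for (attempt in seq_len(max_attempts)) {
    tree <- .bd_forward_once(n, lambda, mu)
    if (!is.null(tree)) return(tree)
  }
  stop("birth-death simulation failed after ", max_attempts, " attempts")
}

# One forward pass; NULL when the process dies out before reaching n extant.
.bd_forward_once <- function(n, lambda, mu) {
  btime <- 0 # birth time per lineage
  dtime <- NA_real_ # death time (NA while alive)
  events <- list(integer(0)) # per lineage: indices of (time, child) pairs
  ev_time <- numeric(0)
  ev_child <- integer(0)
  alive <- 1L
  t <- 0
  total_rate <- lambda + mu
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    dt <- stats::rexp(1, rate = k * total_rate)
    t <- t + dt
    if (k == n) break # stop just before the next event
    who <- alive[sample.int(k, 1)]
    if (stats::runif(1) < lambda / total_rate) {
      new_id <- length(btime) + 1L
      btime[new_id] <- t
      dtime[new_id] <- NA_real_
      events[[new_id]] <- integer(0)
      ev_time <- c(ev_time, t)
      ev_child <- c(ev_child, new_id)
      events[[who]] <- c(events[[who]], length(ev_time))
      alive <- c(alive, new_id)
    } else {
      dtime[who] <- t
      alive <- alive[alive != who]
    }
  }
  stop_time <- t
  end_time <- ifelse(is.na(dtime), stop_time, dtime)
  build <- function(i, from) {
    idx <- events[[i]]
    idx <- idx[ev_time[idx] > from]
    if (length(idx) == 0) {
      label <- if (is.na(dtime[i])) paste0("t", i) else paste0("x", i)
      return(paste0(label, ":", format(end_time[i] - from, digits = 15)))
    }
    s <- ev_time[idx[1]]
    paste0("(", build(i, s), ",", build(ev_child[idx[1]], s), "):",
           format(s - from, digits = 15))
  }
  txt <- paste0(build(1L, 0), ";")
  full <- ape::read.tree(text = txt)
  extinct <- full$tip.label[startsWith(full$tip.label, "x")]
  if (length(extinct)) full <- ape::drop.tip(full, extinct)
  if (is.null(full) || ape::Ntip(full) != n) return(NULL)
  full$root.edge <- NULL
  full$tip.label <- paste0("sp", rank(as.integer(sub("^t", "", full$tip.label))))
  full
}

#' Population size model
#'
#' Constant per-branch effective population size, or i.i.d. per-branch draws
#' from a gamma distribution given its shape and mean.
#'
#' @param kind "constant" or "gamma"
#' @param value constant Ne (individuals), for `kind = "constant"`
#' @param shape gamma shape, for `kind = "gamma"`
#' @param mean gamma mean, for `kind = "gamma"`
#' @return an object of class `population_model`
#' @export
population_model <- function(kind = c("constant", "gamma"), value = NULL,
                             shape = NULL, mean = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    stopifnot(is.numeric(value), value > 0)
  } else {
    stopifnot(is.numeric(shape), shape > 0, is.numeric(mean), mean > 0)
  }
  structure(list(kind = kind, value = value, shape = shape, mean = mean),
            class = "population_model")
}

#' Assign per-branch effective population sizes
#'
#' Every branch carries an Ne, including the root (origin) branch: the result
#' stores a vector `tree$Ne` indexed by node number, holding the Ne of the
#' branch extending rootward from that node.
#'
#' @param tree a `phylo` species tree
#' @param model a [population_model()]
#' @return the tree with an `Ne` field
#' @export
assign_population_sizes <- function(tree, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "population_model"))
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  tree$Ne <- if (model$kind == "constant") {
    rep(model$value, n_nodes)
  } else {
    stats::rgamma(n_nodes, shape = model$shape,
                  rate = model$shape / model$mean)
  }
  tree
}

#' Expected mean branch length in coalescent units
#'
#' For a Yule tree with expected root height R and n species, the expected
#' mean branch length is R / (2 (H_n - 1)) in time units; dividing by 2 Ne
#' gives the closed form (1/4) * R / (H_n - 1) * (1 / Ne) in coalescent units
#' of tau (2 Ne)^-1.
#'
#' @param R expected root height (time units)
#' @param n number of species (>= 2)
#' @param Ne effective population size (individuals)
#' @return expected mean branch length in coalescent units
#' @export
expected_mean_branch_length <- function(R, n, Ne) {
  if (n < 2) stop("n must be at least 2")
  stopifnot(R > 0, Ne > 0)
  0.25 * R / (harmonic_number(n) - 1) / Ne
}

#' Mean branch length of a species tree in coalescent units
#'
#' Mean over branches of tau_b / (2 Ne_b). The root (origin) branch carries an
#' Ne but has no defined length and is excluded.
#'
#' @param tree a `phylo` species tree with an `Ne` field
#' @return mean branch length in coalescent units
#' @export
mean_branch_length_coalescent <- function(tree) {
  if (is.null(tree$Ne)) stop("tree has no per-branch Ne; see assign_population_sizes()")
  child <- tree$edge[, 2]
  mean(tree$edge.length / (2 * tree$Ne[child]))
}
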