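# Nucleotide sequence simulation along gene trees: JC, HKY and GTR+Gamma
# models with strict clocks and between-locus rate variation. The rate matrix
# Q is normalized to unit expected rate at stationarity, so branch length
# times the clock rate is in expected substitutions per site.

NUC <- c("A", "C", "G", "T")

#' Nucleotide substitution model
#'
#' JC (equal rates, equal frequencies), HKY (transition/transversion ratio
#' kappa), or GTR (six exchangeabilities, C<->T conventionally normalized to
#' 1). Between-site rate variation uses a discrete gamma with `gamma_ncat`
#' categories (mean-of-quantile-bin discretization); `gamma_shape = 0` turns
#' rate variation off.
#'
#' @param kind "JC", "HKY" or "GTR"
#' @param freq base frequencies (A, C, G, T), summing to 1
#' @param kappa transition/transversion ratio (HKY)
#' @param rates six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT
#' @param gamma_shape shape of the gamma rate-variation distribution (0 = none)
#' @param gamma_ncat number of discrete gamma categories
#' @return an object of class `substitution_model`
#' @export
substitution_model <- function(kind = c("JC", "HKY", "GTR"),
                               freq = rep(0.25, 4), kappa = NULL,
                               rates = NULL, gamma_shape = 0,
                               gamma_ncat = 4) {
  kind <- match.arg(kind)
  stopifnot(length(freq) == 4, all(freq > 0),
            abs(sum(freq) - 1) < 1e-8, gamma_shape >= 0, gamma_ncat >= 1)
  if (kind == "JC" && max(abs(freq - 0.25)) > 1e-8) {
    stop("JC implies equal base frequencies")
  }
  ex <- switch(kind,
    JC = rep(1, 6),
    HKY = {
      stopifnot(is.numeric(kappa), kappa > 0)
      # transitions: A<->G and C<->T
      c(1, kappa, 1, 1, kappa, 1)
    },
    GTR = {
      stopifnot(length(rates) == 6, all(rates > 0))
      rates
    })
  q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  q["A", "C"] <- ex[1]; q["A", "G"] <- ex[2]; q["A", "T"] <- ex[3]
  q["C", "G"] <- ex[4]; q["C", "T"] <- ex[5]; q["G", "T"] <- ex[6]
  q <- q + t(q)
  q <- q * rep(freq, each = 4) # q_ij = r_ij * pi_j
  diag(q) <- -rowSums(q)
  scale <- -sum(freq * diag(q)) # expected rate at stationarity
  q <- q / scale
  # eigendecomposition of the symmetrized matrix for fast exp(Qt)
  sq <- sqrt(freq)
  sym <- diag(sq) %*% q %*% diag(1 / sq)
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  structure(list(kind = kind, freq = freq, kappa = kappa, rates = ex,
                 Q = q, eig_values = eig$values,
                 left = diag(1 / sq) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(sq),
                 gamma_shape = gamma_shape, gamma_ncat = gamma_ncat),
            class = "substitution_model")
}

#' Transition probability matrix exp(Q t)
#'
#' @param model a [substitution_model()]
#' @param t branch length in expected substitutions per site
#' @return 4x4 stochastic matrix with rows summing to 1
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), t >= 0)
  p <- model$left %*% (exp(model$eig_values * t) * model$right)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(NUC, NUC)
  p
}

#' Discrete gamma rate categories (mean of each quantile bin)
#'
#' Yang-style discretization: the gamma(shape, rate = shape) distribution
#' (mean 1) is cut into `ncat` equal-probability bins and each category rate
#' is the mean of its bin, so the category rates average exactly 1.
#'
#' @param shape gamma shape parameter (> 0)
#' @param ncat number of categories
#' @return numeric vector of `ncat` relative rates with mean 1
#' @export
discrete_gamma_rates <- function(shape, ncat = 4) {
  stopifnot(shape > 0, ncat >= 1)
  if (ncat == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = shape,
                     rate = shape)
  # E[X | a < X < b] for gamma(shape, rate=shape) via the shape+1 identity
  upper <- stats::pgamma(q[-1], shape = shape + 1, rate = shape)
  lower <- stats::pgamma(q[-length(q)], shape = shape + 1, rate = shape)
  ncat * (upper - lower)
}

#' Clock model for between-locus rate variation
#'
#' `fixed`: every locus at the base rate mu0. `log-uniform-locus`: the first
#' locus fixed at mu0 and the rest drawn log-uniformly on (mu0/F, mu0*F), so
#' slower and faster rates are equally dense around mu0 and the fastest /
#' slowest possible ratio is F^2. `gamma-locus`: i.i.d. gamma(shape, scale)
#' rates for all loci.
#'
#' @param kind "fixed", "log-uniform-locus" or "gamma-locus"
#' @param mu0 base rate (substitutions/site/time)
#' @param F spread factor (>= 1), log-uniform mode
#' @param shape,scale gamma parameters, gamma mode
#' @return an object of class `clock_model`
#' @export
clock_model <- function(kind = c("fixed", "log-uniform-locus", "gamma-locus"),
                        mu0 = 0.01, F = 1, shape = NULL, scale = NULL) {
  kind <- match.arg(kind)
  stopifnot(mu0 > 0, F >= 1)
  if (kind == "gamma-locus") stopifnot(shape > 0, scale > 0)
  structure(list(kind = kind, mu0 = mu0, F = F, shape = shape, scale = scale),
            class = "clock_model")
}

#' Draw per-locus clock rates
#'
#' @param nl number of loci
#' @param clock a [clock_model()]
#' @return numeric vector of `nl` rates
#' @export
draw_locus_rates <- function(nl, clock) {
  stopifnot(inherits(clock, "clock_model"), nl >= 1)
  switch(clock$kind,
    "fixed" = rep(clock$mu0, nl),
    "log-uniform-locus" = {
      if (clock$F == 1) return(rep(clock$mu0, nl))
      rest <- exp(stats::runif(nl - 1, log(clock$mu0 / clock$F),
                               log(clock$mu0 * clock$F)))
      c(clock$mu0, rest)
    },
    "gamma-locus" = stats::rgamma(nl, shape = clock$shape, scale = clock$scale)
  )
}

#' Simulate a nucleotide alignment along a gene tree
#'
#' The root sequence is drawn from the stationary frequencies; each branch
#' evolves sites independently through exp(Q * rate * tau * r_site), with
#' r_site from the discrete-gamma categories of the model.
#'
#' @param gene_tree a `phylo` gene tree with branch lengths in time units
#' @param model a [substitution_model()]
#' @param rate strict clock rate (substitutions/site/time)
#' @param ns number of sites
#' @return an object of class `msc_alignment`: list with `sequences` (a
#'   character matrix, taxa x sites) and `clock_rate`
#' @export
simulate_alignment <- function(gene_tree, model, rate, ns) {
  stopifnot(inherits(gene_tree, "phylo"), ns >= 1, rate >= 0)
  ntip <- ape::Ntip(gene_tree)
  n_nodes <- ntip + gene_tree$Nnode
  root <- ntip + 1L
  cat_rates <- if (model$gamma_shape > 0) {
    discrete_gamma_rates(model$gamma_shape, model$gamma_ncat)
  } else {
    1
  }
  site_cat <- sample.int(length(cat_rates), ns, replace = TRUE)
  states <- matrix(0L, n_nodes, ns)
  states[root, ] <- sample.int(4, ns, replace = TRUE, prob = model$freq)
  pre <- ape::reorder.phylo(gene_tree, "cladewise") # parents before children
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    d <- pre$edge.length[k] * rate
    for (ct in seq_along(cat_rates)) {
      sites <- which(site_cat == ct)
      if (!length(sites)) next
      p <- transition_matrix(model, d * cat_rates[ct])
      ps <- states[parent, sites]
      u <- stats::runif(length(sites))
      cum <- t(apply(p, 1, cumsum))
      # invert the per-state CDF: new state = 1 + #{cum < u}
      states[child, sites] <- 1L +
        (u > cum[ps, 1]) + (u > cum[ps, 2]) + (u > cum[ps, 3])
    }
  }
  seqs <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], ntip, ns)
  rownames(seqs) <- gene_tree$tip.label
  structure(list(sequences = seqs, clock_rate = rate),
            class = "msc_alignment")
}

#' Number of variable sites
#'
#' Sites (columns) with more than one extant allele.
#'
#' @param aln an `msc_alignment`
#' @return integer count
#' @export
count_variable_sites <- function(aln) {
  m <- aln$sequences
  stopifnot(is.matrix(m), nrow(m) >= 1)
  if (nrow(m) == 1) return(0L)
  first <- m[1, ]
  sum(colSums(m != matrix(first, nrow(m), ncol(m), byrow = TRUE)) > 0)
}

#' Write an alignment as FASTA
#'
#' @param aln an `msc_alignment`
#' @param path output file path
#' @export
write_fasta <- function(aln, path) {
  m <- aln$sequences
  lines <- character(2 * nrow(m))
  lines[seq(1, by = 2, length.out = nrow(m))] <- paste0(">", rownames(m))
  lines[seq(2, by = 2, length.out = nrow(m))] <-
    apply(m, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA alignment
#'
#' @param path input file path
#' @param clock_rate optional clock rate to attach
#' @return an `msc_alignment`
#' @export
read_fasta <- function(path, clock_rate = NA_real_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no FASTA records in '", path, "'")
  labels <- sub("^>", "", lines[headers])
  bounds <- c(headers, length(lines) + 1L)
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)], collapse = "")
  }, "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("FASTA sequences have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- labels
  structure(list(sequences = m, clock_rate = clock_rate),
            class = "msc_alignment")
}
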