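# Tree and alignment statistics for the post hoc residual-correlation
# analysis: species tree asymmetry, Fitch parsimony mutation counts,
# per-replicate statistic bundles and Spearman correlations with
# Benjamini-Hochberg correction at a fixed family size.

#' Species tree asymmetry
#'
#' The population variance of the number of nodes between each tip and the
#' tree root, counted as edges on the tip-to-root path. Depends only on the
#' topology; a perfectly balanced tree has asymmetry 0.
#'
#' @param tree a rooted `phylo`
#' @return nonnegative variance
#' @export
asymmetry <- function(tree) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2)
  ntip <- ape::Ntip(tree)
  depth <- numeric(ntip + tree$Nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    depth[pre$edge[k, 2]] <- depth[pre$edge[k, 1]] + 1
  }
  d <- depth[seq_len(ntip)]
  mean((d - mean(d))^2)
}

#' Minimum mutation count by Fitch parsimony
#'
#' The parsimonious (minimum) number of mutations required over all sites of
#' an alignment given the true gene tree, by the Fitch small-parsimony pass
#' (intersection/union, generalized to multi-child nodes). Characters outside
#' A/C/G/T are treated as fully ambiguous.
#'
#' @param aln an `msc_alignment` whose labels match the tree leaves
#' @param gene_tree a rooted `phylo`
#' @return total minimum number of mutations across sites
#' @export
fitch_mutations <- function(aln, gene_tree) {
  m <- aln$sequences
  if (!setequal(rownames(m), gene_tree$tip.label)) {
    stop("alignment labels do not match the tree leaves")
  }
  ntip <- ape::Ntip(gene_tree)
  ns <- ncol(m)
  n_nodes <- ntip + gene_tree$Nnode
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  masks <- matrix(15L, n_nodes, ns)
  for (i in seq_len(ntip)) {
    x <- code[m[gene_tree$tip.label[i], ]]
    x[is.na(x)] <- 15L
    masks[i, ] <- x
  }
  po <- ape::reorder.phylo(gene_tree, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])
  # process a node only once all of its children are complete: a parent's
  # last edge in postorder comes after every edge in its subtree
  parents_in_order <- rev(unique(rev(po$edge[, 1])))
  total <- 0L
  for (p in parents_in_order) {
    ch <- children[[as.character(p)]]
    acc_and <- masks[ch[1], ]
    acc_or <- masks[ch[1], ]
    for (c2 in ch[-1]) {
      acc_and <- bitwAnd(acc_and, masks[c2, ])
      acc_or <- bitwOr(acc_or, masks[c2, ])
    }
    empty <- acc_and == 0L
    total <- total + sum(empty)
    masks[p, ] <- ifelse(empty, acc_or, acc_and)
  }
  total
}

#' Per-replicate tree and alignment statistics
#'
#' The eight statistics correlated with residual MCMC performance and error:
#' species tree height, mean population size, species tree asymmetry, mean
#' deep coalescences, mean parsimonious mutations, mean variable site count,
#' mean tree height difference (gene minus species), and mutations per
#' variable site (total mutations / total variable sites; NA when no site is
#' variable).
#'
#' @param species_tree a `phylo` species tree with per-branch `Ne`
#' @param gene_trees list of `phylo` gene trees (one per locus)
#' @param alignments list of `msc_alignment` objects matching the gene trees
#' @return one-row data frame of the eight statistics
#' @export
replicate_stats <- function(species_tree, gene_trees, alignments) {
  stopifnot(length(gene_trees) >= 1,
            length(alignments) == length(gene_trees))
  sp_height <- tree_height(species_tree)
  mean_ne <- if (is.null(species_tree$Ne)) NA_real_ else mean(species_tree$Ne)
  deep <- vapply(gene_trees, count_deep_coalescences, 0L,
                 species_tree = species_tree)
  mut <- mapply(fitch_mutations, alignments, gene_trees)
  varsites <- vapply(alignments, count_variable_sites, 0L)
  hdiff <- vapply(gene_trees, tree_height, 0) - sp_height
  total_var <- sum(varsites)
  data.frame(
    species_tree_height = sp_height,
    mean_population_size = mean_ne,
    species_tree_asymmetry = asymmetry(species_tree),
    mean_deep_coalescences = mean(deep),
    mean_parsimonious_mutations = mean(mut),
    mean_variable_site_count = mean(varsites),
    mean_tree_height_difference = mean(hdiff),
    mutations_per_variable_site = if (total_var > 0) {
      sum(mut) / total_var
    } else {
      NA_real_
    }
  )
}

#' Spearman correlations of residuals with replicate statistics
#'
#' Spearman's rank correlation (average ranks for ties) between a residual
#' series and each column of a replicate-statistics table. P-values use the
#' asymptotic t approximation t = rho * sqrt((m-2)/(1-rho^2)) on m-2 degrees
#' of freedom, then Benjamini-Hochberg correction scaled to the full family
#' size `n_tests` (default 48) even when fewer statistics are computed.
#'
#' @param residuals numeric vector of residuals, one per replicate
#' @param stats_table data frame of statistics, rows aligned with `residuals`
#' @param n_tests family size for the multiple-testing correction
#' @return data frame with columns statistic, rho, p, p_adj
#' @export
residual_correlations <- function(residuals, stats_table, n_tests = 48) {
  stopifnot(is.data.frame(stats_table),
            nrow(stats_table) == length(residuals),
            length(residuals) >= 4)
  m <- length(residuals)
  if (stats::sd(residuals) == 0) {
    stop("undefined correlation: residual series is constant")
  }
  rho <- vapply(stats_table, function(col) {
    if (stats::sd(col) == 0) {
      stop("undefined correlation: a statistic series is constant")
    }
    stats::cor(residuals, col, method = "spearman")
  }, 0)
  tval <- rho * sqrt((m - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = m - 2)
  p_adj <- stats::p.adjust(p, method = "BH", n = max(n_tests, length(p)))
  data.frame(statistic = names(stats_table), rho = unname(rho),
             p = unname(p), p_adj = unname(p_adj), row.names = NULL)
}
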