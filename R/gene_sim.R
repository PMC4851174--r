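# Gene tree simulation under the multispecies coalescent: within each branch
# of the species tree, gene lineages coalesce pairwise at rate 1/(2 Ne);
# lineages not coalesced by the top of a branch are passed rootward, and the
# process continues above the root in the origin branch until one lineage
# remains.

#' Simulate a gene tree within a species tree
#'
#' Coalescent rate per lineage pair is 1/(2 Ne) with Ne and time in the same
#' nominal units, so branch length in coalescent units is tau / (2 Ne).
#' Gene-copy tips are labelled `<species>_<index>`.
#'
#' @param species_tree a `phylo` species tree with per-branch `Ne`
#'   (see [assign_population_sizes()])
#' @param ni number of gene copies sampled per species (uniform)
#' @return a `phylo` gene tree with n * ni tips
#' @export
simulate_gene_tree <- function(species_tree, ni = 1) {
  stopifnot(inherits(species_tree, "phylo"), ni >= 1)
  if (is.null(species_tree$Ne)) {
    stop("species tree has no per-branch Ne; see assign_population_sizes()")
  }
  ntip <- ape::Ntip(species_tree)
  sh <- node_heights(species_tree)
  root <- ntip + 1L
  parent_of <- integer(ntip + species_tree$Nnode)
  parent_of[species_tree$edge[, 2]] <- species_tree$edge[, 1]

  tip_labels <- unlist(lapply(species_tree$tip.label, function(s) {
    paste0(s, "_", seq_len(ni))
  }))
  b <- new_lineage_builder(tip_labels)

  # gene lineages currently waiting at the base of each species-tree branch
  pending <- vector("list", ntip + species_tree$Nnode)
  for (i in seq_len(ntip)) {
    pending[[i]] <- seq.int((i - 1L) * ni + 1L, i * ni)
  }

  order_nodes <- order(sh) # tips (height 0) first, root last
  for (v in order_nodes) {
    lineages <- pending[[v]]
    if (is.null(lineages)) next
    start <- sh[v]
    end <- if (v == root) Inf else sh[parent_of[v]]
    ne <- species_tree$Ne[v]
    t <- start
    while (length(lineages) >= 2) {
      k <- length(lineages)
      rate <- k * (k - 1) / 2 / (2 * ne)
      t_next <- t + stats::rexp(1, rate = rate)
      if (t_next >= end) break
      t <- t_next
      pair <- sample(k, 2)
      id <- merge_lineages(b, lineages[pair[1]], lineages[pair[2]], t)
      lineages <- c(lineages[-pair], id)
    }
    if (v == root) {
      return(finalize_lineage_tree(b, lineages))
    }
    up <- parent_of[v]
    pending[[up]] <- c(pending[[up]], lineages)
  }
  stop("internal error: species tree root never reached")
}

#' Simulate a set of independent loci
#'
#' Loci evolve with free recombination between them: each gene tree is drawn
#' independently. When `seed` is given, per-locus substreams make the first j
#' trees of a large draw identical to a j-locus draw at the same seed.
#'
#' @param species_tree a `phylo` species tree with per-branch `Ne`
#' @param ni gene copies per species
#' @param nl number of loci
#' @param seed optional integer seed for per-locus substreams
#' @return list of `phylo` gene trees of length `nl`
#' @export
simulate_locus_set <- function(species_tree, ni = 1, nl = 1, seed = NULL) {
  stopifnot(nl >= 1)
  lapply(seq_len(nl), function(j) {
    if (is.null(seed)) {
      simulate_gene_tree(species_tree, ni)
    } else {
      with_substream(substream_seed(seed, j),
                     simulate_gene_tree(species_tree, ni))
    }
  })
}

#' Count deep coalescences of a gene tree within a species tree
#'
#' Maddison's deep-coalescence cost: the sum over species-tree branches of the
#' number of gene lineages exiting the branch rootward minus one. A gene tree
#' perfectly congruent with the species tree (one copy per species,
#' coalescences at the divergences) costs zero.
#'
#' @param gene_tree a `phylo` gene tree with `<species>_<index>` tip labels
#' @param species_tree the companion `phylo` species tree
#' @return nonnegative integer count
#' @export
count_deep_coalescences <- function(gene_tree, species_tree) {
  sp <- species_of(gene_tree$tip.label)
  if (!all(sp %in% species_tree$tip.label)) {
    stop("gene-copy species map inconsistent with the species tree")
  }
  ntip_s <- ape::Ntip(species_tree)
  sh <- node_heights(species_tree)
  gh <- node_heights(gene_tree)
  sparent <- integer(ntip_s + species_tree$Nnode)
  sparent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  gparent <- integer(ape::Ntip(gene_tree) + gene_tree$Nnode)
  gparent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]

  # species tip sets below each species-tree node
  species_below <- vector("list", ntip_s + species_tree$Nnode)
  for (i in seq_len(ntip_s)) species_below[[i]] <- species_tree$tip.label[i]
  po <- ape::reorder.phylo(species_tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; cld <- po$edge[k, 2]
    species_below[[p]] <- c(species_below[[p]], species_below[[cld]])
  }

  # gene lineage containing a tip at height h: highest ancestor with height <= h
  lineage_at <- function(tip, h) {
    node <- tip
    repeat {
      p <- gparent[node]
      if (p == 0L || gh[p] > h) return(node)
      node <- p
    }
  }

  root_s <- ntip_s + 1L
  total <- 0L
  for (v in seq_len(ntip_s + species_tree$Nnode)) {
    if (v == root_s) next
    top <- sh[sparent[v]]
    members <- which(sp %in% species_below[[v]])
    exiting <- length(unique(vapply(members, lineage_at, 0L, h = top)))
    total <- total + (exiting - 1L)
  }
  total
}
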