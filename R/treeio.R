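# Core rooted time-tree model: ape "phylo" objects are the container
# throughout. Heights are measured from the leaves (0) upward, so an
# ultrametric tree has all tips at height 0 and the root at the tree height.

#' Node heights of a rooted tree
#'
#' Heights are measured upward from the leaves: the deepest tip sits at height
#' 0 and the root at the tree height. For ultrametric trees every tip is at
#' height 0.
#'
#' @param tree a rooted `phylo` tree with branch lengths
#' @return numeric vector indexed by node number (tips first, as in `phylo`)
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Tree height (root height)
#'
#' @param tree a rooted `phylo`
#' @return height of the root above the deepest leaf
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Rebuild branch lengths from a vector of node heights
#'
#' @param tree a rooted `phylo`
#' @param heights numeric vector indexed by node number
#' @return the tree with `edge.length = heights[parent] - heights[child]`
#' @keywords internal
set_node_heights <- function(tree, heights) {
  tree$edge.length <- heights[tree$edge[, 1]] - heights[tree$edge[, 2]]
  tree
}

#' Check ultrametricity with a height-relative tolerance
#'
#' Serialized trees lose precision, so ultrametricity is judged relative to
#' the tree height (default relative tolerance 1e-6).
#'
#' @param tree a rooted `phylo`
#' @param rel_tol relative tolerance as a fraction of tree height
#' @return logical
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-6) {
  if (ape::Ntip(tree) == 1) return(TRUE)
  h <- node_heights(tree)[seq_len(ape::Ntip(tree))]
  diff(range(h)) <= rel_tol * max(tree_height(tree), .Machine$double.eps)
}

#' Parse a rooted Newick string
#'
#' Wraps `ape::read.tree` with a structural pre-check that reports the
#' position of unbalanced parentheses. Non-ultrametric input is accepted but
#' flagged with a warning; ultrametricity is enforced only by operations that
#' require it.
#'
#' @param text a Newick string with branch lengths
#' @param warn_nonultrametric warn when the parsed tree is not ultrametric
#' @return a `phylo` tree
#' @export
parse_newick <- function(text, warn_nonultrametric = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' by position ",
         length(chars))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("malformed Newick: ape could not parse the string")
  if (is.null(tree$edge.length) && ape::Ntip(tree) > 1) {
    stop("malformed Newick: branch lengths are required")
  }
  if (warn_nonultrametric && ape::Ntip(tree) > 1 &&
      !is_ultrametric_tree(tree)) {
    warning("parsed tree is not ultrametric")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` tree
#' @param digits significant digits for branch lengths
#' @return a Newick string
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Monophyletic clades of a rooted tree
#'
#' One clade (set of leaf labels) per node except the root: singleton tip
#' clades are included, and the root clade (the full leaf set) is excluded
#' because it has no rootward branch.
#'
#' @param tree a rooted `phylo`
#' @return a list of character vectors of leaf labels, sorted within clades
#' @export
clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (ntip == 1) return(list())
  nnode <- tree$Nnode
  root <- ntip + 1L
  tips_below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  # postorder: children are visited before their parent
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    tips_below[[parent]] <- c(tips_below[[parent]], tips_below[[child]])
  }
  out <- lapply(seq_len(ntip + nnode)[-root], function(i) sort(tips_below[[i]]))
  out
}

#' Rootward branch length of every clade
#'
#' Maps each clade (keyed by its sorted leaf labels) to the length of the
#' branch extending rootward from its most recent common ancestor. Clades
#' occurring more than once (possible only with zero-length branches) have
#' their rootward lengths summed.
#'
#' @param tree a rooted `phylo` with branch lengths
#' @return named numeric vector; names are `|`-joined sorted leaf labels
#' @keywords internal
clade_lengths <- function(tree) {
  cl <- clades(tree)
  keys <- vapply(cl, paste, "", collapse = "|")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nodes <- seq_len(ntip + tree$Nnode)[-root]
  lens <- numeric(length(nodes))
  parent_edge <- match(nodes, tree$edge[, 2])
  lens <- tree$edge.length[parent_edge]
  tapply(lens, keys, sum)
}

#' Read a tab-separated MCMC trace log
#'
#' BEAST-style logs: a header row naming the columns, a first column holding
#' the state index, and comment lines beginning with '#'. Ragged rows raise a
#' format error.
#'
#' @param path path to the log file
#' @return data frame of numeric series keyed by header
#' @export
read_trace <- function(path) {
  out <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, fill = FALSE),
    error = function(e) stop("trace format error in '", path, "': ",
                             conditionMessage(e))
  )
  if (ncol(out) < 1) stop("trace format error: no columns in '", path, "'")
  out
}

#' Combine resumed-chain trace logs into a single chain
#'
#' When an MCMC chain is resumed, the first state of the resumed log repeats
#' the final state of the previous one; the duplicate boundary state is
#' dropped.
#'
#' @param traces list of trace data frames (in chain order)
#' @return one combined data frame
#' @export
combine_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  out <- traces[[1]]
  state_col <- 1L
  for (tr in traces[-1]) {
    if (!identical(names(tr), names(out))) {
      stop("trace format error: resumed log columns differ")
    }
    if (nrow(tr) > 0 && nrow(out) > 0 &&
        tr[1, state_col] == out[nrow(out), state_col]) {
      tr <- tr[-1, , drop = FALSE]
    }
    out <- rbind(out, tr)
  }
  rownames(out) <- NULL
  out
}

#' Read a NEXUS tree log
#'
#' Supports translate tables and zero-length branches (the BEAST dialect),
#' via `ape::read.nexus`.
#'
#' @param path path to a NEXUS file with a trees block
#' @param burnin_frac fraction of initial trees to discard
#' @return list of `phylo` trees
#' @export
read_tree_log <- function(path, burnin_frac = 0) {
  trees <- ape::read.nexus(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  if (burnin_frac > 0) {
    drop_n <- floor(length(trees) * burnin_frac)
    if (drop_n > 0) trees <- trees[-seq_len(drop_n)]
  }
  trees
}

#' Construct a posterior sample
#'
#' An ordered set of species-tree samples plus scalar trace columns of equal
#' length (at minimum the log posterior and the species tree age).
#'
#' @param trees list of `phylo` trees sharing one leaf-label set
#' @param trace data frame of scalar series, one row per sample
#' @return an object of class `posterior_sample`
#' @export
posterior_sample <- function(trees, trace = NULL) {
  stopifnot(length(trees) >= 1)
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labels)) {
      stop("all posterior trees must share one leaf-label set")
    }
  }
  if (!is.null(trace)) {
    stopifnot(is.data.frame(trace))
    lens <- vapply(trace, length, 0L)
    if (length(unique(lens)) > 1) stop("trace series must have equal lengths")
  }
  structure(list(trees = trees, trace = trace, k = length(trees)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", x$k, "trees over",
      ape::Ntip(x$trees[[1]]), "taxa")
  if (!is.null(x$trace)) cat(";", ncol(x$trace), "trace columns")
  cat("\n")
  invisible(x)
}

# ---- species / gene label plumbing ------------------------------------------

#' Species of each gene copy
#'
#' Gene-copy labels follow the convention `<species>_<index>`; the map from
#' copy to species is derived by stripping the trailing index.
#'
#' @param labels character vector of gene-copy labels
#' @return character vector of species labels
#' @export
species_of <- function(labels) {
  sub("_[0-9]+$", "", labels)
}

#' Assert the multispecies-coalescent nesting invariant
#'
#' For any two gene copies from different species, their coalescence height in
#' the gene tree must be at least the divergence height of those species in
#' the species tree.
#'
#' @param gene_tree a `phylo` gene tree with `<species>_<index>` tip labels
#' @param species_tree the companion `phylo` species tree
#' @param tol absolute height tolerance
#' @return TRUE invisibly; stops on violation
#' @export
check_msc_nesting <- function(gene_tree, species_tree, tol = 1e-9) {
  gh <- node_heights(gene_tree)
  sh <- node_heights(species_tree)
  g_mrca <- ape::mrca(gene_tree)
  s_mrca <- ape::mrca(species_tree)
  sp <- species_of(gene_tree$tip.label)
  if (!all(sp %in% species_tree$tip.label)) {
    stop("gene copies map to species absent from the species tree")
  }
  n <- ape::Ntip(gene_tree)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sp[i] == sp[j]) next
      g_h <- gh[g_mrca[gene_tree$tip.label[i], gene_tree$tip.label[j]]]
      s_h <- sh[s_mrca[sp[i], sp[j]]]
      if (g_h < s_h - tol) {
        stop("MSC nesting violated: copies ", gene_tree$tip.label[i], ", ",
             gene_tree$tip.label[j], " coalesce at ", g_h,
             " below species divergence ", s_h)
      }
    }
  }
  invisible(TRUE)
}

# ---- incremental tree builder (used by the coalescent-style simulators) -----

# Lineages are built bottom-up: tips start at given heights and pairs are
# merged at strictly later heights. Internal representation keeps parent and
# height arrays; finalize() renumbers so the root is Ntip+1 as ape expects.

new_lineage_builder <- function(tip_labels, tip_heights = 0) {
  n <- length(tip_labels)
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$labels <- tip_labels
  env$heights <- c(rep_len(tip_heights, n), numeric(0))
  env$parent <- integer(n)
  env$next_id <- n + 1L
  env
}

merge_lineages <- function(b, i, j, height) {
  id <- b$next_id
  b$next_id <- id + 1L
  b$heights[id] <- height
  b$parent[id] <- 0L
  b$parent[i] <- id
  b$parent[j] <- id
  id
}

finalize_lineage_tree <- function(b, root_id) {
  n <- b$n
  total <- b$next_id - 1L
  nnode <- total - n
  if (n == 1) {
    # degenerate single-tip tree: represent with a root edge
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           edge.length = b$heights[root_id],
                           tip.label = b$labels, Nnode = 1L),
                      class = "phylo")
    return(tree)
  }
  # renumber internals so the root becomes n+1
  map <- integer(total)
  map[seq_len(n)] <- seq_len(n)
  internals <- seq.int(n + 1L, total)
  others <- setdiff(internals, root_id)
  map[root_id] <- n + 1L
  if (length(others)) map[others] <- seq.int(n + 2L, total)
  child <- seq_len(total)[-root_id]
  parent <- b$parent[child]
  if (any(parent == 0L)) stop("internal error: unattached lineage")
  edge <- cbind(map[parent], map[child])
  edge.length <- b$heights[parent] - b$heights[child]
  tree <- structure(list(edge = edge, edge.length = edge.length,
                         tip.label = b$labels, Nnode = nnode),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}
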