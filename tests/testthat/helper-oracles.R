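# Independent brute-force oracles and small fixtures used across test files.
# These deliberately avoid the package's own tree plumbing: clades are
# enumerated by a separate recursive descent over the raw edge matrix.

# all leaf-label sets below non-root nodes, by direct recursion
oracle_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  tips_below <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    sort(unlist(lapply(kids(v), tips_below)))
  }
  nodes <- setdiff(seq_len(ntip + tree$Nnode), root)
  lapply(nodes, tips_below)
}

# rootward branch length of the clade below node v
oracle_clade_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(seq_len(ntip + tree$Nnode), root)
  cl <- oracle_clades(tree)
  keys <- vapply(cl, paste, "", collapse = "|")
  lens <- tree$edge.length[match(nodes, tree$edge[, 2])]
  tapply(lens, keys, sum)
}

oracle_rbs <- function(t1, t2) {
  b1 <- oracle_clade_lengths(t1)
  b2 <- oracle_clade_lengths(t2)
  keys <- union(names(b1), names(b2))
  g <- function(b, k) if (k %in% names(b)) b[[k]] else 0
  sum(vapply(keys, function(k) abs(g(b1, k) - g(b2, k)), 0))
}

oracle_rrf <- function(t1, t2) {
  k1 <- unique(vapply(oracle_clades(t1), paste, "", collapse = "|"))
  k2 <- unique(vapply(oracle_clades(t2), paste, "", collapse = "|"))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# minimum mutations over all internal state assignments (exhaustive)
oracle_parsimony_site <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  internals <- seq.int(ntip + 1L, ntip + tree$Nnode)
  best <- Inf
  combos <- expand.grid(rep(list(c("A", "C", "G", "T")), length(internals)),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    assign_state <- c(tip_states[tree$tip.label], unlist(combos[r, ]))
    names(assign_state) <- NULL
    states <- character(ntip + tree$Nnode)
    states[seq_len(ntip)] <- tip_states[tree$tip.label]
    states[internals] <- unlist(combos[r, ])
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# random ultrametric rooted tree over n tips (coalescent shape)
random_time_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rcoal(n, tip.label = labels)
  tr
}

# 3-species asymmetric tree ((A,B):T_extra, C) with given internal branch T
three_species_tree <- function(internal_t, ne, stem = 1) {
  txt <- sprintf("((A:%f,B:%f):%f,C:%f);", stem, stem, internal_t,
                 stem + internal_t)
  tr <- ape::read.tree(text = txt)
  tr$Ne <- rep(ne, 5)
  tr
}

# two-species species tree with a pendant branch long enough that copies of
# sp1 coalesce within it almost surely
two_species_tree <- function(root_height, ne) {
  txt <- sprintf("(sp1:%f,sp2:%f);", root_height, root_height)
  tr <- ape::read.tree(text = txt)
  tr$Ne <- rep(ne, 3)
  tr
}

make_alignment <- function(mat) {
  structure(list(sequences = mat, clock_rate = NA_real_),
            class = "msc_alignment")
}
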