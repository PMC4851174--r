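test_that("asymmetry is the population variance of tip depths", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(asymmetry(bal), 0)

  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  # depths 3,3,2,1: population variance 0.6875
  expect_equal(asymmetry(cat4), 0.6875)

  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(asymmetry(two), 0)

  # invariant to branch-length rescaling
  cat4b <- cat4
  cat4b$edge.length <- cat4$edge.length * 17
  expect_equal(asymmetry(cat4b), asymmetry(cat4))
})

test_that("Fitch mutation counts match hand and brute-force minima", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,B1:2);")
  inv <- make_alignment(matrix("C", 3, 4,
                               dimnames = list(c("A1", "A2", "B1"), NULL)))
  expect_equal(fitch_mutations(inv, tr), 0)

  one <- make_alignment(matrix(c("G", "G", "T"), 3, 1,
                               dimnames = list(c("A1", "A2", "B1"), NULL)))
  expect_equal(fitch_mutations(one, tr), 1)

  # exhaustive minimization over internal assignments on 4-leaf trees
  set.seed(601)
  tr4 <- random_time_tree(4, labels = c("a", "b", "c", "d"))
  for (i in 1:20) {
    site <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    names(site) <- c("a", "b", "c", "d")
    aln <- make_alignment(matrix(site, 4, 1,
                                 dimnames = list(names(site), NULL)))
    expect_equal(fitch_mutations(aln, tr4),
                 oracle_parsimony_site(tr4, site))
  }

  bad <- make_alignment(matrix("A", 2, 1, dimnames = list(c("A1", "X"), NULL)))
  expect_error(fitch_mutations(bad, tr), "labels")
})

test_that("Fitch agrees with phangorn on random alignments", {
  skip_if_not_installed("phangorn")
  set.seed(602)
  tr <- random_time_tree(6)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE), 6, 30,
              dimnames = list(tr$tip.label, NULL))
  pd <- phangorn::phyDat(m, type = "DNA")
  expect_equal(fitch_mutations(make_alignment(m), tr),
               phangorn::parsimony(tr, pd, method = "fitch"))
})

test_that("replicate statistics follow their definitions", {
  set.seed(603)
  sp <- assign_population_sizes(simulate_yule(4, 1),
                                population_model("constant", value = 0.2))
  gts <- simulate_locus_set(sp, ni = 2, nl = 3)
  alns <- lapply(gts, simulate_alignment,
                 model = substitution_model("JC"), rate = 0.05, ns = 50)
  st <- replicate_stats(sp, gts, alns)

  expect_equal(st$species_tree_height, tree_height(sp))
  expect_equal(st$mean_population_size, 0.2)
  expect_equal(st$mean_deep_coalescences,
               mean(vapply(gts, count_deep_coalescences, 0L,
                           species_tree = sp)))
  expect_equal(st$mean_tree_height_difference,
               mean(vapply(gts, tree_height, 0)) - tree_height(sp))
  expect_equal(st$mean_variable_site_count,
               mean(vapply(alns, count_variable_sites, 0L)))
  # totals, not ratio of means
  expect_equal(st$mutations_per_variable_site,
               sum(mapply(fitch_mutations, alns, gts)) /
                 sum(vapply(alns, count_variable_sites, 0L)))
  expect_gte(st$mutations_per_variable_site, 1)

  # single invariant locus: variable sites 0, ratio reported as missing
  inv <- list(make_alignment(matrix("A", 8, 10,
              dimnames = list(gts[[1]]$tip.label, NULL))))
  st0 <- replicate_stats(sp, gts[1], inv)
  expect_equal(st0$mean_variable_site_count, 0)
  expect_true(is.na(st0$mutations_per_variable_site))

  expect_error(replicate_stats(sp, list(), list()), "length")
})

test_that("Spearman correlations match rank-then-Pearson with BH at 48 tests", {
  expect_equal(residual_correlations(1:10,
               data.frame(up = (1:10)^2))$rho, 1)
  expect_equal(residual_correlations(1:10,
               data.frame(down = -(1:10)^3))$rho, -1)

  set.seed(604)
  resid <- rnorm(10)
  tab <- data.frame(s1 = rnorm(10), s2 = runif(10))
  out <- residual_correlations(resid, tab, n_tests = 48)
  for (j in 1:2) {
    rho_oracle <- stats::cor(rank(resid), rank(tab[[j]]))
    expect_equal(out$rho[j], rho_oracle)
    t_oracle <- rho_oracle * sqrt((10 - 2) / (1 - rho_oracle^2))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), 8)
    expect_equal(out$p[j], p_oracle)
  }
  # BH correction is scaled to the full family of 48 tests
  expect_equal(out$p_adj, stats::p.adjust(out$p, "BH", n = 48))

  expect_error(residual_correlations(rep(1, 10), tab), "constant")
})
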