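test_that("calibrated birth rate matches the harmonic-sum closed form", {
  expect_equal(calibrated_birth_rate(2, 1), 0.5)
  expect_equal(calibrated_birth_rate(8, 1), sum(1 / 2:8))
  expect_equal(calibrated_birth_rate(8, 1), 1.717857, tolerance = 1e-6)
  expect_equal(calibrated_birth_rate(8, 16), 1.717857 / 16, tolerance = 1e-6)
  expect_error(calibrated_birth_rate(1, 1), "at least 2")
})

test_that("Yule simulator matches analytic root height and branch length", {
  set.seed(101)
  reps <- 3000
  # n = 2: root height ~ Exponential(2 lambda)
  h2 <- replicate(reps, tree_height(simulate_yule(2, 1)))
  expect_lt(abs(mean(h2) - 0.5), 3 * stats::sd(h2) / sqrt(reps))

  # calibration identity: mean root height ~= R
  lam <- calibrated_birth_rate(8, 1)
  h8 <- replicate(reps, tree_height(simulate_yule(8, lam)))
  expect_lt(abs(mean(h8) - 1), 3 * stats::sd(h8) / sqrt(reps))

  # expected mean branch length 1 / (2 lambda)
  bl <- replicate(reps, mean(simulate_yule(8, 1)$edge.length))
  expect_lt(abs(mean(bl) - 0.5), 3 * stats::sd(bl) / sqrt(reps))
})

test_that("birth-death trees have the requested tip count and nest Yule", {
  set.seed(202)
  trees <- replicate(20, simulate_birth_death(5, 1, 0.2), simplify = FALSE)
  expect_true(all(vapply(trees, ape::Ntip, 0L) == 5))
  expect_true(all(vapply(trees, is_ultrametric_tree, TRUE)))

  # mu = 0 reduces to the Yule distribution (KS on root heights)
  reps <- 400
  h_bd <- replicate(reps, tree_height(simulate_birth_death(5, 1, 0)))
  h_yu <- replicate(reps, tree_height(simulate_yule(5, 1)))
  ks <- suppressWarnings(stats::ks.test(h_bd, h_yu))
  expect_gt(ks$p.value, 0.01)

  # root height grows with n at fixed rates
  h5 <- mean(replicate(300, tree_height(simulate_birth_death(5, 1, 0.2))))
  h13 <- mean(replicate(300, tree_height(simulate_birth_death(13, 1, 0.2))))
  expect_gt(h13, h5)
})

test_that("population size assignment covers every branch including the root", {
  set.seed(5)
  tr <- simulate_yule(6, 1)
  n_nodes <- ape::Ntip(tr) + tr$Nnode
  const <- assign_population_sizes(tr, population_model("constant", value = 0.5))
  expect_length(const$Ne, n_nodes)
  expect_true(all(const$Ne == 0.5))

  draws <- replicate(2000, {
    assign_population_sizes(tr, population_model("gamma", shape = 2,
                                                 mean = 6.35e-3))$Ne
  })
  m <- mean(draws)
  v <- stats::var(as.vector(draws))
  expect_equal(m, 6.35e-3, tolerance = 0.05)
  # gamma(shape 2, mean m) variance = m^2 / 2
  expect_equal(v, (6.35e-3)^2 / 2, tolerance = 0.1)
  expect_true(all(draws > 0))
})

test_that("expected mean branch length in coalescent units is exact", {
  expect_equal(expected_mean_branch_length(0.01315, 8, 1 / 302.05), 0.578,
               tolerance = 5e-4)
  # R = H_n - 1 and Ne = 1/4 cancel to exactly 1
  expect_equal(expected_mean_branch_length(harmonic_number(11) - 1, 11, 0.25), 1)
  # Ne -> infinity drives the coalescent branch length to 0
  expect_lt(expected_mean_branch_length(0.01315, 8, 1e12), 1e-12)
  expect_error(expected_mean_branch_length(1, 1, 1), "at least 2")
})

test_that("observed coalescent branch lengths follow tau / (2 Ne)", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tr$Ne <- c(0.5, 0.5, 0.5)
  expect_equal(mean_branch_length_coalescent(tr), 1)

  set.seed(9)
  tr2 <- simulate_yule(6, 2)
  tr2 <- assign_population_sizes(tr2, population_model("constant", value = 0.3))
  expect_equal(mean_branch_length_coalescent(tr2),
               mean(tr2$edge.length) / (2 * 0.3))
  tr2$Ne <- NULL
  expect_error(mean_branch_length_coalescent(tr2), "Ne")
})

test_that("shallow-design trees land near the reported coalescent scale", {
  # gamma Ne with shape 2 has a heavy-tailed reciprocal, so only
  # order-of-magnitude agreement with the printed 0.539 is expected
  set.seed(33)
  grand <- replicate(100, {
    tr <- simulate_yule(8, 125.3)
    tr <- assign_population_sizes(tr, population_model("gamma", shape = 2,
                                                       mean = 6.35e-3))
    mean_branch_length_coalescent(tr)
  })
  expect_gt(median(grand), 0.539 / 10)
  expect_lt(median(grand), 0.539 * 10)
})
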