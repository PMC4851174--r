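test_that("locus rate draws respect the clock model", {
  # F = 1 collapses to the base rate
  expect_equal(draw_locus_rates(5, clock_model("log-uniform-locus",
                                               mu0 = 0.01, F = 1)),
               rep(0.01, 5))
  set.seed(401)
  r <- draw_locus_rates(500, clock_model("log-uniform-locus", mu0 = 0.01,
                                         F = 3))
  expect_equal(r[1], 0.01) # first locus fixed at mu0
  expect_true(all(r >= 0.01 / 3 - 1e-12 & r <= 0.03 + 1e-12))
  # factor of 9 between fastest and slowest possible rates
  expect_equal((0.01 * 3) / (0.01 / 3), 9)
  # log-uniform: equal density of slower and faster rates around mu0
  expect_lt(abs(mean(r[-1] > 0.01) - 0.5), 3 * 0.5 / sqrt(499))

  g <- draw_locus_rates(4000, clock_model("gamma-locus", shape = 6.22,
                                          scale = 0.173))
  expect_equal(mean(g), 6.22 * 0.173, tolerance = 0.03)
})

test_that("zero rate leaves all sequences identical", {
  set.seed(402)
  tr <- random_time_tree(5)
  a <- simulate_alignment(tr, substitution_model("JC"), 0, 100)
  expect_equal(count_variable_sites(a), 0)
  expect_true(all(a$sequences == rep(a$sequences[1, ],
                                     each = nrow(a$sequences))))
})

test_that("JC divergence follows the saturation closed form", {
  set.seed(403)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  rate <- 0.15
  ns <- 20000
  a <- simulate_alignment(tr, substitution_model("JC"), rate, ns)
  d <- rate * 2 # path length between the two tips, in substitutions
  p_expected <- 0.75 * (1 - exp(-4 * d / 3))
  p_hat <- mean(a$sequences["A", ] != a$sequences["B", ])
  se <- sqrt(p_expected * (1 - p_expected) / ns)
  expect_lt(abs(p_hat - p_expected), 3 * se)
})

test_that("HKY transition probabilities agree with a matrix-exponential oracle", {
  m <- substitution_model("HKY", kappa = 4)
  for (t in c(0.01, 0.1, 0.7, 2.3)) {
    p <- transition_matrix(m, t)
    expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # independent oracle: ape's matexpo on the same generator
    p_oracle <- ape::matexpo(m$Q * t)
    expect_equal(unname(p), unname(p_oracle), tolerance = 1e-8)
  }
  # kappa = 4 inflates transitions over transversions in the generator
  expect_equal(m$Q["A", "G"] / m$Q["A", "C"], 4)

  set.seed(404)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  a <- simulate_alignment(tr, m, 0.1, 20000)
  diffs <- a$sequences["A", ] != a$sequences["B", ]
  is_transition <- (a$sequences["A", ] %in% c("A", "G") &
                    a$sequences["B", ] %in% c("A", "G")) |
                   (a$sequences["A", ] %in% c("C", "T") &
                    a$sequences["B", ] %in% c("C", "T"))
  p2 <- transition_matrix(m, 0.2)
  exp_ts <- p2["A", "G"] # transition probability (equal frequencies)
  exp_tv <- 2 * p2["A", "C"]
  ratio_hat <- sum(diffs & is_transition) / sum(diffs & !is_transition)
  expect_equal(ratio_hat, exp_ts / exp_tv, tolerance = 0.15)
})

test_that("base composition is stationary at the model frequencies", {
  set.seed(405)
  freq <- c(0.4, 0.3, 0.2, 0.1)
  m <- substitution_model("GTR", freq = freq,
                          rates = c(0.5, 2, 0.3, 0.4, 1, 0.6))
  tr <- ape::read.tree(text = "(A:1,B:1);")
  a <- simulate_alignment(tr, m, 0.5, 30000)
  counts <- table(factor(a$sequences, levels = c("A", "C", "G", "T")))
  chi <- suppressWarnings(stats::chisq.test(counts, p = freq))
  expect_gt(chi$p.value, 0.001)
})

test_that("discrete gamma categories average to 1 and vanish at high shape", {
  for (shape in c(0.05, 0.5, 2, 50)) {
    r <- discrete_gamma_rates(shape, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(discrete_gamma_rates(1e6, 4), rep(1, 4), tolerance = 1e-2)
  # site-difference proportions with huge shape match the no-variation model
  set.seed(406)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  a_g <- simulate_alignment(tr, substitution_model("JC", gamma_shape = 1e7),
                            0.1, 20000)
  a_0 <- simulate_alignment(tr, substitution_model("JC"), 0.1, 20000)
  p_g <- mean(a_g$sequences[1, ] != a_g$sequences[2, ])
  p_0 <- mean(a_0$sequences[1, ] != a_0$sequences[2, ])
  expect_lt(abs(p_g - p_0), 4 * sqrt(0.25 / 20000) * 2)
})

test_that("variable site counting matches a brute-force column scan", {
  a0 <- make_alignment(matrix("A", 3, 5,
                              dimnames = list(c("A", "B", "C"), NULL)))
  expect_equal(count_variable_sites(a0), 0)
  a1 <- make_alignment(rbind(A = strsplit("ACGT", "")[[1]],
                             B = strsplit("ACGA", "")[[1]]))
  expect_equal(count_variable_sites(a1), 1)

  set.seed(407)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T"), 40, replace = TRUE), 4, 10,
                dimnames = list(paste0("t", 1:4), NULL))
    brute <- sum(vapply(seq_len(10),
                        function(j) length(unique(m[, j])) > 1, TRUE))
    expect_equal(count_variable_sites(make_alignment(m)), brute)
  }
})

test_that("FASTA round-trips an alignment", {
  set.seed(408)
  tr <- random_time_tree(4)
  a <- simulate_alignment(tr, substitution_model("JC"), 0.1, 30)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a, f)
  back <- read_fasta(f)
  expect_equal(back$sequences[rownames(a$sequences), ], a$sequences)
})
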