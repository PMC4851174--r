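test_that("ESS recovers white-noise and AR(1) autocorrelation times", {
  set.seed(701)
  x <- rnorm(10000)
  expect_gt(ess(x) / length(x), 0.8)
  expect_lte(ess(x) / length(x), 1.2)

  # AR(1) with coefficient 0.9: ESS ~= N (1 - rho) / (1 + rho)
  n <- 100000
  rho <- 0.9
  ar <- as.vector(stats::arima.sim(list(ar = rho), n))
  expect_equal(ess(ar), n * (1 - rho) / (1 + rho), tolerance = 0.2)

  # 10 values each held for 1000 states: far fewer effective samples than N
  dup <- rep(rnorm(10), each = 1000)
  expect_lt(ess(dup), length(dup) / 50)

  expect_error(ess(rep(1, 100)), "constant")
  expect_error(ess(rnorm(5)), "n >= 10")
})

test_that("log-log regression recovers known coefficients", {
  # noiseless: exact recovery
  grid <- expand.grid(nl = c(2, 4, 8, 16, 32, 64), n = c(5, 8, 13),
                      ni = c(1, 2, 4))
  beta <- c(beta1 = -2.81, beta2 = -0.42, beta3 = -0.46, alpha = 17.98)
  grid$Y <- exp(beta["beta1"] * log(grid$nl) + beta["beta2"] * grid$n +
                beta["beta3"] * grid$ni + beta["alpha"])
  fit <- suppressWarnings(fit_loglog(grid)) # lm warns on a perfect fit
  expect_equal(fit$coefficients, beta, tolerance = 1e-8)

  # Gaussian log-noise: recovery within 3 standard errors
  set.seed(702)
  rows <- data.frame(nl = sample(c(2, 4, 8, 16, 32, 64, 128, 256), 800,
                                 replace = TRUE),
                     n = sample(c(5, 8, 13), 800, replace = TRUE),
                     ni = sample(c(2, 4, 8), 800, replace = TRUE))
  rows$Y <- exp(beta["beta1"] * log(rows$nl) + beta["beta2"] * rows$n +
                beta["beta3"] * rows$ni + beta["alpha"] +
                rnorm(800, 0, 0.1))
  fit2 <- fit_loglog(rows)
  for (k in names(beta)) {
    expect_lt(abs(fit2$coefficients[k] - beta[k]), 3 * fit2$se[k])
  }

  # single-predictor restriction reproduces a plain power-law fit
  sub <- rows[rows$n == 5 & rows$ni == 2, ]
  fit3 <- fit_loglog(sub, predictors = "log_nl")
  plain <- stats::lm(log(Y) ~ log(nl), data = sub)
  expect_equal(unname(fit3$coefficients["beta1"]),
               unname(stats::coef(plain)[2]))
  expect_error(fit_loglog(rows[1:3, ]), "nrow")
})

test_that("power-law predictions reproduce the printed worked examples", {
  # relative error at 256 loci from the reported (slope, intercept)
  expect_equal(powerlaw_predict(power_law(-0.435, -0.889), 256), 0.037,
               tolerance = 0.01)
  # ESS per million states at 256 loci
  expect_equal(powerlaw_predict(power_law(-1.97, 7.86), 256), 0.047,
               tolerance = 0.01)
  expect_equal(powerlaw_predict(power_law(0, 1.5), 123), exp(1.5))

  # extrapolations
  # the printed extrapolation is given to two significant figures
  expect_equal(powerlaw_extrapolate(0.037, 256, 1024, -0.435), 0.020,
               tolerance = 0.025)
  expect_equal(powerlaw_extrapolate(4.3, 256, 1024, 1.97), 66,
               tolerance = 0.01)
  expect_equal(powerlaw_extrapolate(0.42, 64, 64, -1), 0.42)
})

test_that("workload and error-reduction arithmetic", {
  # 200 ESS at 0.047 per million states: about 4.3 billion states
  expect_equal(workload(200, 0.047) * 1e6, 4.3e9, tolerance = 0.02)
  expect_equal(workload(200, 200), 1)
  expect_equal(workload(100, 0.5), 2 * workload(100, 1))
  expect_error(workload(200, 0), "positive")

  expect_equal(error_reduction(16, -0.433), 70, tolerance = 0.01)
  expect_equal(error_reduction(16, -0.365), 64, tolerance = 0.01)
  expect_equal(error_reduction(16, -0.568), 79, tolerance = 0.01)
  expect_equal(error_reduction(1, -0.435), 0)
  expect_warning(error_reduction(2, 0.5), "increases")
})

test_that("ESS/hour and ESS/Mstates slopes differ by one on constructed data", {
  # constant states-per-hour across nl-proportional workloads
  set.seed(703)
  nl <- rep(c(8, 16, 32, 64, 128, 256), each = 10)
  ess_per_mstates <- exp(7.86 - 1.97 * log(nl) + rnorm(60, 0, 0.05))
  mstates_per_hour <- 50 / nl # time per state linear in the number of loci
  ess_per_hour <- ess_per_mstates * mstates_per_hour
  f_s <- fit_loglog(data.frame(Y = ess_per_mstates, nl = nl, n = 5, ni = 2),
                    predictors = "log_nl")
  f_h <- fit_loglog(data.frame(Y = ess_per_hour, nl = nl, n = 5, ni = 2),
                    predictors = "log_nl")
  expect_equal(unname(f_h$coefficients["beta1"]),
               unname(f_s$coefficients["beta1"]) - 1, tolerance = 1e-8)
})

test_that("crossover finder recovers a constructed crossover point", {
  set.seed(704)
  c_true <- 1.5
  bl <- exp(runif(120, log(0.1), log(10)))
  ratios <- (bl / c_true)^0.8 * exp(rnorm(120, 0, 0.05))
  cross <- find_crossover(bl, ratios, span = 0.5)
  expect_equal(cross, c_true, tolerance = 0.15)

  # invariant to reordering of the points
  ord <- sample(120)
  expect_equal(find_crossover(bl[ord], ratios[ord], span = 0.5), cross)

  # all ratios below 1: no-crossover signal
  expect_true(is.na(find_crossover(bl, rep(0.5, 120) *
                                     exp(rnorm(120, 0, 0.01)))))
  expect_error(find_crossover(bl[1:10], ratios[1:10]), "20 points")
})
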