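# ESS estimation, log-log multiple regression of MCMC performance and error
# against the number of loci, species and individuals, power-law prediction
# and extrapolation, workload arithmetic, and the local-regression crossover
# finder. All logarithms are natural logs; the printed slope/intercept pairs
# of the scaling fits reproduce their worked predictions only under natural
# log.

#' Effective sample size of an MCMC trace
#'
#' Tracer-style estimator: the autocorrelation time (ACT) is computed from
#' the empirical autocorrelation function truncated at the first lag whose
#' paired sum (initial-positive-sequence rule) turns negative, with a maximum
#' lag of N/3; ESS = N / ACT, capped at N.
#'
#' @param series numeric trace column (length >= 10)
#' @return effective sample size (<= N)
#' @export
ess <- function(series) {
  n <- length(series)
  stopifnot(n >= 10)
  if (stats::sd(series) == 0) {
    stop("undefined autocorrelation: trace series is constant")
  }
  max_lag <- floor(n / 3)
  rho <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  # paired sums Gamma_m = rho_{2m} + rho_{2m+1} (rho_0 = 1)
  n_pairs <- floor((length(rho)) / 2)
  act <- 0
  gsum <- 0
  for (m in seq_len(n_pairs)) {
    g <- rho[2 * m - 1] + rho[2 * m]
    if (m > 1 && g < 0) break
    gsum <- gsum + g
  }
  act <- max(2 * gsum - 1, 1)
  min(n / act, n)
}

#' Power-law coefficients
#'
#' @param slope dimensionless log-log slope
#' @param intercept intercept on the natural-log scale
#' @return an object of class `power_law`
#' @export
power_law <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept), class = "power_law")
}

#' Fit the log-log multiple regression
#'
#' Ordinary least squares of log(Y) on log(nl), n, ni and an intercept:
#' log(Y) = beta1 log(nl) + beta2 n + beta3 ni + alpha, all logarithms
#' natural. Coefficient standard errors come from the usual OLS variance.
#'
#' @param rows data frame with columns `Y` (> 0), `nl` (>= 1), `n`, `ni`;
#'   at least 5 rows
#' @param predictors which explanatory variables to include (restriction to
#'   `"log_nl"` alone reproduces a plain power-law fit)
#' @return an object of class `loglog_fit` with `coefficients`, `se` and the
#'   underlying `lm` fit
#' @export
fit_loglog <- function(rows, predictors = c("log_nl", "n", "ni")) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 5,
            all(c("Y", "nl") %in% names(rows)),
            all(rows$Y > 0), all(rows$nl >= 1))
  dat <- data.frame(logY = log(rows$Y), log_nl = log(rows$nl))
  if ("n" %in% predictors) dat$n <- rows$n
  if ("ni" %in% predictors) dat$ni <- rows$ni
  form <- stats::as.formula(paste("logY ~",
                                  paste(intersect(predictors, names(dat)),
                                        collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("rank-deficient design: coefficients not estimable")
  sm <- summary(fit)
  out <- list(
    coefficients = c(
      beta1 = unname(cf["log_nl"]),
      beta2 = if ("n" %in% names(cf)) unname(cf["n"]) else NA_real_,
      beta3 = if ("ni" %in% names(cf)) unname(cf["ni"]) else NA_real_,
      alpha = unname(cf["(Intercept)"])
    ),
    se = c(
      beta1 = unname(sm$coefficients["log_nl", "Std. Error"]),
      beta2 = if ("n" %in% rownames(sm$coefficients)) {
        unname(sm$coefficients["n", "Std. Error"])
      } else NA_real_,
      beta3 = if ("ni" %in% rownames(sm$coefficients)) {
        unname(sm$coefficients["ni", "Std. Error"])
      } else NA_real_,
      alpha = unname(sm$coefficients["(Intercept)", "Std. Error"])
    ),
    r_squared = sm$r.squared,
    fit = fit
  )
  class(out) <- "loglog_fit"
  out
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("log-log fit (natural log):\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("R-squared:", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' Predict a response from a power law
#'
#' Evaluates exp(intercept + slope * ln nl).
#'
#' @param pl a [power_law()]
#' @param nl number of loci (>= 1)
#' @return predicted response value
#' @export
powerlaw_predict <- function(pl, nl) {
  stopifnot(inherits(pl, "power_law"), nl >= 1)
  exp(pl$intercept + pl$slope * log(nl))
}

#' Extrapolate a response along a power law
#'
#' Given the response at nl0 loci, the response at nl1 loci is
#' value * (nl1 / nl0)^slope.
#'
#' @param value response at `nl0` (> 0)
#' @param nl0,nl1 locus counts (>= 1)
#' @param slope power-law slope
#' @return response at `nl1`
#' @export
powerlaw_extrapolate <- function(value, nl0, nl1, slope) {
  stopifnot(value > 0, nl0 >= 1, nl1 >= 1)
  value * (nl1 / nl0)^slope
}

#' Workload to reach a target ESS
#'
#' @param target_ess required effective sample size
#' @param ess_rate ESS produced per unit of work (> 0); e.g. ESS per million
#'   states or ESS per hour
#' @return units of work required
#' @export
workload <- function(target_ess, ess_rate) {
  if (ess_rate <= 0) stop("ESS rate must be positive")
  target_ess / ess_rate
}

#' Error reduction from a fold increase in loci
#'
#' With a negative power-law slope, multiplying the number of loci by
#' `fold_increase` reduces the error by 100 * (1 - fold_increase^slope)
#' percent.
#'
#' @param fold_increase ratio of locus counts (>= 1)
#' @param slope power-law slope (negative for a reduction)
#' @return percent reduction in error
#' @export
error_reduction <- function(fold_increase, slope) {
  stopifnot(fold_increase >= 1)
  if (slope > 0) warning("positive slope: error increases with more loci")
  100 * (1 - fold_increase^slope)
}

#' Crossover point of an error-ratio curve
#'
#' First-degree local regression (tricube weights) of log error ratio on log
#' mean branch length; returns the branch length (coalescent units) at which
#' the smoothed curve crosses ratio 1, found by bisection on the smoothed
#' function. Returns NA (the no-crossover signal) when the smoothed curve
#' never crosses 1.
#'
#' @param branch_lengths mean branch lengths in coalescent units (> 0)
#' @param ratios error ratios (> 0), aligned with `branch_lengths`
#' @param span local-regression span
#' @return crossover branch length in coalescent units, or NA
#' @export
find_crossover <- function(branch_lengths, ratios, span = 0.75) {
  stopifnot(length(branch_lengths) == length(ratios),
            all(branch_lengths > 0), all(ratios > 0))
  if (length(ratios) < 20) stop("at least 20 points are required")
  ord <- order(branch_lengths)
  x <- log(branch_lengths[ord])
  y <- log(ratios[ord])
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = 512)
  smooth <- stats::predict(fit, newdata = data.frame(x = grid))
  sgn <- sign(smooth)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (any(smooth == 0)) return(exp(grid[which(smooth == 0)[1]]))
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  root <- stats::uniroot(function(z) {
    stats::predict(fit, newdata = data.frame(x = z))
  }, lower = grid[i], upper = grid[i + 1])$root
  exp(root)
}
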