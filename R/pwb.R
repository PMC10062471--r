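#' Configuration for the partial-weight-bearing simulation
#'
#' True per-cycle maximum forces are drawn from
#' `F ~ Normal(mu_f, sigma_f^2)` (%BW), defaults 50 +/- 25 %BW as
#' reported for patients walking under 50% PWB instructions. The sensor's
#' measurement error follows the fitted difference-vs-magnitude model:
#' `D | F ~ Normal(slope * F + intercept, resid_sd^2)`, and the measured
#' value is `M = F + D`. Both `M` and the truth `F` are classified
#' against the prescribed limit `limit` (strictly greater = overload).
#'
#' @param mu_f,sigma_f Mean and SD of true maximum force, %BW.
#' @param limit Prescribed PWB limit, %BW.
#' @param n_draws Number of simulated gait cycles.
#' @param slope,intercept,resid_sd Error model (dimensionless, %BW, %BW).
#' @param seed Integer seed.
#' @return An object of class `pwb_config`.
#' @export
pwb_config <- function(mu_f = 50, sigma_f = 25, limit = 50,
                       n_draws = 1e7, slope = 0, intercept = 0,
                       resid_sd = 0, seed = 1L) {
  stopifnot(sigma_f > 0, resid_sd >= 0, n_draws >= 1)
  structure(
    list(mu_f = mu_f, sigma_f = sigma_f, limit = limit,
         n_draws = as.double(n_draws), slope = slope,
         intercept = intercept, resid_sd = resid_sd,
         seed = as.integer(seed)),
    class = "pwb_config"
  )
}

pwb_result <- function(tab, n_draws, analytic = FALSE) {
  # tab: named counts below_below, below_above, above_below, above_above
  # ("truth_measured"); sensitivity = correct below / true below,
  # specificity = correct above / true above
  n_below <- tab[["below_below"]] + tab[["below_above"]]
  n_above <- tab[["above_below"]] + tab[["above_above"]]
  sens <- if (n_below > 0) tab[["below_below"]] / n_below else NA_real_
  spec <- if (n_above > 0) tab[["above_above"]] / n_above else NA_real_
  se <- function(p, n) if (!is.na(p) && n > 0 && !analytic) {
    sqrt(p * (1 - p) / n)
  } else 0
  structure(
    list(sensitivity = sens, specificity = spec,
         sensitivity_se = se(sens, n_below),
         specificity_se = se(spec, n_above),
         counts = tab, n_draws = n_draws, analytic = analytic),
    class = "pwb_result"
  )
}

#' @export
print.pwb_result <- function(x, ...) {
  cat(sprintf(
    "<pwb_result%s> sensitivity = %.4f (SE %.2g), specificity = %.4f (SE %.2g)\n",
    if (x$analytic) ", analytic" else "", x$sensitivity,
    x$sensitivity_se, x$specificity, x$specificity_se))
  invisible(x)
}

#' Monte-Carlo simulation of overload detection under PWB
#'
#' Draws `n_draws` true maximum forces, corrupts each with the configured
#' error model, classifies truth and measurement against the limit, and
#' reports sensitivity (correctly identified below-limit forces over all
#' truly below-limit forces) and specificity (correctly identified
#' above-limit forces over all truly above-limit forces) with their
#' binomial Monte-Carlo standard errors. Deterministic given the seed;
#' values exactly at the limit classify as "below" (overload is strictly
#' greater than the limit).
#'
#' @param cfg A `pwb_config`.
#' @return A `pwb_result` with the 2x2 classification counts.
#' @export
simulate_pwb <- function(cfg) {
  stopifnot(inherits(cfg, "pwb_config"))
  n <- cfg$n_draws
  tab <- with_seed(cfg$seed, {
    f <- stats::rnorm(n, cfg$mu_f, cfg$sigma_f)
    d <- cfg$slope * f + cfg$intercept
    if (cfg$resid_sd > 0) d <- d + stats::rnorm(n, 0, cfg$resid_sd)
    m <- f + d
    t_above <- f > cfg$limit
    m_above <- m > cfg$limit
    c(below_below = sum(!t_above & !m_above),
      below_above = sum(!t_above & m_above),
      above_below = sum(t_above & !m_above),
      above_above = sum(t_above & m_above))
  })
  pwb_result(as.list(tab), n)
}

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard normal margins with correlation
#' `rho`, by adaptive quadrature of the single-integral representation
#' (the tetrachoric integral over the correlation path). Accurate to
#' ~1e-12; handles `rho = +/-1` by the degenerate limits.
#'
#' @param h,k Upper limits.
#' @param rho Correlation in [-1, 1].
#' @return Probability.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(h) == 1L, length(k) == 1L, abs(rho) <= 1)
  if (rho == 0 || is.infinite(h) || is.infinite(k)) {
    return(stats::pnorm(h) * stats::pnorm(k))
  }
  if (rho == 1) return(stats::pnorm(min(h, k)))
  if (rho == -1) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  f <- function(t) {
    exp(-(h^2 + k^2 - 2 * h * k * sin(t)) / (2 * cos(t)^2))
  }
  v <- stats::integrate(f, 0, asin(rho), rel.tol = 1e-13,
                        abs.tol = 1e-15)$value
  stats::pnorm(h) * stats::pnorm(k) + v / (2 * pi)
}

#' Closed-form PWB sensitivity and specificity
#'
#' The analytic counterpart (zero Monte-Carlo error) of
#' [simulate_pwb()]. With `M = (1 + s) F + b + e`,
#' `(F, M)` is bivariate normal with means `(mu_f, (1+s) mu_f + b)`,
#' standard deviations `(sigma_f, sqrt((1+s)^2 sigma_f^2 + resid_sd^2))`
#' and covariance `(1+s) sigma_f^2`; sensitivity and specificity are
#' ratios of bivariate-normal orthant probabilities. The degenerate case
#' `resid_sd = 0` (perfectly correlated or anti-correlated margins) is
#' handled by the corresponding limit expressions.
#'
#' @param cfg A `pwb_config` (`n_draws` is ignored).
#' @return A `pwb_result` with expected counts scaled to `n_draws`.
#' @export
analytic_pwb <- function(cfg) {
  stopifnot(inherits(cfg, "pwb_config"))
  a <- 1 + cfg$slope
  mu1 <- cfg$mu_f
  mu2 <- a * cfg$mu_f + cfg$intercept
  sd1 <- cfg$sigma_f
  sd2 <- sqrt(a^2 * cfg$sigma_f^2 + cfg$resid_sd^2)
  p_below_truth <- stats::pnorm(cfg$limit, mu1, sd1)
  if (sd2 == 0) {
    # a == 0 and resid_sd == 0: M is the constant intercept
    m_below <- (cfg$intercept <= cfg$limit)
    p_bb <- if (m_below) p_below_truth else 0
    p_aa <- if (!m_below) 1 - p_below_truth else 0
  } else {
    h <- (cfg$limit - mu1) / sd1
    k <- (cfg$limit - mu2) / sd2
    rho <- a * cfg$sigma_f^2 / (sd1 * sd2)
    p_bb <- pbvnorm(h, k, rho)
    p_aa <- 1 - stats::pnorm(h) - stats::pnorm(k) + p_bb
  }
  n <- cfg$n_draws
  tab <- list(below_below = n * p_bb,
              below_above = n * (p_below_truth - p_bb),
              above_below = n * (1 - p_below_truth - p_aa),
              above_above = n * p_aa)
  pwb_result(tab, n, analytic = TRUE)
}

#' PWB performance implied by a fitted agreement analysis
#'
#' Takes the difference-vs-magnitude error model (slope, intercept,
#' residual SD) from a [bland_altman()] result and evaluates overload
#' detection with both the Monte-Carlo engine and the closed-form oracle.
#'
#' @param ba A `bland_altman` result.
#' @param ... Overrides passed to [pwb_config()] (e.g. `mu_f`, `n_draws`,
#'   `seed`).
#' @return List with elements `mc` and `analytic` (both `pwb_result`) and
#'   `discrepancy` (named numeric: absolute rate differences).
#' @export
pwb_from_agreement <- function(ba, ...) {
  if (is.null(ba$slope) || is.null(ba$intercept) || is.null(ba$resid_sd)) {
    stop("bland_altman result lacks the bias-vs-magnitude regression",
         call. = FALSE)
  }
  cfg <- pwb_config(slope = ba$slope, intercept = ba$intercept,
                    resid_sd = ba$resid_sd, ...)
  mc <- simulate_pwb(cfg)
  an <- analytic_pwb(cfg)
  list(mc = mc, analytic = an,
       discrepancy = c(
         sensitivity = abs(mc$sensitivity - an$sensitivity),
         specificity = abs(mc$specificity - an$specificity)))
}
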