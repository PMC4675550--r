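#' Cohort counts of benign and aggressive tumors
#'
#' Container for the observed numbers of benign (PA-I) and aggressive
#' (PA-II) cases from which the benign fraction is estimated.
#'
#' @param benign Nonnegative integer count of benign PA-I cases.
#' @param aggressive Nonnegative integer count of aggressive PA-II cases.
#' @return An object of class `"cohort_counts"`.
#' @examples
#' cohort_counts(57, 9)
#' @export
cohort_counts <- function(benign, aggressive) {
  for (x in list(benign, aggressive))
    if (length(x) != 1L || !is.finite(x) || x < 0 || x != round(x))
      stop("counts must be single nonnegative integers")
  if (benign + aggressive < 1) stop("the cohort must contain at least one case")
  structure(list(benign = as.integer(benign),
                 aggressive = as.integer(aggressive)),
            class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("Cohort: %d benign (PA-I), %d aggressive (PA-II), total %d\n",
              x$benign, x$aggressive, x$benign + x$aggressive))
  invisible(x)
}

#' Estimate the benign fraction from cohort counts
#'
#' Point estimate `p_hat = benign / total` with its binomial (Wald)
#' standard error `sqrt(p_hat (1 - p_hat) / total)`.
#'
#' @param cohort A [cohort_counts()] object.
#' @return List with `p_hat` and `stderr`.
#' @examples
#' estimate_fraction(cohort_counts(57, 9))   # p_hat = 0.8636
#' @export
estimate_fraction <- function(cohort) {
  if (!inherits(cohort, "cohort_counts"))
    stop("`cohort` must come from cohort_counts()")
  n <- cohort$benign + cohort$aggressive
  p <- cohort$benign / n
  list(p_hat = p, stderr = sqrt(p * (1 - p) / n))
}

#' Invert the asymptotic absorption identity for the risk coefficient
#'
#' Solves `alpha_asymptotic(gamma) = p_hat` for `gamma`.  Since
#' `alpha(gamma) = 1/I0(2*sqrt(gamma))` is continuous and strictly
#' decreasing with `alpha(0) = 1`, the root is unique; it is found by
#' bracketed root finding on `[0, gamma_max]` with the bracket doubled
#' until it straddles the root.
#'
#' @param p_hat Observed benign fraction in `(0, 1]`.
#' @param tol Tolerance on `alpha(gamma) - p_hat` (default `1e-10`).
#' @return The nonnegative risk coefficient `gamma`.
#' @examples
#' calibrate_gamma(57 / 66)   # ~ 0.152
#' calibrate_gamma(1)         # 0
#' @export
calibrate_gamma <- function(p_hat, tol = 1e-10) {
  if (length(p_hat) != 1L || !is.finite(p_hat) || p_hat <= 0 || p_hat > 1)
    stop("`p_hat` must lie in (0, 1]")
  if (p_hat == 1) return(0)
  hi <- 1
  while (alpha_asymptotic(hi) >= p_hat) {
    hi <- hi * 2
    if (hi > 1e12) stop("failed to bracket the root for p_hat = ", p_hat)
  }
  root <- uniroot(function(g) alpha_asymptotic(g) - p_hat,
                  lower = 0, upper = hi, tol = 1e-14)$root
  if (abs(alpha_asymptotic(root) - p_hat) > tol)
    stop("root finder did not reach the requested tolerance")
  root
}

#' Calibrate the risk coefficient from a cohort
#'
#' Full calibration: estimates the benign fraction, inverts the absorption
#' identity for `gamma_hat`, and propagates the sampling uncertainty of the
#' fraction into a `gamma` interval.  With `method = "wald"` the interval
#' maps `p_hat -/+ 1 SE` through the (decreasing) inverse; with
#' `method = "exact"` a Clopper-Pearson interval at ~68.3% coverage (the
#' 1-SD analogue) is mapped instead, which is better behaved for small
#' cohorts.
#'
#' @param cohort A [cohort_counts()] object.
#' @param method `"wald"` (default) or `"exact"`.
#' @param tol Solver tolerance passed to [calibrate_gamma()].
#' @return An object of class `"calibration_result"`: list with `p_hat`,
#'   `p_hat_stderr`, `gamma_hat`, `gamma_interval` (low, high),
#'   `solver_tolerance`, `method`.
#' @examples
#' calibrate(cohort_counts(57, 9))
#' @export
calibrate <- function(cohort, method = c("wald", "exact"), tol = 1e-10) {
  method <- match.arg(method)
  est <- estimate_fraction(cohort)
  gamma_hat <- calibrate_gamma(est$p_hat, tol = tol)
  if (method == "wald") {
    interval <- gamma_uncertainty(cohort, tol = tol)
  } else {
    ci <- binom.test(cohort$benign, cohort$benign + cohort$aggressive,
                     conf.level = 2 * stats::pnorm(1) - 1)$conf.int
    interval <- c(calibrate_gamma(min(ci[2], 1), tol = tol),
                  calibrate_gamma(ci[1], tol = tol))
  }
  structure(list(p_hat = est$p_hat, p_hat_stderr = est$stderr,
                 gamma_hat = gamma_hat, gamma_interval = interval,
                 solver_tolerance = tol, method = method),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Risk-coefficient calibration\n")
  cat(sprintf("  p_hat     = %.4f (SE %.4f)\n", x$p_hat, x$p_hat_stderr))
  cat(sprintf("  gamma_hat = %.6f  [%s interval %.6f, %.6f]\n",
              x$gamma_hat, x$method, x$gamma_interval[1], x$gamma_interval[2]))
  invisible(x)
}

#' Risk-coefficient interval from the sampling error of the benign fraction
#'
#' Maps `p_hat + stderr` and `p_hat - stderr` through the inverse of the
#' absorption identity.  Since the inverse is decreasing, the higher
#' fraction gives the lower `gamma`; the returned pair is `(low, high)`
#' and brackets `gamma_hat`.
#'
#' @inheritParams calibrate
#' @return Numeric vector `c(low, high)`.
#' @examples
#' gamma_uncertainty(cohort_counts(57, 9))
#' @export
gamma_uncertainty <- function(cohort, tol = 1e-10) {
  est <- estimate_fraction(cohort)
  if (est$p_hat - est$stderr <= 0)
    stop("p_hat - stderr is not positive; the lower fraction bound is ",
         "outside (0, 1]")
  c(calibrate_gamma(min(est$p_hat + est$stderr, 1), tol = tol),
    calibrate_gamma(est$p_hat - est$stderr, tol = tol))
}

#' The calibrated PA-regression-function
#'
#' Returns the regression curve for a calibrated risk coefficient as a
#' function of the residual fraction `rho`, in the factored form
#' `prefactor * sqrt(1-rho) * I1(arg_coef * sqrt(1-rho))` with
#' `prefactor = 1/I1(2*sqrt(gamma_hat))` and `arg_coef = 2*sqrt(gamma_hat)`
#' exposed as attributes (and as `$prefactor` / `$arg_coef` via the
#' returned object's environment).
#'
#' @param gamma_hat Positive calibrated risk coefficient.
#' @return A function of `rho` with attributes `prefactor`, `arg_coef`
#'   and `gamma`, class `"pa_regression_fn"`.
#' @examples
#' f <- pa_regression_function(0.152)
#' attr(f, "prefactor")   # 2.3795
#' attr(f, "arg_coef")    # 0.7797
#' f(1/9)                 # 0.8816
#' @export
pa_regression_function <- function(gamma_hat) {
  if (length(gamma_hat) != 1L || !is.finite(gamma_hat) || gamma_hat <= 0)
    stop("`gamma_hat` must be a single positive number")
  f <- function(rho) beta_asymptotic(gamma_hat, rho)
  attr(f, "gamma") <- gamma_hat
  attr(f, "prefactor") <- 1 / besselI(2 * sqrt(gamma_hat), 1)
  attr(f, "arg_coef") <- 2 * sqrt(gamma_hat)
  class(f) <- c("pa_regression_fn", "function")
  f
}

#' @export
print.pa_regression_fn <- function(x, ...) {
  cat(sprintf(
    "PA-regression-function: beta(rho) = %.4f * sqrt(1-rho) * I1(%.4f * sqrt(1-rho))\n",
    attr(x, "prefactor"), attr(x, "arg_coef")))
  cat(sprintf("  (gamma = %g)\n", attr(x, "gamma")))
  invisible(x)
}
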