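# Ratio I1(2*sqrt(gamma*(1-rho))) / I1(2*sqrt(gamma)) evaluated through
# exponentially scaled Bessel functions, stable for large gamma.
bessel_i1_ratio <- function(gamma, rho) {
  x1 <- 2 * sqrt(gamma * (1 - rho))
  x2 <- 2 * sqrt(gamma)
  besselI(x1, 1, expon.scaled = TRUE) / besselI(x2, 1, expon.scaled = TRUE) *
    exp(x1 - x2)
}

# gamma below this routes to the exact neutral formula 1 - rho (the Bessel
# ratio degenerates to 0/0 as gamma -> 0).
.neutral_gamma_eps <- 1e-10

#' Asymptotic tumor regression function
#'
#' Probability that a residual tumor occupying fraction `rho = k/N` of the
#' critical size regresses (the type-I lineage goes extinct before reaching
#' `N` or producing a type-II cell), in the large-`N` diffusion limit:
#' `beta_gamma(rho) = sqrt(1-rho) * I1(2*sqrt(gamma*(1-rho))) / I1(2*sqrt(gamma))`.
#' `beta(0) = 1`, `beta(1) = 0`, strictly decreasing in `rho` and in
#' `gamma`.  For `gamma` below `1e-10` the exact neutral Moran limit
#' `1 - rho` is returned.
#'
#' @param gamma Nonnegative risk coefficient.
#' @param rho Residual tumor fraction(s) in `[0, 1]` (vectorized).
#' @return Regression probabilities in `[0, 1]`.
#' @examples
#' beta_asymptotic(0.152, 1/9)   # 1 cm^3 of a 9 cm^3 critical volume
#' beta_asymptotic(0.152, c(0, 0.5, 1))
#' @export
beta_asymptotic <- function(gamma, rho) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a single nonnegative number")
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("`rho` must lie in [0, 1]")
  if (gamma < .neutral_gamma_eps) return(1 - rho)
  sqrt(1 - rho) * bessel_i1_ratio(gamma, rho)
}

#' Exact finite-N regression probability
#'
#' Probability of tumor extinction (absorption at 0) for the `u = 0`
#' sub-process started from `k` type-I cells, from the exact first-step
#' solve with all three absorbing states.  Converges to
#' [beta_asymptotic()] at `rho = k/N` as `N` grows.
#'
#' @param N Population size (integer `>= 2`).
#' @param gamma Risk coefficient with `gamma / N^2 < 1`.
#' @param k Start state(s), integers in `[0, N]`.
#' @return Extinction probabilities in `[0, 1]`.
#' @examples
#' beta_finite(100, 0.152, 50)
#' beta_finite(100, 0, 0:100)   # neutral: exactly 1 - k/N
#' @export
beta_finite <- function(N, gamma, k) {
  if (any(k != round(k)) || any(k < 0) || any(k > N))
    stop("`k` must be integers in [0, N]")
  pr <- absorption_probs_finite(tgp_params(N = N, gamma = gamma))
  pr$hit_zero[k + 1L]
}

# Value and slope of the regression function at the expansion point 0.5.
# d/drho [sqrt(1-rho) I1(2 sqrt(gamma (1-rho)))] at rho = 0.5 gives, with
# y = sqrt(2*gamma),
#   slope = -[2 I1(y) + y (I0(y) + I2(y))] / (2 sqrt(2) I1(2 sqrt(gamma)))
# using I1'(x) = (I0(x) + I2(x)) / 2.
taylor_coefs <- function(gamma) {
  if (gamma < .neutral_gamma_eps)
    return(list(value = 0.5, slope = -1))
  y <- sqrt(2 * gamma)
  slope <- -(2 * besselI(y, 1) + y * (besselI(y, 0) + besselI(y, 2))) /
    (2 * sqrt(2) * besselI(2 * sqrt(gamma), 1))
  list(value = beta_asymptotic(gamma, 0.5), slope = slope)
}

#' First-order Taylor polynomial of the regression function
#'
#' Evaluates `T1(rho) = beta_gamma(0.5) + beta_gamma'(0.5) * (rho - 0.5)`,
#' the tangent of the regression function at the midpoint.  The derivative
#' is the closed form built from `I0`, `I1`, `I2` (see
#' [max_taylor_deviation()] for the deviation analysis).  In the neutral
#' limit `T1(rho) = 1 - rho` is recovered exactly.
#'
#' @param gamma Positive risk coefficient (or 0/near-0 for the neutral
#'   limit).
#' @param rho Evaluation point(s) in `[0, 1]` (vectorized).
#' @return Values of the tangent line.
#' @examples
#' taylor_t1(0.152, c(0, 0.5, 1))
#' @export
taylor_t1 <- function(gamma, rho) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a single nonnegative number")
  if (any(rho < 0) || any(rho > 1)) stop("`rho` must lie in [0, 1]")
  co <- taylor_coefs(gamma)
  co$value + co$slope * (rho - 0.5)
}

#' Analytic bound on the Taylor remainder
#'
#' The Lagrange remainder of the first-order expansion of the regression
#' function at `rho = 0.5` is bounded by `gamma / 8` uniformly on
#' `[0, 1]`.
#'
#' @param gamma Nonnegative risk coefficient.
#' @return `gamma / 8`.
#' @examples
#' remainder_bound(0.152)
#' @export
remainder_bound <- function(gamma) {
  if (any(gamma < 0)) stop("`gamma` must be nonnegative")
  gamma / 8
}

#' Maximal deviation of the regression function from its midpoint tangent
#'
#' Evaluates `|beta_gamma(rho) - T1(rho)|` on a grid over `[0, 1]`
#' (endpoints included) and reports the supremum together with the analytic
#' bound `gamma / 8`.  Because the regression function has single-signed
#' curvature, the extremum of the deviation from the midpoint tangent sits
#' at an endpoint; the grid is a safety net, not a necessity.
#'
#' @param gamma Nonnegative risk coefficient.
#' @param grid_step Grid spacing in `(0, 1e-3]`; default `1e-5`.
#' @return An object of class `"taylor_approximation"`: list with `gamma`,
#'   `expansion_point` (0.5), `intercept_at_0` (`T1(0)`), `slope`,
#'   `remainder_bound` (`gamma/8`), `max_observed_deviation`, and
#'   `argmax_rho`.
#' @examples
#' max_taylor_deviation(0.152)
#' @export
max_taylor_deviation <- function(gamma, grid_step = 1e-5) {
  if (length(grid_step) != 1L || grid_step <= 0 || grid_step > 1e-3)
    stop("`grid_step` must lie in (0, 1e-3]")
  rho <- unique(c(seq(0, 1, by = grid_step), 1))
  co <- taylor_coefs(gamma)
  dev <- abs(beta_asymptotic(gamma, rho) - (co$value + co$slope * (rho - 0.5)))
  i <- which.max(dev)
  structure(list(gamma = gamma,
                 expansion_point = 0.5,
                 intercept_at_0 = co$value - 0.5 * co$slope,
                 slope = co$slope,
                 remainder_bound = remainder_bound(gamma),
                 max_observed_deviation = dev[i],
                 argmax_rho = rho[i]),
            class = "taylor_approximation")
}

#' @export
print.taylor_approximation <- function(x, ...) {
  cat(sprintf("Midpoint tangent of beta_gamma, gamma = %g\n", x$gamma))
  cat(sprintf("  T1(rho) = %.5f %+.5f * rho\n",
              x$intercept_at_0, x$slope))
  cat(sprintf("  max |beta - T1| = %.5f at rho = %g (bound gamma/8 = %.5f)\n",
              x$max_observed_deviation, x$argmax_rho, x$remainder_bound))
  invisible(x)
}
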