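#' Generate a synthetic cohort of tumor classifications
#'
#' Draws the benign count of an `n_patients` cohort from
#' `Binomial(n_patients, alpha(true_gamma))` — the data-generating process
#' the calibration assumes when the observed benign fraction is read as
#' the absorption probability at state `N`.  By default the asymptotic
#' absorption probability is used; supplying `finite_N` switches the
#' success probability to the exact finite-population value
#' [alpha_finite()] for sensitivity checks.
#'
#' @param true_gamma Nonnegative risk coefficient of the generating model.
#' @param n_patients Positive cohort size.
#' @param seed Integer seed; identical arguments give identical counts.
#' @param finite_N Optional population size; when given, the success
#'   probability is `alpha_finite(finite_N, true_gamma)`.
#' @return A [cohort_counts()] object with attribute `seed`.
#' @examples
#' generate_cohort(0.152, 66, seed = 1)
#' @export
generate_cohort <- function(true_gamma, n_patients, seed, finite_N = NULL) {
  if (n_patients < 1 || n_patients != round(n_patients))
    stop("`n_patients` must be a positive integer")
  p <- if (is.null(finite_N)) alpha_asymptotic(true_gamma)
       else alpha_finite(finite_N, true_gamma)
  set.seed(as.integer(seed))
  benign <- rbinom(1L, as.integer(n_patients), p)
  out <- cohort_counts(benign, n_patients - benign)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Parameter recovery across synthetic cohorts
#'
#' End-to-end check of the calibration loop: generates `n_cohorts`
#' independent cohorts at a known risk coefficient, calibrates each, and
#' summarizes the bias, spread and interval coverage of the recovered
#' estimates.  Degenerate cohorts with zero aggressive cases calibrate to
#' `gamma_hat = 0` and are kept (their `(0, 0)` interval cannot cover a
#' positive truth).
#'
#' @param true_gamma Positive generating risk coefficient.
#' @param n_patients Cohort size.
#' @param n_cohorts Number of cohorts (`>= 2`).
#' @param seed Master seed; one sub-seed is derived per cohort.
#' @return An object of class `"recovery_report"`: list with `true_gamma`,
#'   `n_cohorts`, `n_patients`, `mean_gamma_hat`, `sd_gamma_hat`,
#'   `coverage` (fraction of `+/- 1 SE` intervals containing the truth),
#'   and the vector `gamma_hats`.
#' @examples
#' parameter_recovery(0.152, n_patients = 1000, n_cohorts = 20, seed = 3)
#' @export
parameter_recovery <- function(true_gamma, n_patients, n_cohorts, seed) {
  if (n_cohorts < 2) stop("`n_cohorts` must be >= 2")
  seeds <- derive_seeds(seed, n_cohorts)
  gamma_hats <- numeric(n_cohorts)
  covered <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cohort <- generate_cohort(true_gamma, n_patients, seed = seeds[i])
    est <- estimate_fraction(cohort)
    gamma_hats[i] <- calibrate_gamma(est$p_hat)
    if (est$stderr == 0 || est$p_hat - est$stderr <= 0) {
      covered[i] <- FALSE
    } else {
      interval <- gamma_uncertainty(cohort)
      covered[i] <- interval[1] <= true_gamma && true_gamma <= interval[2]
    }
  }
  structure(list(true_gamma = true_gamma,
                 n_cohorts = as.integer(n_cohorts),
                 n_patients = as.integer(n_patients),
                 mean_gamma_hat = mean(gamma_hats),
                 sd_gamma_hat = sd(gamma_hats),
                 coverage = mean(covered),
                 gamma_hats = gamma_hats,
                 seed = as.integer(seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: true gamma = %g, %d cohorts of %d patients\n",
              x$true_gamma, x$n_cohorts, x$n_patients))
  cat(sprintf("  mean gamma_hat = %.4f (sd %.4f), 1-SE interval coverage %.2f\n",
              x$mean_gamma_hat, x$sd_gamma_hat, x$coverage))
  invisible(x)
}

#' Simulate outcomes of partially resected tumors
#'
#' Runs the `u = 0` sub-process from `k0` residual type-I cells `reps`
#' times and reports the empirical regression fraction (absorption at 0)
#' with its binomial standard error, alongside the full per-replicate
#' records.
#'
#' @param N Population size (critical cell number).
#' @param gamma Risk coefficient.
#' @param k0 Residual cell count, `0 < k0 < N`.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return List with `summary` (the [simulate_batch()] result),
#'   `regression_fraction`, `stderr`, and `outcomes` (the per-replicate
#'   data frame).
#' @examples
#' generate_resection_outcomes(50, 0.152, k0 = 25, reps = 500, seed = 2)$regression_fraction
#' @export
generate_resection_outcomes <- function(N, gamma, k0, reps, seed) {
  if (k0 <= 0 || k0 >= N) stop("`k0` must satisfy 0 < k0 < N")
  params <- tgp_params(N = N, gamma = gamma)
  sim <- simulate_batch(params, k0 = k0, reps = reps, seed = seed)
  list(summary = sim,
       regression_fraction = sim$fraction_0,
       stderr = sim$stderr_0,
       outcomes = sim$trajectories)
}
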