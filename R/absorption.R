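# Modified Bessel function of the first kind, integer order, by its power
# series sum_k (x/2)^(2k+n) / (k! (k+n)!).  Kept as an independent second
# route: the closed forms in this package all go through base besselI(),
# and the two evaluations are cross-checked in the test suite.
bessel_i_series <- function(x, nu, rel_tol = 1e-15, max_terms = 500L) {
  stopifnot(length(x) == 1L, is.finite(x), x >= 0, nu >= 0, nu == round(nu))
  term <- (x / 2)^nu / factorial(nu)
  total <- term
  for (k in seq_len(max_terms)) {
    term <- term * (x / 2)^2 / (k * (k + nu))
    total <- total + term
    if (term <= rel_tol * total) return(total)
  }
  stop("Bessel series failed to converge at x = ", x)
}

#' Exact absorption probabilities of the TGP sub-process
#'
#' First-step analysis of the `u = 0` sub-process on `{0, ..., N, E}`.
#' For each absorbing target (0, `N`, `E`) the hitting probabilities
#' `h(k)` satisfy the linear system
#' `h(k) = p_up(k) h(k+1) + p_down(k) h(k-1) + p_to_E(k) h(E)` with the
#' boundary condition 1 at the target and 0 at the other absorbing states.
#' The `(N-1) x (N-1)` tridiagonal systems are assembled sparsely and
#' solved with \pkg{Matrix}; this is algebraically the same solution a
#' determinant (Cramer) route would give, but numerically stable for
#' large `N`.
#'
#' @param params A [tgp_params()] object; `u` must satisfy `u*N < 1`
#'   (the single-lineage regime) and is treated as 0.
#' @return An object of class `"absorption_profile"`: list with `N`,
#'   `gamma`, and numeric vectors `hit_zero`, `hit_N`, `hit_E`, each of
#'   length `N + 1` indexed by the start state `k = 0..N`.
#' @examples
#' pr <- absorption_probs_finite(tgp_params(N = 10, gamma = 0.152))
#' pr$hit_zero[1]                      # start at k = 0: already extinct
#' pr$hit_N[2] + pr$hit_E[2] + pr$hit_zero[2]  # rows sum to one
#' @export
absorption_probs_finite <- function(params) {
  params <- as_tgp_params(params)
  check_decomposition_regime(params)
  N <- params$N; v <- params$v
  k <- seq_len(N - 1)
  rE <- k * v
  rUp <- k * (1 - v) * (N - k) / N
  rDown <- k * (N - k) / N
  tot <- rE + rUp + rDown
  pU <- rUp / tot; pD <- rDown / tot; pE <- rE / tot
  n <- N - 1L
  A <- if (n == 1L) Matrix::Matrix(1, 1, 1, sparse = TRUE)
       else Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                               diagonals = list(-pD[-1L], rep(1, n), -pU[-n]))
  solve_for <- function(b) as.numeric(Matrix::solve(A, b))
  h0 <- solve_for(c(pD[1L], rep(0, n - 1L)))
  hN <- solve_for(c(rep(0, n - 1L), pU[n]))
  hE <- solve_for(pE)
  bad <- abs(h0 + hN + hE - 1) > 1e-8
  if (any(bad))
    stop("absorption solve lost probability mass at k = ",
         paste(which(bad), collapse = ", "), " (max residual ",
         format(max(abs(h0 + hN + hE - 1))), ")")
  structure(list(N = N, gamma = params$gamma,
                 hit_zero = c(1, h0, 0),
                 hit_N = c(0, hN, 1),
                 hit_E = c(0, hE, 0)),
            class = "absorption_profile")
}

#' @export
print.absorption_profile <- function(x, ...) {
  cat(sprintf("Absorption profile: N = %d, gamma = %g\n", x$N, x$gamma))
  cat(sprintf("  from k = 1: P(0) = %.6f, P(N) = %.6f, P(E) = %.6f\n",
              x$hit_zero[2], x$hit_N[2], x$hit_E[2]))
  cat(sprintf("  conditional P(N | N or E) from k = 1: %.6f\n",
              x$hit_N[2] / (x$hit_N[2] + x$hit_E[2])))
  invisible(x)
}

#' Finite-N conditional absorption probability at state N
#'
#' Probability that a successful type-I mutant lineage (one that does not
#' simply go extinct) produces a benign PA-I tumor rather than an
#' aggressive PA-II tumor: `hit_N(1) / (hit_N(1) + hit_E(1))` from the
#' exact finite-`N` solve.  This is the finite-population analogue of
#' [alpha_asymptotic()] and converges to it as `N` grows.
#'
#' @param N Population size (integer `>= 2`).
#' @param gamma Nonnegative risk coefficient with `gamma / N^2 < 1`.
#' @return A probability in `[0, 1]`.
#' @examples
#' alpha_finite(100, 0.152)
#' alpha_asymptotic(0.152)
#' @export
alpha_finite <- function(N, gamma) {
  pr <- absorption_probs_finite(tgp_params(N = N, gamma = gamma))
  pr$hit_N[2] / (pr$hit_N[2] + pr$hit_E[2])
}

#' Asymptotic absorption probability at state N
#'
#' The large-`N` limit of the conditional absorption probability of the TGP
#' process in state `N`, `alpha(gamma) = 1 / I0(2*sqrt(gamma))`, with `I0`
#' the modified Bessel function of the first kind of order 0.  Strictly
#' decreasing in `gamma`, with `alpha(0) = 1`.  Evaluated with
#' exponentially scaled Bessel functions so large `gamma` cannot overflow.
#'
#' @param gamma Nonnegative risk coefficient (vectorized).
#' @return Probabilities in `(0, 1]`.
#' @examples
#' alpha_asymptotic(0.152)   # ~ 0.8636, the calibrated benign fraction
#' alpha_asymptotic(0)       # 1: no second hits possible
#' @export
alpha_asymptotic <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("`gamma` must be nonnegative")
  x <- 2 * sqrt(gamma)
  exp(-x) / besselI(x, 0, expon.scaled = TRUE)
}

#' Compare exact, simulated and asymptotic absorption probabilities
#'
#' For each population size in `N_list`, computes the conditional
#' absorption probability at `N` from a single mutant three ways: the exact
#' tridiagonal solve ([alpha_finite()]), a Monte-Carlo estimate from
#' [simulate_batch()] started at `k0 = 1` (fraction absorbed at `N` among
#' those absorbed at `N` or `E`), and the asymptotic closed form
#' ([alpha_asymptotic()]).
#'
#' @param N_list Integer vector of population sizes (`>= 2`).
#' @param gamma Risk coefficient.
#' @param reps Replicates per population size.
#' @param seed Master seed; one sub-seed is derived per population size.
#' @return A data frame with columns `N`, `alpha_exact`, `alpha_simulated`,
#'   `stderr` (binomial SE of the conditional estimate), `alpha_asymptotic`,
#'   `reps`.
#' @examples
#' compare_absorption(c(10, 50), gamma = 0.152, reps = 2000, seed = 7)
#' @export
compare_absorption <- function(N_list, gamma, reps, seed) {
  if (any(N_list < 2) || any(N_list != round(N_list)))
    stop("all entries of `N_list` must be integers >= 2")
  if (reps < 1) stop("`reps` must be >= 1")
  seeds <- derive_seeds(seed, length(N_list))
  rows <- lapply(seq_along(N_list), function(i) {
    N <- N_list[i]
    params <- tgp_params(N = N, gamma = gamma)
    sim <- simulate_batch(params, k0 = 1, reps = reps, seed = seeds[i])
    m <- round((sim$fraction_N + sim$fraction_E) * reps)
    a_sim <- if (m > 0) sim$fraction_N / (sim$fraction_N + sim$fraction_E) else NA_real_
    data.frame(N = as.integer(N),
               alpha_exact = alpha_finite(N, gamma),
               alpha_simulated = a_sim,
               stderr = if (m > 0) sqrt(a_sim * (1 - a_sim) / m) else NA_real_,
               alpha_asymptotic = alpha_asymptotic(gamma),
               reps = as.integer(reps))
  })
  do.call(rbind, rows)
}
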