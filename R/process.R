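#' Embedded one-step jump distribution of the TGP sub-process
#'
#' For a transient state with `k` type-I cells (0 < k < N) in the `u = 0`
#' sub-process, returns the probabilities of the three possible moves of the
#' embedded chain: one more type-I cell, one fewer, or absorption at `E`
#' (first type-II cell).  The underlying event rates are
#' `k*v` (to `E`), `k*(1-v)*(N-k)/N` (up) and `k*(N-k)/N` (down); each cell
#' reproduces at unit rate, the offspring of a type-I birth carries a second
#' hit with probability `v`, and otherwise the offspring replaces a
#' uniformly chosen cell.  Self-replacements are removed as self-loops.
#'
#' @param params A [tgp_params()] object (`u` plays no role here).
#' @param k Integer number of type-I cells, `1 <= k <= N-1`.
#' @return An object of class `"tgp_jump"`: list with `p_up`, `p_down`,
#'   `p_to_E` summing to 1.
#' @examples
#' jump_distribution(tgp_params(N = 2, v = 0.1), k = 1)
#' @export
jump_distribution <- function(params, k) {
  params <- as_tgp_params(params)
  N <- params$N; v <- params$v
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1 || k > N - 1)
    stop("`k` must be an integer in (0, N)")
  rE <- k * v
  rUp <- k * (1 - v) * (N - k) / N
  rDown <- k * (N - k) / N
  tot <- rE + rUp + rDown
  structure(list(p_up = rUp / tot, p_down = rDown / tot, p_to_E = rE / tot,
                 k = as.integer(k), N = N, v = v),
            class = "tgp_jump")
}

#' @export
print.tgp_jump <- function(x, ...) {
  cat(sprintf("Embedded jump distribution at k = %d (N = %d, v = %g)\n",
              x$k, x$N, x$v))
  cat(sprintf("  up %.6f | down %.6f | to E %.6f\n",
              x$p_up, x$p_down, x$p_to_E))
  invisible(x)
}

#' Simulate one trajectory of the TGP process
#'
#' Iterates the embedded jump chain from `k0` until absorption at 0, `N`
#' or `E`.  With `u > 0` the full process is emulated: whenever the count
#' hits 0 a fresh type-I mutant is injected (0 -> 1, one counted step), so
#' absorption can only occur at `N` or `E` — this is the decomposition of
#' the full process into successive single-mutant lineages.  With `u = 0`,
#' state 0 is absorbing (tumor extinction).
#'
#' @param params A [tgp_params()] object.
#' @param k0 Starting number of type-I cells in `[0, N]`.  `k0 = 0`
#'   requires `u > 0`.
#' @param seed Integer seed; identical `(params, k0, seed)` give identical
#'   outcomes.
#' @param step_cap Guard against non-termination; the simulator stops with
#'   an error after this many embedded jumps (default `1e9`).
#' @return An object of class `"tgp_trajectory"`: list with
#'   `absorbing_state` (one of `"0"`, `"N"`, `"E"`), `steps` (embedded
#'   jumps taken; 0 when started in an absorbing state), and `seed`.
#' @examples
#' simulate_trajectory(tgp_params(N = 20, gamma = 0.152), k0 = 1, seed = 42)
#' @export
simulate_trajectory <- function(params, k0, seed, step_cap = 1e9) {
  params <- as_tgp_params(params)
  if (length(k0) != 1L || k0 != round(k0) || k0 < 0 || k0 > params$N)
    stop("`k0` must be an integer in [0, N]")
  if (k0 == 0 && params$u <= 0)
    stop("starting at k0 = 0 requires u > 0 (state 0 is absorbing when u = 0)")
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  if (step_cap <= 0) stop("`step_cap` must be positive")
  set.seed(as.integer(seed))
  out <- tgp_run_trajectory_cpp(params$N, params$v, params$u,
                                as.integer(k0), as.numeric(step_cap))
  structure(list(absorbing_state = c("0", "N", "E")[out$code + 1L],
                 steps = out$steps, seed = as.integer(seed)),
            class = "tgp_trajectory")
}

# Per-replicate seed streams: the master seed seeds R's RNG once, from which
# one 31-bit seed per replicate is drawn; replicate i then runs on its own
# stream seeded with that value.  Documented in the README.
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n, replace = TRUE)
}

#' Simulate a batch of TGP trajectories
#'
#' Runs `reps` independent trajectories from `k0` and summarizes the
#' absorption fractions with binomial standard errors.  Reproducibility:
#' the master `seed` deterministically derives one sub-seed per replicate
#' (see README), so identical `(params, k0, reps, seed)` give bit-identical
#' results.
#'
#' @inheritParams simulate_trajectory
#' @param reps Positive number of replicates.
#' @return An object of class `"tgp_sim_summary"`: list with `reps`,
#'   `fraction_0`, `fraction_N`, `fraction_E`, the matching `stderr_*`
#'   (`sqrt(f*(1-f)/reps)`), the master `seed`, and `trajectories`, a
#'   data frame with columns `replicate`, `k0`, `absorbing_state`, `steps`,
#'   `seed` suitable for [write_trajectories()].
#' @examples
#' simulate_batch(tgp_params(N = 10, v = 0), k0 = 5, reps = 200, seed = 1)
#' @export
simulate_batch <- function(params, k0, reps, seed, step_cap = 1e9) {
  params <- as_tgp_params(params)
  if (length(reps) != 1L || !is.finite(reps) || reps < 1 || reps != round(reps))
    stop("`reps` must be a positive integer")
  reps <- as.integer(reps)
  if (k0 == 0 && params$u <= 0)
    stop("starting at k0 = 0 requires u > 0")
  rep_seeds <- derive_seeds(seed, reps)
  code <- integer(reps)
  steps <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    out <- tgp_run_trajectory_cpp(params$N, params$v, params$u,
                                  as.integer(k0), as.numeric(step_cap))
    code[i] <- out$code
    steps[i] <- out$steps
  }
  f <- tabulate(code + 1L, nbins = 3L) / reps
  se <- sqrt(f * (1 - f) / reps)
  structure(list(reps = reps,
                 fraction_0 = f[1], fraction_N = f[2], fraction_E = f[3],
                 stderr_0 = se[1], stderr_N = se[2], stderr_E = se[3],
                 seed = as.integer(seed),
                 trajectories = data.frame(
                   replicate = seq_len(reps),
                   k0 = as.integer(k0),
                   absorbing_state = c("0", "N", "E")[code + 1L],
                   steps = steps,
                   seed = rep_seeds)),
            class = "tgp_sim_summary")
}

#' @export
print.tgp_sim_summary <- function(x, ...) {
  cat(sprintf("TGP simulation summary (%d replicates, master seed %d)\n",
              x$reps, x$seed))
  cat(sprintf("  absorbed at 0: %.4f (SE %.4f)\n", x$fraction_0, x$stderr_0))
  cat(sprintf("  absorbed at N: %.4f (SE %.4f)\n", x$fraction_N, x$stderr_N))
  cat(sprintf("  absorbed at E: %.4f (SE %.4f)\n", x$fraction_E, x$stderr_E))
  invisible(x)
}

#' Export simulated trajectories as CSV
#'
#' Writes the per-replicate records of a [simulate_batch()] result
#' (`replicate`, `k0`, `absorbing_state`, `steps`, `seed`) to a CSV file.
#'
#' @param x A `"tgp_sim_summary"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  if (!inherits(x, "tgp_sim_summary"))
    stop("`x` must come from simulate_batch()")
  write.csv(x$trajectories, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
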