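test_that("jump distribution matches direct rate normalization", {
  # neutral symmetric case
  j0 <- jump_distribution(tgp_params(N = 2, v = 0), 1)
  expect_equal(j0$p_up, 0.5)
  expect_equal(j0$p_down, 0.5)
  expect_equal(j0$p_to_E, 0)
  # N = 2, v = 0.1: rates 0.45 (up), 0.5 (down), 0.1 (to E)
  j <- jump_distribution(tgp_params(N = 2, v = 0.1), 1)
  expect_equal(j$p_up, 0.45 / 1.05)
  expect_equal(j$p_down, 0.5 / 1.05)
  expect_equal(j$p_to_E, 0.1 / 1.05)
})

test_that("jump probabilities always sum to one and are neutral-symmetric at v = 0", {
  for (N in c(2, 5, 17, 120)) {
    for (v in c(0, 1e-6, 0.05, 0.6)) {
      p <- tgp_params(N = N, v = v)
      for (k in unique(c(1L, N %/% 2L, N - 1L))) {
        if (k < 1 || k > N - 1) next
        j <- jump_distribution(p, k)
        expect_equal(j$p_up + j$p_down + j$p_to_E, 1, tolerance = 1e-12)
        if (v == 0) {
          expect_identical(j$p_to_E, 0)
          expect_equal(j$p_up, 0.5)
        }
      }
    }
  }
  expect_error(jump_distribution(tgp_params(N = 10, v = 0.1), 0), "k")
  expect_error(jump_distribution(tgp_params(N = 10, v = 0.1), 10), "k")
})

test_that("trajectories are reproducible, terminate, and respect absorbing starts", {
  p <- tgp_params(N = 30, gamma = 0.152)
  t1 <- simulate_trajectory(p, k0 = 5, seed = 11)
  t2 <- simulate_trajectory(p, k0 = 5, seed = 11)
  expect_identical(t1, t2)
  expect_true(t1$absorbing_state %in% c("0", "N", "E"))
  expect_gte(t1$steps, 1)
  # start in an absorbing state
  t0 <- simulate_trajectory(tgp_params(N = 10, v = 0), k0 = 10, seed = 1)
  expect_identical(t0$absorbing_state, "N")
  expect_identical(t0$steps, 0)
  # v = 1 forbids upward moves: only extinction or progression possible
  for (s in 1:20) {
    tv <- simulate_trajectory(tgp_params(N = 5, v = 1 - 1e-12), k0 = 1, seed = s)
    expect_true(tv$absorbing_state %in% c("0", "E"))
  }
  # k0 = 0 needs u > 0, and with u > 0 absorption is at N or E only
  expect_error(simulate_trajectory(p, k0 = 0, seed = 1), "u > 0")
  tu <- simulate_trajectory(tgp_params(N = 10, gamma = 0.152, u = 0.01),
                            k0 = 0, seed = 7)
  expect_true(tu$absorbing_state %in% c("N", "E"))
})

test_that("a tight step cap fails loudly with a diagnostic", {
  p <- tgp_params(N = 100, v = 0)
  expect_error(simulate_trajectory(p, k0 = 50, seed = 1, step_cap = 5),
               "step cap")
})

test_that("neutral Moran extinction frequency matches 1 - k/N", {
  p <- tgp_params(N = 50, v = 0)
  s <- simulate_batch(p, k0 = 25, reps = 1e4, seed = 101)
  expect_equal(s$fraction_0 + s$fraction_N + s$fraction_E, 1)
  expect_identical(s$fraction_E, 0)               # v = 0 forbids E
  expect_lt(abs(s$fraction_0 - 0.5), 3 * s$stderr_0)
  expect_equal(s$stderr_0, sqrt(s$fraction_0 * (1 - s$fraction_0) / s$reps))
})

test_that("batches are bit-identical under a fixed master seed", {
  p <- tgp_params(N = 20, gamma = 0.3)
  a <- simulate_batch(p, k0 = 3, reps = 200, seed = 42)
  b <- simulate_batch(p, k0 = 3, reps = 200, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_batch(p, k0 = 3, reps = 0, seed = 1), "reps")
})

test_that("conditional Monte-Carlo absorption agrees with the exact solve", {
  N <- 100
  s <- simulate_batch(tgp_params(N = N, gamma = 0.152), k0 = 1,
                      reps = 1e4, seed = 2024)
  a_sim <- s$fraction_N / (s$fraction_N + s$fraction_E)
  m <- (s$fraction_N + s$fraction_E) * s$reps
  se <- sqrt(a_sim * (1 - a_sim) / m)
  expect_lt(abs(a_sim - alpha_finite(N, 0.152)), 3 * se)
})

test_that("trajectory batches export the documented CSV columns", {
  s <- simulate_batch(tgp_params(N = 10, gamma = 0.1), k0 = 2,
                      reps = 50, seed = 9)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectories(s, path)
  got <- read.csv(path)
  expect_identical(names(got),
                   c("replicate", "k0", "absorbing_state", "steps", "seed"))
  expect_identical(nrow(got), 50L)
})
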