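test_that("N = 2 absorption probabilities match one-step enumeration", {
  v <- 0.1
  pr <- absorption_probs_finite(tgp_params(N = 2, v = v))
  expect_equal(pr$hit_zero[2], (1 / 2) / (1 + v / 2), tolerance = 1e-12)
  expect_equal(pr$hit_E[2], v / (1 + v / 2), tolerance = 1e-12)
  expect_equal(pr$hit_N[2], ((1 - v) / 2) / (1 + v / 2), tolerance = 1e-12)
  # neutral case
  pr0 <- absorption_probs_finite(tgp_params(N = 2, v = 0))
  expect_equal(pr0$hit_zero[2], 0.5)
  expect_equal(pr0$hit_N[2], 0.5)
  expect_identical(pr0$hit_E[2], 0)
})

test_that("tridiagonal solve matches the brute-force fixed-point oracle", {
  for (N in 2:6) {
    for (v in c(0, 1e-4, 0.05, 0.4)) {
      pr <- absorption_probs_finite(tgp_params(N = N, v = v))
      expect_equal(pr$hit_zero, oracle_absorption(N, v, "zero"),
                   tolerance = 1e-10)
      expect_equal(pr$hit_N, oracle_absorption(N, v, "N"), tolerance = 1e-10)
      expect_equal(pr$hit_E, oracle_absorption(N, v, "E"), tolerance = 1e-10)
    }
  }
})

test_that("absorption profiles conserve probability and are monotone in k", {
  for (gamma in c(0, 0.152, 2)) {
    pr <- absorption_probs_finite(tgp_params(N = 40, gamma = gamma))
    expect_equal(pr$hit_zero + pr$hit_N + pr$hit_E, rep(1, 41),
                 tolerance = 1e-10)
    expect_identical(pr$hit_zero[1], 1)
    expect_identical(pr$hit_N[41], 1)
    expect_true(all(diff(pr$hit_N) >= -1e-12))
    expect_true(all(diff(pr$hit_zero) <= 1e-12))
  }
})

test_that("finite-N conditional absorption has its N = 2 closed form and neutral limit", {
  for (g in c(0.04, 0.4, 2)) {
    v <- g / 4
    expect_equal(alpha_finite(2, g), (1 - v) / (1 + v), tolerance = 1e-12)
  }
  expect_equal(alpha_finite(25, 0), 1)
})

test_that("asymptotic absorption probability evaluates the Bessel closed form", {
  expect_lt(abs(alpha_asymptotic(0.152) - 57 / 66), 1e-4)
  expect_identical(alpha_asymptotic(0), 1)
  expect_equal(round(alpha_asymptotic(1), 4), 0.4387)  # 1/I0(2)
  expect_error(alpha_asymptotic(-0.1), "nonnegative")
  # strictly decreasing on a gamma grid
  a <- alpha_asymptotic(seq(0, 10, by = 0.1))
  expect_true(all(diff(a) < 0))
})

test_that("library Bessel evaluation agrees with the power-series route", {
  for (x in c(0, 0.1, 0.5514, 0.7797, 2, 14)) {
    for (nu in 0:2) {
      expect_equal(besselI(x, nu), patgp:::bessel_i_series(x, nu),
                   tolerance = 1e-13)
    }
  }
})

test_that("finite-N absorption converges to the asymptotic closed form", {
  Ns <- c(10, 100, 1000)
  for (g in c(0.05, 0.152, 0.5, 1)) {
    err <- abs(vapply(Ns, alpha_finite, 0, gamma = g) - alpha_asymptotic(g))
    expect_true(all(diff(err) < 0))          # error shrinks with N
  }
  expect_lt(abs(alpha_finite(1000, 0.152) - alpha_asymptotic(0.152)), 0.005)
})

test_that("the three-way absorption comparison is internally consistent", {
  tab <- compare_absorption(c(10, 50, 100), gamma = 0.152, reps = 1e4,
                            seed = 31)
  expect_identical(nrow(tab), 3L)
  expect_true(all(abs(tab$alpha_simulated - tab$alpha_exact) <
                    3 * tab$stderr))
  expect_true(all(tab$alpha_exact >= 0 & tab$alpha_exact <= 1))
  # gamma = 0: all three routes give certainty of the benign outcome
  tab0 <- compare_absorption(c(5, 20), gamma = 0, reps = 100, seed = 1)
  expect_equal(tab0$alpha_exact, c(1, 1))
  expect_equal(tab0$alpha_simulated, c(1, 1))
  expect_equal(tab0$alpha_asymptotic, c(1, 1))
})
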