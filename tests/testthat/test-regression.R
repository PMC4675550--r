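test_that("regression function hits its endpoints and tabulated value", {
  for (g in c(0.01, 0.152, 1, 50)) {
    expect_equal(beta_asymptotic(g, 0), 1, tolerance = 1e-12)
    expect_equal(beta_asymptotic(g, 1), 0, tolerance = 1e-12)
  }
  expect_equal(beta_asymptotic(0.152, 1 / 9), 0.8816, tolerance = 5e-5)
  expect_error(beta_asymptotic(0.152, 1.2), "rho")
  expect_error(beta_asymptotic(-1, 0.5), "gamma")
})

test_that("regression function is monotone in rho and in gamma", {
  rho <- seq(0, 1, by = 0.01)
  prev <- NULL
  for (g in c(0.01, 0.152, 1, 50)) {
    b <- beta_asymptotic(g, rho)
    expect_true(all(diff(b) < 0))
    if (!is.null(prev)) {
      mid <- rho > 0 & rho < 1
      expect_true(all(b[mid] < prev[mid]))   # larger risk, lower curves
    }
    prev <- b
  }
})

test_that("neutral limit recovers the linear Moran extinction probability", {
  rho <- c(0, 0.2, 0.5, 0.9, 1)
  expect_equal(beta_asymptotic(1e-8, rho), 1 - rho, tolerance = 1e-6)
  expect_equal(beta_asymptotic(0, rho), 1 - rho)
  expect_equal(beta_finite(40, 0, seq(0, 40, by = 5)),
               1 - seq(0, 40, by = 5) / 40, tolerance = 1e-10)
})

test_that("finite-N extinction matches enumeration at N = 2 and converges in N", {
  for (g in c(0.04, 0.4, 2)) {
    v <- g / 4
    expect_equal(beta_finite(2, g, 1), 1 / (2 + v), tolerance = 1e-12)
  }
  for (rho in c(1 / 9, 0.5, 8 / 9)) {
    err <- vapply(c(50, 500, 2000), function(N) {
      abs(beta_finite(N, 0.152, round(rho * N)) - beta_asymptotic(0.152, rho))
    }, 0)
    expect_true(all(diff(err) < 0))
  }
  expect_lt(abs(beta_finite(2000, 0.152, round(2000 / 9)) -
                  beta_asymptotic(0.152, 1 / 9)), 0.01)
  expect_error(beta_finite(10, 0.1, 11), "k")
})

test_that("empirical extinction frequency matches the exact solve", {
  s <- simulate_batch(tgp_params(N = 200, gamma = 0.152), k0 = 100,
                      reps = 1e4, seed = 77)
  expect_lt(abs(s$fraction_0 - beta_finite(200, 0.152, 100)),
            3 * s$stderr_0)
})

test_that("midpoint tangent has the closed-form value and slope", {
  expect_equal(taylor_t1(0.152, 0.5), 0.4817, tolerance = 5e-5)
  co <- patgp:::taylor_coefs(0.152)
  expect_equal(co$slope, -0.9995, tolerance = 5e-5)
  # derivative cross-checked against central finite differences
  for (g in c(0.05, 0.152, 1, 5)) {
    fd <- fd_derivative(function(r) beta_asymptotic(g, r), 0.5)
    expect_equal(patgp:::taylor_coefs(g)$slope, fd, tolerance = 1e-6)
  }
  # neutral limit: T1 becomes exactly 1 - rho
  expect_equal(taylor_t1(1e-12, c(0, 0.3, 1)), 1 - c(0, 0.3, 1))
})

test_that("Taylor remainder: observed supremum respects the gamma/8 bound", {
  expect_equal(remainder_bound(0.152), 0.019)
  expect_identical(remainder_bound(0), 0)
  for (g in c(0.05, 0.152, 0.5, 1)) {
    ta <- max_taylor_deviation(g, grid_step = 1e-4)
    expect_lte(ta$max_observed_deviation, ta$remainder_bound + 1e-9)
  }
  ta <- max_taylor_deviation(0.152)
  expect_equal(round(ta$max_observed_deviation, 4), 0.0185)
  expect_identical(ta$argmax_rho, 0)           # extremum at full resection
  # essentially linear already in the near-neutral regime
  expect_lt(max_taylor_deviation(1e-8, 1e-3)$max_observed_deviation, 1e-8)
  expect_error(max_taylor_deviation(0.152, grid_step = 0.1), "grid_step")
})
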