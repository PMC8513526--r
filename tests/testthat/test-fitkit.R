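test_that("Boltzmann evaluation satisfies its analytic identities", {
  expect_equal(boltzmann_eval(-65, 8, -65, 6), 4)
  expect_equal(boltzmann_eval(-65 + 6, 8, -65, 6), 8 / (1 + exp(1)))
  expect_equal(boltzmann_eval(-1e4, 8, -65, 6), 8, tolerance = 1e-12)
  expect_equal(boltzmann_eval(1e4, 8, -65, 6), 0, tolerance = 1e-12)
  v <- seq(-140, -20, by = 5)
  expect_false(is.unsorted(rev(boltzmann_eval(v, 8, -65, 6))))
  expect_error(boltzmann_eval(-65, 8, -65, 0), "k must be")
})

test_that("recovery evaluation satisfies its analytic identities", {
  # boundary: tip = 0 leaves only the unmodulated fraction
  expect_equal(recovery_eval(0, 10, 0.5, 0.2, 0.3, tau1 = 3, tau2 = 200),
               3)
  # single exponential special case at tip = tau1
  expect_equal(recovery_eval(3, 10, 1, 0, 0, tau1 = 3, tau2 = 200),
               10 * (1 - exp(-1)), tolerance = 1e-9)
  # normalization limit: full recovery at long intervals
  expect_equal(recovery_eval(1e6, 10, 0.6, 0.3, 0.1, tau1 = 3, tau2 = 200),
               10, tolerance = 1e-9)
  # non-decreasing in tip
  tip <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128, 498)
  y <- recovery_eval(tip, 10, 0.7, 0.2, 0.1, tau1 = 5, tau2 = 150, x = 2)
  expect_false(is.unsorted(y))
  expect_error(recovery_eval(1, 10, 0.9, 0.3, 0, tau1 = 3, tau2 = 200),
               "equal 1")
  expect_error(recovery_eval(1, 10, 0.9, 0.1, 0, tau1 = 300, tau2 = 200),
               "smaller")
})

test_that("the extended equation nests the plain bi-exponential exactly", {
  tip <- c(0.3, 1, 2, 4, 8, 16, 32, 64, 498, 1000)
  for (a1 in c(0.2, 0.9)) {
    biexp <- recovery_eval(tip, 7, a1, 1 - a1, 0, tau1 = 4, tau2 = 250,
                           x = 1)
    manual <- 7 * (a1 * (1 - exp(-tip / 4)) +
                     (1 - a1) * (1 - exp(-tip / 250)))
    expect_identical(biexp, manual)
  }
})

test_that("RMSE and relative error implement their definitions", {
  expect_equal(rmse_percent(c(1, 2, 3), c(1, 2, 3), 10), 0)
  expect_equal(rmse_percent(c(10.3, 9.6), c(10, 10), 10),
               sqrt(0.125) / 10 * 100)
  # homogeneity: doubling residuals doubles the error
  a <- c(5, 6, 7); b <- c(5.2, 5.9, 7.3)
  expect_equal(rmse_percent(a, a + 2 * (b - a), 10),
               2 * rmse_percent(a, b, 10))
  expect_error(rmse_percent(1:3, 1:3, 0), "non-zero")
  expect_equal(relative_error(c(2, 4), c(1, 4)), c(0.5, 0))
  expect_equal(relative_error(c(0, 2), c(1, 1)), c(NA, 0.5))
})

test_that("fixed slow time constant is the supervised mean, band-checked", {
  expect_equal(fixed_tau2_from_supervised(c(150, 250)), 200)
  expect_equal(fixed_tau2_from_supervised(350), 350)
  expect_warning(out <- fixed_tau2_from_supervised(c(50)), "100-400")
  expect_equal(out, 50)
  expect_error(fixed_tau2_from_supervised(numeric(0)), "no supervised")
})

test_that("noiseless Boltzmann points are recovered to numerical precision", {
  v <- c(-130, -110, -100, -90, -80, -70)
  I <- boltzmann_eval(v, 8, -65, 6)
  f <- fit_boltzmann(v, I)
  expect_true(f$diagnostics$converged)
  expect_equal(f$params$imax, 8, tolerance = 1e-6)
  expect_equal(f$params$v_half, -65, tolerance = 1e-6)
  expect_equal(f$params$k, 6, tolerance = 1e-6)
  expect_equal(f$diagnostics$rmse_pct, 0, tolerance = 1e-6)
  expect_error(fit_boltzmann(c(-100, -80), c(5, 2)), "4 distinct")
})

test_that("noiseless bi-exponential recovery data are recovered exactly", {
  tip <- c(1, 2, 4, 8, 16, 32, 64, 498)
  I <- recovery_eval(tip, 9, 0.9, 0.1, 0, tau1 = 3, tau2 = 200)
  f <- fit_recovery(tip, I, "biexp")
  expect_equal(f$params$a1, 0.9, tolerance = 1e-5)
  expect_equal(f$params$tau1, 3, tolerance = 1e-4)
  expect_equal(f$params$tau2, 200, tolerance = 1e-2)
  expect_lt(f$diagnostics$rmse_pct, 1e-6)
  # constraint contract: returned taus are ordered even from a bad start
  f2 <- fit_recovery(tip, I, "biexp",
                     init = list(imax = 9, a1 = 0.1, tau1 = 300,
                                 tau2 = 2))
  expect_lt(f2$params$tau1, f2$params$tau2)
  expect_equal(f2$params$tau1, 3, tolerance = 1e-3)
})

test_that("constrained fits match the brute-force grid oracle", {
  # Boltzmann on 5 noisy datasets
  withr::with_seed(21, {
    for (i in 1:5) {
      truth <- list(imax = runif(1, 4, 10), v_half = runif(1, -90, -50),
                    k = runif(1, 4, 9))
      v <- c(-130, -110, -100, -90, -80, -70)
      I <- pmax(boltzmann_eval(v, truth$imax, truth$v_half, truth$k) +
                  rnorm(6, 0, 0.02 * truth$imax), 0)
      f <- fit_boltzmann(v, I)
      o <- grid_oracle_boltzmann(I = I, Vp = v,
                                 v_half_grid = seq(-120, -40, by = 0.25),
                                 k_grid = seq(2, 12, by = 0.1))
      # the constrained fit is at least as good as the dense grid optimum
      ssq_fit <- sum((boltzmann_eval(v, f$params$imax, f$params$v_half,
                                     f$params$k) - I)^2)
      expect_lte(ssq_fit, o$ssq * (1 + 1e-6) + 1e-12)
      expect_equal(f$params$v_half, o$v_half, tolerance = 0.5)
      expect_equal(f$params$k, o$k, tolerance = 0.2)
    }
  })
  # bi-exponential on 5 noisy datasets
  withr::with_seed(22, {
    tip <- c(1, 2, 4, 8, 16, 32, 64, 498)
    for (i in 1:5) {
      truth <- list(imax = runif(1, 5, 10), a1 = runif(1, 0.6, 0.95),
                    tau1 = runif(1, 2, 8), tau2 = runif(1, 120, 300))
      I <- pmax(recovery_eval(tip, truth$imax, truth$a1, 1 - truth$a1, 0,
                              tau1 = truth$tau1, tau2 = truth$tau2) +
                  rnorm(8, 0, 0.02 * truth$imax), 0)
      f <- fit_recovery(tip, I, "biexp")
      o <- grid_oracle_biexp(tip, I,
                             tau1_grid = exp(seq(log(0.5), log(20),
                                                 length.out = 80)),
                             tau2_grid = exp(seq(log(50), log(600),
                                                 length.out = 80)))
      q <- f$params
      ssq_fit <- sum((recovery_eval(tip, q$imax, q$a1, q$a2, q$a3,
                                    tau1 = q$tau1, tau2 = q$tau2,
                                    x = q$x) - I)^2)
      expect_lte(ssq_fit, o$ssq * (1 + 1e-6) + 1e-12)
      expect_equal(q$tau1, o$tau1, tolerance = 0.15 * o$tau1)
      expect_equal(q$a1, o$a1, tolerance = 0.05)
    }
  })
})

test_that("stepwise extension selects the generating model class", {
  tip <- c(1, 2, 4, 8, 16, 32, 64, 498)
  # clean bi-exponential data: no extension needed
  I <- recovery_eval(tip, 9, 0.9, 0.1, 0, tau1 = 3, tau2 = 200)
  sw <- stepwise_extension(tip, I, fixed_tau2 = 200)
  expect_equal(sw$selected, "biexp_fixed_tau2")
  expect_length(sw$steps, 1)
  # extended data with a free unmodulated fraction (x = 1)
  I2 <- recovery_eval(tip, 9, 0.5, 0.2, 0.3, tau1 = 24, tau2 = 200, x = 1)
  sw2 <- stepwise_extension(tip, I2, fixed_tau2 = 200)
  expect_equal(sw2$selected, "ext_A3")
  expect_equal(sw2$fit$params$a3, 0.3, tolerance = 0.02)
  # steeper-than-exponential data (x = 2, little unmodulated fraction, so
  # freeing A3 alone cannot absorb the steepness): full extension
  I3 <- recovery_eval(tip, 9, 0.9, 0.05, 0.05, tau1 = 16, tau2 = 200,
                      x = 2)
  sw3 <- stepwise_extension(tip, I3, fixed_tau2 = 200)
  expect_equal(sw3$selected, "ext_A3_x")
  rmses <- vapply(sw3$steps, function(s) s$diagnostics$rmse_pct, 1)
  expect_length(rmses, 3)
  expect_false(is.unsorted(rev(rmses)))   # non-increasing along the steps
  expect_lt(rmses[3], 0.01)
  # the exponent-free fit flags tau1 as non-comparable
  expect_false(sw3$fit$diagnostics$tau1_comparable)
  expect_true(sw$fit$diagnostics$tau1_comparable)
})

test_that("model nesting never worsens the fit on random datasets", {
  withr::with_seed(33, {
    tip <- c(1, 2, 4, 8, 16, 32, 64, 498)
    for (i in 1:8) {
      a1 <- runif(1, 0.3, 0.9); a3 <- runif(1, 0, min(0.3, 1 - a1))
      I <- pmax(recovery_eval(tip, runif(1, 4, 10), a1, 1 - a1 - a3, a3,
                              tau1 = runif(1, 2, 25),
                              tau2 = runif(1, 120, 300),
                              x = runif(1, 1, 2.5)) + rnorm(8, 0, 0.1), 0)
      f1 <- fit_recovery(tip, I, "biexp")
      f2 <- fit_recovery(tip, I, "ext_A3", init = f1$params)
      f3 <- fit_recovery(tip, I, "ext_A3_x", init = f2$params)
      expect_lte(f2$diagnostics$rmse_pct,
                 f1$diagnostics$rmse_pct + 1e-8)
      expect_lte(f3$diagnostics$rmse_pct,
                 f2$diagnostics$rmse_pct + 1e-8)
    }
  })
})

test_that("the smallest-amplitude points dominate the relative error", {
  tip <- c(1, 2, 4, 8, 16, 32, 64, 498)
  withr::with_seed(7, {
    I <- recovery_eval(tip, 9, 0.9, 0.1, 0, tau1 = 3, tau2 = 200) +
      rnorm(8, 0, 0.05)
  })
  f <- fit_recovery(tip, I, "biexp")
  er <- f$diagnostics$erel
  # the shortest intervals (smallest currents) carry the largest Erel
  expect_gt(mean(er[tip <= 2]), mean(er[tip >= 64]))
})
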