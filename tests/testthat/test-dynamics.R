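sim_one <- function(drugs = list(), schedule = short_schedule(),
                    noise = 0.05, seed = 11, cell = NULL) {
  p <- ref_protocol()
  if (is.null(cell)) cell <- cell_ensemble_spec(noise_sd_nA = noise)
  sim <- simulate_experiment(p, schedule, drugs, list(cell),
                             seed = seed)[[1]]
  list(protocol = p, sim = sim, cell = cell, schedule = schedule)
}

test_that("control experiments track flat parameters at the truth", {
  s <- sim_one()
  ser <- sweepwise_parameters(s$sim$amplitudes, s$protocol)
  expect_equal(nrow(ser), nrow(s$sim$amplitudes$amplitudes))
  expect_true(all(ser$converged_ssi))
  vh <- ser$v_half
  expect_lt(abs(mean(vh) - s$cell$control_v_half_mV), 1)
  expect_lt(diff(range(vh)), 6 * sd(vh) + 1e-9)  # flat within noise
})

test_that("lidocaine-like tracking shows the A1 -> A2 redistribution", {
  sch <- short_schedule("lido", 300)
  s <- sim_one(list(lidocaine_like_spec(300, name = "lido")),
               schedule = sch)
  ser <- sweepwise_parameters(s$sim$amplitudes, s$protocol)
  tr <- s$sim$truth
  ctl <- 31:40; plateau <- 71:80; washed <- 111:120
  # A1 falls during application and recovers on washout
  expect_lt(mean(ser$a1[plateau]), mean(ser$a1[ctl]) - 0.2)
  expect_gt(mean(ser$a1[washed]), mean(ser$a1[plateau]) + 0.1)
  # recovered A1 matches the generator truth
  expect_lt(abs(mean(ser$a1[plateau]) - mean(tr$a1[plateau])), 0.05)
  # V1/2 plateau shift matches the programmed shift within 1 mV
  shift_fit <- mean(ser$v_half[plateau]) - mean(ser$v_half[ctl])
  shift_true <- mean(tr$v_half[plateau]) - mean(tr$v_half[ctl])
  expect_lt(abs(shift_fit - shift_true), 1)
  # fitted tau2 stays at its fixed value (the lidocaine-like signature
  # leaves the slow time constant untouched)
  expect_equal(unique(ser$tau2[!ser$flagged]), 200)
})

test_that("riluzole-like tracking shows tau1 slowing at preserved split", {
  sch <- short_schedule("rilu", 100)
  s <- sim_one(list(riluzole_like_spec(100, name = "rilu")),
               schedule = sch)
  cfg <- sweepwise_config(rfi_model = "stepwise")
  ser <- sweepwise_parameters(s$sim$amplitudes, s$protocol, cfg)
  tr <- s$sim$truth
  ctl <- 31:40; plateau <- 71:80
  fold_fit <- mean(ser$tau1[plateau]) / mean(ser$tau1[ctl])
  fold_true <- mean(tr$tau1[plateau]) / mean(tr$tau1[ctl])
  expect_gt(fold_fit, 2)                       # marked slowing
  expect_lt(abs(fold_fit / fold_true - 1), 0.25)
  # the fast fraction is not redistributed into the slow one
  expect_gt(mean(ser$a1[plateau] + ser$a3[plateau]), 0.75)
})

test_that("endpoint averages reduce noise as 1/sqrt(n)", {
  sch <- short_schedule("lido", 300)
  s <- sim_one(list(lidocaine_like_spec(300, name = "lido")),
               schedule = sch, seed = 13)
  ep <- endpoint_average(s$sim$amplitudes, sch, n = 3)
  expect_equal(nrow(ep), 2)     # one window, pre + end
  expect_setequal(ep$phase, c("pre", "end"))
  # averaged pre-window values sit near the noiseless control amplitudes
  pc <- napdyn:::control_parameters(s$cell)
  a_true <- sweep_amplitudes(s$protocol, pc, s$cell)
  pre <- as.numeric(ep[ep$phase == "pre", sprintf("p%02d", 1:17)])
  expect_lt(max(abs(pre - a_true)),
            4 * s$cell$noise_sd_nA / sqrt(3) + 0.02 * max(abs(a_true)))
  # n = 1 picks the single boundary sweeps
  ep1 <- endpoint_average(s$sim$amplitudes, sch, n = 1)
  amp <- s$sim$amplitudes$amplitudes
  expect_equal(as.numeric(ep1[ep1$phase == "pre", sprintf("p%02d", 1:17)]),
               unname(amp[40, ]))
  # constant matrix: averages equal the constant
  m <- amplitude_matrix(matrix(-4, 120, 17), t0_s = 0:119)
  epc <- endpoint_average(m, sch, n = 3)
  expect_true(all(epc[, sprintf("p%02d", 1:17)] == -4))
  # windows shorter than n sweeps are refused
  tiny <- napdyn:::new_schedule(
    data.frame(label = c("control", "d"), concentration = c(0, 10),
               unit = "uM", start_s = c(0, 1), duration_s = c(1, 2)),
    repetitions = 1L)
  expect_error(endpoint_average(s$sim$amplitudes, tiny, n = 3),
               "fewer than")
})

test_that("macro time constants are recovered from relaxation series", {
  # exact round trip on a noiseless first-order series
  t <- 0:39
  y <- 5 + (10 - 5) * exp(-t / 10)
  mk <- macro_time_constants(t, y, window_start_s = 0,
                             window_duration_s = 40)
  expect_equal(mk$onset_tau_s, 10, tolerance = 1e-6)
  expect_equal(mk$onset_plateau, 5, tolerance = 1e-6)
  # 2 % noise over 40 samples: within 15 % across seeds
  errs <- vapply(1:10, function(s) {
    yn <- withr::with_seed(s, y + rnorm(40, 0, 0.02 * 10))
    m <- macro_time_constants(t, yn, 0, 40)
    abs(m$onset_tau_s / 10 - 1)
  }, numeric(1))
  expect_lt(stats::quantile(errs, 0.9), 0.15)
  # flat series: flagged undefined, not fitted
  mkf <- macro_time_constants(t, rep(3, 40), 0, 40)
  expect_true(is.na(mkf$onset_tau_s))
  expect_true("flat_series" %in% mkf$flags)
})

test_that("per-pulse macro-kinetics reflect the membrane time constants", {
  sch <- short_schedule("lido", 300, lead = 40, app = 60, wash = 60)
  drug <- lidocaine_like_spec(300, name = "lido")
  s <- sim_one(list(drug), schedule = sch, noise = 0.02)
  mk <- macro_kinetics_by_pulse(s$sim$amplitudes, sch, pulses = c(7, 17))
  expect_equal(nrow(mk), 2)
  # onset is governed by tau_on, offset by tau_off, loosely (the observed
  # relaxation follows the saturating effect, not concentration, exactly)
  expect_true(all(is.finite(mk$onset_tau_s)))
  expect_lt(abs(mk$onset_tau_s[1] - drug$tau_on_s), drug$tau_on_s)
  expect_lt(abs(mk$offset_tau_s[1] - drug$tau_off_s), drug$tau_off_s)
})

test_that("the 17/12 amplitude ratio flags availability drift", {
  # stable synthetic cell: flat ratio near its control value
  s <- sim_one(noise = 0.02)
  sm <- shift_monitor(s$sim$amplitudes)
  expect_equal(nrow(sm), 120)
  expect_false(any(sm$flagged))
  expect_lt(sd(sm$ratio), 0.02)
  # a drifting V1/2 in the generator depresses the ratio monotonically
  p <- ref_protocol()
  cell <- quiet_cell(seal_drift_frac = 0)
  amps <- t(vapply(seq(0, 25, length.out = 50), function(dv) {
    pc <- napdyn:::control_parameters(cell)
    pc$v_half <- pc$v_half - dv
    sweep_amplitudes(p, pc, cell)
  }, numeric(17)))
  m <- amplitude_matrix(amps, t0_s = 0:49)
  smd <- shift_monitor(m)
  expect_false(is.unsorted(rev(smd$ratio)))
  # near-zero denominators are flagged, not divided
  amps[50, 12] <- 1e-6
  m2 <- amplitude_matrix(amps, t0_s = 0:49)
  sm2 <- shift_monitor(m2)
  expect_true(sm2$flagged[50])
  expect_true(is.na(sm2$ratio[50]))
})

test_that("repetition internal control detects incomplete recovery", {
  p <- ref_protocol()
  # fast washout: repetitions agree, no flags
  sch <- two_rep_schedule("lido", 300)
  fast <- lidocaine_like_spec(300, name = "lido")
  sim <- simulate_experiment(p, sch, list(fast),
                             list(cell_ensemble_spec(noise_sd_nA = 0.03,
                                                     seal_drift_frac = 0)),
                             seed = 4)[[1]]
  ef <- endpoint_fits(sim$amplitudes, p, sch)
  rc <- repeat_consistency(ef)
  expect_true(rc$available)
  expect_false(any(rc$baseline_flags$incomplete_recovery))
  expect_lt(abs(rc$differences$d_v_half), 1.5)
  # slow washout (tau_off >> wash): baseline deviates, flag raised
  slow <- drug_kinetics_spec("lido", 300, tau_on_s = 4, tau_off_s = 400,
                             potency_uM = 300, tonic_block_max = 0.5,
                             max_shift_mV = 20)
  sim2 <- simulate_experiment(p, sch, list(slow),
                              list(cell_ensemble_spec(noise_sd_nA = 0.03,
                                                      seal_drift_frac = 0)),
                              seed = 4)[[1]]
  ef2 <- endpoint_fits(sim2$amplitudes, p, sch)
  rc2 <- repeat_consistency(ef2)
  expect_true(any(rc2$baseline_flags$incomplete_recovery))
  # an infinite tolerance never flags
  rc3 <- repeat_consistency(ef2, amplitude_tol_frac = Inf,
                            v_half_tol_mV = Inf)
  expect_false(any(rc3$baseline_flags$incomplete_recovery))
  # single repetition: report marked unavailable
  ef1 <- ef[ef$repetition <= 1, ]
  expect_false(repeat_consistency(ef1)$available)
})
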