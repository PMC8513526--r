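test_that("membrane concentration follows first-order wash-in/wash-out", {
  sch <- short_schedule(conc = 100, lead = 40, app = 400, wash = 40)
  sp <- drug_kinetics_spec("drugA", 100, tau_on_s = 5, tau_off_s = 8)
  # long application approaches the aqueous concentration
  expect_equal(membrane_concentration(sch, sp, 439), 100, tolerance = 1e-6)
  # one tau_on into the application: 1 - exp(-1) of the target
  expect_equal(membrane_concentration(sch, sp, 45), 100 * (1 - exp(-1)),
               tolerance = 1e-9)
  # before any application: zero
  expect_equal(membrane_concentration(sch, sp, c(0, 10, 39.9)), rep(0, 3))
  # a compound absent from the schedule never builds up
  other <- drug_kinetics_spec("unscheduled", 50)
  expect_equal(membrane_concentration(sch, other, seq(0, 400, by = 25)),
               rep(0, 17))
  expect_error(membrane_concentration(sch, sp, -1), ">= 0")
})

test_that("membrane concentration is continuous and bounded", {
  sch <- two_rep_schedule(conc = 80)
  sp <- drug_kinetics_spec("drugA", 80, tau_on_s = 4, tau_off_s = 12)
  t <- seq(0, schedule_duration_s(sch), by = 0.1)
  cm <- membrane_concentration(sch, sp, t)
  expect_true(all(cm >= 0 & cm <= 80 + 1e-9))
  # no jump anywhere exceeds what the fastest time constant allows
  expect_true(max(abs(diff(cm))) < 80 * 0.1 / 4 + 1e-6)
})

test_that("modulated parameters interpolate saturating from control", {
  cell <- cell_ensemble_spec()
  sp <- drug_kinetics_spec("d", 100, potency_uM = 50, max_shift_mV = 20,
                           tau1_multiplier_max = 8,
                           a1_suppression_max = 0.5,
                           tonic_block_max = 0.4,
                           unmodulated_fraction_max = 0.3,
                           exponent_x_max = 2)
  p0 <- modulated_parameters(0, sp, cell)
  expect_equal(p0$v_half, cell$control_v_half_mV)
  expect_equal(p0$tau1, cell$control_tau1_ms)
  expect_equal(p0$a1, cell$control_a1)
  expect_equal(p0$a3, 0)
  expect_equal(p0$tonic_block, 0)
  # at the half-effect concentration every effect is half-maximal
  ph <- modulated_parameters(50, sp, cell)
  expect_equal(ph$v_half, cell$control_v_half_mV - 10)
  expect_equal(ph$tau1, cell$control_tau1_ms * (1 + 0.5 * 7))
  # saturation limit
  ps <- modulated_parameters(1e9, sp, cell)
  expect_equal(ps$tau1, cell$control_tau1_ms * 8, tolerance = 1e-6)
  expect_equal(ps$v_half, cell$control_v_half_mV - 20, tolerance = 1e-5)
})

test_that("sweep amplitudes evaluate the availability equations per role", {
  p <- ref_protocol()
  cell <- quiet_cell()
  pc <- napdyn:::control_parameters(cell)
  a <- sweep_amplitudes(p, pc, cell)
  expect_length(a, 17)
  expect_true(all(a < 0))  # inward currents, signed
  # SSI pulse #13 (-110 mV): Boltzmann value scaled by the 40-ms recovery
  # ceiling, both evaluated directly
  r40 <- recovery_eval(40, 1, pc$a1, 1 - pc$a1, 0,
                       tau1 = pc$tau1, tau2 = pc$tau2)
  expect_equal(a[13],
               -cell$control_amplitude_nA * r40 *
                 boltzmann_eval(-110, 1, pc$v_half, pc$k),
               tolerance = 1e-12)
  # RFI pulse #7 (1 ms): direct evaluation of the recovery equation
  expect_equal(a[7],
               -cell$control_amplitude_nA *
                 recovery_eval(1, 1, pc$a1, 1 - pc$a1, 0,
                               tau1 = pc$tau1, tau2 = pc$tau2),
               tolerance = 1e-12)
  # pulse #1: 498 ms >> tau2, essentially full recovery
  expect_equal(a[1], -cell$control_amplitude_nA, tolerance = 0.01)
})

test_that("drug-saturated amplitudes follow the extended equation", {
  p <- ref_protocol()
  cell <- quiet_cell()
  sp <- riluzole_like_spec(1e9)   # saturating concentration
  pm <- modulated_parameters(1e9, sp, cell)
  a <- sweep_amplitudes(p, pm, cell)
  expect_equal(pm$tau1, cell$control_tau1_ms * sp$tau1_multiplier_max,
               tolerance = 1e-6)
  a2 <- 1 - pm$a1 - pm$a3
  expected7 <- -cell$control_amplitude_nA * (1 - pm$tonic_block) *
    recovery_eval(1, 1, pm$a1, a2, pm$a3, tau1 = pm$tau1, tau2 = pm$tau2,
                  x = pm$x)
  expect_equal(a[7], expected7, tolerance = 1e-9)
})

test_that("simulation is deterministic and has null-case structure", {
  p <- ref_protocol()
  sch <- short_schedule()
  cell <- cell_ensemble_spec(noise_sd_nA = 0.05)
  s1 <- simulate_experiment(p, sch, list(), list(cell), seed = 5)
  s2 <- simulate_experiment(p, sch, list(), list(cell), seed = 5)
  expect_identical(s1[[1]]$amplitudes$amplitudes,
                   s2[[1]]$amplitudes$amplitudes)
  expect_identical(s1[[1]]$seals, s2[[1]]$seals)
  # zero noise, no drug, no drift: constant rows
  cell0 <- quiet_cell(seal_drift_frac = 0)
  s0 <- simulate_experiment(p, sch, list(), list(cell0), seed = 5)[[1]]
  amp <- s0$amplitudes$amplitudes
  expect_equal(max(apply(amp, 2, function(x) diff(range(x)))), 0)
  # with all drug effects zeroed the schedule does not matter
  inert <- drug_kinetics_spec("drugA", 100)
  si <- simulate_experiment(p, sch, list(inert), list(cell0), seed = 5)[[1]]
  expect_equal(si$amplitudes$amplitudes, amp)
  expect_error(simulate_experiment(p, sch, list(), list(), seed = 5),
               "at least one")
})

test_that("a 1700-s schedule yields 1700 sweeps and a ground-truth log", {
  p <- ref_protocol()
  sch <- build_reference_schedule(paste0("c", 1:7))
  cell <- quiet_cell()
  sim <- simulate_experiment(p, sch, list(), list(cell), seed = 1)[[1]]
  expect_equal(nrow(sim$amplitudes$amplitudes), 1700)
  expect_equal(nrow(sim$truth), 1700)
  expect_true(all(c("v_half", "k", "tau1", "a1", "x") %in%
                    names(sim$truth)))
  expect_equal(nrow(sim$seals), 1700)
})

test_that("rendered traces reduce to their constituents in edge cases", {
  p <- ref_protocol()
  render <- trace_render_spec()
  # infinite seal, zero noise, zero amplitudes: pure capacitive transients
  cell_inf <- quiet_cell(seal_resistance_MOhm = 1e12)
  tr0 <- render_sweep_trace(p, rep(0, 17), render, cell_inf)
  e <- step_edges(p)
  fs <- render$sampling_rate_khz
  on1 <- e$time_ms[e$edge == "onset" & e$pulse_index == 6]
  i <- floor(on1 * fs + 0.5) + 1
  expect_equal(tr0$current_nA[i],
               render$capacitive_amplitude_nA_per_mV * 130,
               tolerance = 1e-9)
  # decay of that transient
  expect_equal(tr0$current_nA[i + 2] / tr0$current_nA[i],
               exp(-2 / fs / render$capacitive_tau_ms), tolerance = 1e-6)
  # leak at the holding potential with a 10-MOhm seal: -13 nA
  cell10 <- quiet_cell(seal_resistance_MOhm = 10)
  tr1 <- render_sweep_trace(p, rep(0, 17), cell = cell10, render = render)
  expect_equal(tr1$current_nA[1], -13, tolerance = 1e-9)
  expect_equal(length(tr1$current_nA), 522 * 20)
})
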