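# -- synthetic ensemble experiments ------------------------------------------
#
# The generator emulates the four instrument inputs (traces, protocol file,
# schedule, seal series) with the statistical structure the analysis assumes:
# availability follows the Boltzmann / extended-recovery equations, drug
# effects interpolate between control and saturating values as a function of
# the membrane-phase concentration, which itself relaxes first-order toward
# the aqueous concentration of the active perfusion window.

#' Drug kinetics and modulation specification
#'
#' Describes how a compound's membrane-phase concentration follows perfusion
#' (first-order wash-in/wash-out) and how a given membrane concentration
#' modulates the availability parameters. All effect sizes are *saturating*
#' maxima, scaled by `c / (c + potency_uM)`.
#'
#' @param name compound label; must match schedule window labels
#' @param applied_concentration_uM aqueous concentration during application
#' @param tau_on_s,tau_off_s membrane buildup / depletion time constants (s)
#' @param potency_uM half-effect membrane concentration
#' @param max_shift_mV saturating hyperpolarizing shift of V1/2 (positive =
#'   leftward)
#' @param tau1_multiplier_max saturating fold-slowing of the fast recovery
#'   time constant (1 = no slowing)
#' @param a1_suppression_max saturating fraction of A1 redistributed to A2
#' @param tonic_block_max saturating fraction of peak current blocked at rest
#' @param unmodulated_fraction_max saturating unmodulated fraction A3
#' @param exponent_x_max saturating recovery exponent (>= 1)
#' @param sdo_block_max saturating depolarization-induced block in the SDO
#'   section
#' @param sdo_tau_ms onset time constant of SDO block at depolarized
#'   potential
#' @return a `drug_kinetics_spec`
#' @export
drug_kinetics_spec <- function(name,
                               applied_concentration_uM,
                               tau_on_s = 5,
                               tau_off_s = 8,
                               potency_uM = 100,
                               max_shift_mV = 0,
                               tau1_multiplier_max = 1,
                               a1_suppression_max = 0,
                               tonic_block_max = 0,
                               unmodulated_fraction_max = 0,
                               exponent_x_max = 1,
                               sdo_block_max = 0,
                               sdo_tau_ms = 20) {
  spec <- as.list(environment())
  stopifnot(applied_concentration_uM >= 0, tau_on_s > 0, tau_off_s > 0,
            potency_uM > 0, tau1_multiplier_max > 0, exponent_x_max >= 1,
            sdo_tau_ms > 0)
  fracs <- c(a1_suppression_max, tonic_block_max, unmodulated_fraction_max,
             sdo_block_max)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractional effect sizes must lie in [0, 1]")
  }
  structure(spec, class = "drug_kinetics_spec")
}

#' Lidocaine-like modulation preset
#'
#' Redistribution of the fast recovery fraction into the slow one (A1 down,
#' A2 up) with an unchanged fast time constant, a hyperpolarizing
#' availability shift and substantial tonic block -- the qualitative
#' signature of a compound that stabilises slow-recovering drug-bound states.
#'
#' @param concentration_uM applied concentration
#' @param name schedule label
#' @export
lidocaine_like_spec <- function(concentration_uM = 300,
                                name = "lidocaine_like") {
  drug_kinetics_spec(
    name = name, applied_concentration_uM = concentration_uM,
    tau_on_s = 4, tau_off_s = 6, potency_uM = 300,
    max_shift_mV = 22, tau1_multiplier_max = 1,
    a1_suppression_max = 0.85, tonic_block_max = 0.45,
    unmodulated_fraction_max = 0, exponent_x_max = 1,
    sdo_block_max = 0.5, sdo_tau_ms = 15
  )
}

#' Riluzole-like modulation preset
#'
#' Strong slowing of the fast recovery time constant (saturating ~8-fold)
#' with an unmodulated channel fraction and steeper-than-exponential
#' recovery (exponent > 1) -- the signature of a compound that delays fast
#' recovery without redistributing it into the slow component.
#'
#' @inheritParams lidocaine_like_spec
#' @export
riluzole_like_spec <- function(concentration_uM = 100,
                               name = "riluzole_like") {
  drug_kinetics_spec(
    name = name, applied_concentration_uM = concentration_uM,
    tau_on_s = 3, tau_off_s = 5, potency_uM = 60,
    max_shift_mV = 15, tau1_multiplier_max = 8,
    a1_suppression_max = 0, tonic_block_max = 0.2,
    unmodulated_fraction_max = 0.35, exponent_x_max = 2,
    sdo_block_max = 0.4, sdo_tau_ms = 10
  )
}

#' Control-parameter specification of one cell ensemble
#'
#' Ground-truth availability parameters, amplitude, seal resistance and
#' noise level of a simulated ~20-cell ensemble.
#'
#' @param well_id ensemble identifier
#' @param control_amplitude_nA peak inward current magnitude at rest
#' @param control_v_half_mV,control_k_mV Boltzmann midpoint and slope of the
#'   control availability curve
#' @param control_tau1_ms,control_tau2_ms fast and slow recovery time
#'   constants (`tau1 < tau2`)
#' @param control_a1 fractional contribution of the fast component
#' @param seal_resistance_MOhm ensemble seal resistance
#' @param seal_drift_frac multiplicative drift over the whole experiment
#'   (e.g. -0.05 = 5 percent gradual loss)
#' @param noise_sd_nA additive Gaussian noise (per amplitude and per trace
#'   sample)
#' @return a `cell_ensemble_spec`
#' @export
cell_ensemble_spec <- function(well_id = "W01",
                               control_amplitude_nA = 9.5,
                               control_v_half_mV = -65,
                               control_k_mV = 6,
                               control_tau1_ms = 3,
                               control_tau2_ms = 200,
                               control_a1 = 0.9,
                               seal_resistance_MOhm = 8.75,
                               seal_drift_frac = -0.03,
                               noise_sd_nA = 0.05) {
  stopifnot(control_amplitude_nA > 0, control_k_mV > 0,
            control_tau1_ms > 0, control_tau2_ms > control_tau1_ms,
            control_a1 >= 0, control_a1 <= 1,
            seal_resistance_MOhm > 0, noise_sd_nA >= 0)
  structure(as.list(environment()), class = "cell_ensemble_spec")
}

#' Trace rendering specification
#'
#' Parameters of the raw-trace model: a difference-of-exponentials sodium
#' transient at each test pulse, residual (post-compensation) capacitive
#' transients at every voltage step proportional to the step size, ohmic
#' seal leak and additive noise, sampled at 20 kHz.
#'
#' @param activation_tau_ms,inactivation_tau_ms rise and decay time
#'   constants of the sodium-current template
#' @param capacitive_amplitude_nA_per_mV residual capacitive transient
#'   amplitude per mV of step
#' @param capacitive_tau_ms capacitive transient decay time constant
#' @param reversal_potential_mV sodium reversal potential (sets the inward
#'   sign of test-pulse currents)
#' @param sampling_rate_khz sampling rate (20 for the reference output)
#' @return a `trace_render_spec`
#' @export
trace_render_spec <- function(activation_tau_ms = 0.1,
                              inactivation_tau_ms = 0.5,
                              capacitive_amplitude_nA_per_mV = 2e-4,
                              capacitive_tau_ms = 0.05,
                              reversal_potential_mV = 62,
                              sampling_rate_khz = 20) {
  stopifnot(activation_tau_ms > 0, inactivation_tau_ms > 0,
            inactivation_tau_ms != activation_tau_ms,
            capacitive_tau_ms > 0, sampling_rate_khz > 0)
  structure(as.list(environment()), class = "trace_render_spec")
}

#' Membrane-phase drug concentration at time t
#'
#' The aqueous concentration switches instantaneously between perfusion
#' windows (complete solution exchange between sweeps); the membrane phase
#' relaxes toward it first-order, with `tau_on_s` while loading and
#' `tau_off_s` while unloading. The result is continuous in `t` and bounded
#' by `[0, applied_concentration_uM]`.
#'
#' @param schedule an `experiment_schedule`
#' @param spec a `drug_kinetics_spec`; only windows whose label equals
#'   `spec$name` drive this compound
#' @param t time(s) from experiment start, s (>= 0)
#' @return membrane concentration(s), uM
#' @export
membrane_concentration <- function(schedule, spec, t) {
  if (any(t < 0)) stop("t must be >= 0")
  w <- schedule$windows
  active <- w[w$label == spec$name, , drop = FALSE]
  if (!nrow(active)) return(rep(0, length(t)))
  # piecewise-constant aqueous target over breakpoints
  breaks <- sort(unique(c(0, active$start_s,
                          active$start_s + active$duration_s)))
  target <- function(x) {
    hit <- which(x >= active$start_s - 1e-12 &
                   x < active$start_s + active$duration_s - 1e-12)
    if (length(hit)) active$concentration[hit[1]] else 0
  }
  # propagate the exact first-order solution across breakpoints
  cvals <- numeric(length(breaks))
  for (i in seq_along(breaks)[-1]) {
    tgt <- target(breaks[i - 1])
    tau <- if (tgt > cvals[i - 1]) spec$tau_on_s else spec$tau_off_s
    dt <- breaks[i] - breaks[i - 1]
    cvals[i] <- tgt + (cvals[i - 1] - tgt) * exp(-dt / tau)
  }
  eval_one <- function(x) {
    i <- findInterval(x, breaks)
    if (i < 1) return(0)
    i <- min(i, length(breaks))
    tgt <- target(breaks[i])
    tau <- if (tgt > cvals[i]) spec$tau_on_s else spec$tau_off_s
    tgt + (cvals[i] - tgt) * exp(-(x - breaks[i]) / tau)
  }
  vapply(t, eval_one, numeric(1))
}

#' Effective availability parameters at a membrane concentration
#'
#' Saturating interpolation between control and maximal-effect parameters
#' with effect fraction `e = c / (c + potency)`; `c = 0` returns the control
#' parameters exactly.
#'
#' @param c_m membrane concentration, uM (scalar, >= 0)
#' @param spec a `drug_kinetics_spec`
#' @param cell a `cell_ensemble_spec`
#' @return list with `v_half`, `k`, `tau1`, `tau2`, `a1`, `a3`, `x`,
#'   `tonic_block`, `sdo_block`, `sdo_tau_ms`
#' @export
modulated_parameters <- function(c_m, spec, cell) {
  stopifnot(length(c_m) == 1L, c_m >= 0)
  e <- c_m / (c_m + spec$potency_uM)
  a3 <- e * spec$unmodulated_fraction_max
  a1 <- cell$control_a1 * (1 - e * spec$a1_suppression_max)
  a1 <- min(a1, 1 - a3)
  list(
    v_half = cell$control_v_half_mV - e * spec$max_shift_mV,
    k = cell$control_k_mV,
    tau1 = cell$control_tau1_ms * (1 + e * (spec$tau1_multiplier_max - 1)),
    tau2 = cell$control_tau2_ms,
    a1 = a1,
    a3 = a3,
    x = 1 + e * (spec$exponent_x_max - 1),
    tonic_block = e * spec$tonic_block_max,
    sdo_block = e * spec$sdo_block_max,
    sdo_tau_ms = spec$sdo_tau_ms
  )
}

control_parameters <- function(cell) {
  modulated_parameters(0, drug_kinetics_spec("none", 0), cell)
}

# combine several compounds' modulation; shifts add, fractional effects
# combine multiplicatively on the surviving fraction
combine_modulation <- function(c_ms, specs, cell) {
  if (!length(specs)) return(control_parameters(cell))
  e <- vapply(seq_along(specs),
              function(i) c_ms[i] / (c_ms[i] + specs[[i]]$potency_uM),
              numeric(1))
  get <- function(f) vapply(specs, `[[`, numeric(1), f)
  a3 <- min(sum(e * get("unmodulated_fraction_max")), 0.95)
  a1 <- cell$control_a1 * prod(1 - e * get("a1_suppression_max"))
  list(
    v_half = cell$control_v_half_mV - sum(e * get("max_shift_mV")),
    k = cell$control_k_mV,
    tau1 = cell$control_tau1_ms *
      (1 + sum(e * (get("tau1_multiplier_max") - 1))),
    tau2 = cell$control_tau2_ms,
    a1 = min(a1, 1 - a3),
    a3 = a3,
    x = 1 + sum(e * (get("exponent_x_max") - 1)),
    tonic_block = 1 - prod(1 - e * get("tonic_block_max")),
    sdo_block = 1 - prod(1 - e * get("sdo_block_max")),
    sdo_tau_ms = if (sum(e) > 0) {
      sum(e * get("sdo_tau_ms")) / sum(e)
    } else {
      mean(get("sdo_tau_ms"))
    }
  )
}

recovery_frac <- function(tip, p) {
  a2 <- 1 - p$a1 - p$a3
  recovery_eval(tip, 1, p$a1, a2, p$a3,
                tau1 = min(p$tau1, p$tau2 * (1 - 1e-9)),
                tau2 = p$tau2, x = p$x)
}

#' Noiseless 17-pulse amplitudes for one sweep
#'
#' Evaluates the availability model at each pulse's conditioning: recovery
#' pulses at their interpulse interval (extended recovery equation), SSI
#' pulses at their pre-pulse potential (Boltzmann, scaled by the recovery
#' attainable during the 40-ms pre-pulse), SDO pulses by a single-exponential
#' onset of depolarization-induced block on top of the short-gap recovery
#' level. All amplitudes are scaled by the control amplitude and by
#' `(1 - tonic_block)`, and returned signed (inward currents negative).
#'
#' @param protocol a validated `sweep_protocol` (or its [pulse_roles()])
#' @param params effective parameters from [modulated_parameters()]
#' @param cell a `cell_ensemble_spec`
#' @return numeric vector of 17 signed peak amplitudes (nA)
#' @export
sweep_amplitudes <- function(protocol, params, cell) {
  roles <- if (is.data.frame(protocol)) protocol else pulse_roles(protocol)
  if (anyNA(roles$rfi_interval_ms[roles$rfi])) {
    stop("pulse roles are missing RFI conditioning values")
  }
  avail <- numeric(nrow(roles))
  p <- params
  ssi_prepulse_ms <- 40
  r_ceiling <- recovery_frac(ssi_prepulse_ms, p)
  for (i in seq_len(nrow(roles))) {
    if (roles$rfi[i]) {
      avail[i] <- recovery_frac(roles$rfi_interval_ms[i], p)
    } else if (roles$ssi[i]) {
      avail[i] <- r_ceiling *
        boltzmann_eval(roles$ssi_prepulse_mV[i], 1, p$v_half, p$k)
    } else if (roles$sdo[i]) {
      base <- recovery_frac(2.5, p)
      onset <- 1 - p$sdo_block *
        (1 - exp(-roles$sdo_cum_depol_ms[i] / p$sdo_tau_ms))
      avail[i] <- base * onset
    }
  }
  -cell$control_amplitude_nA * (1 - p$tonic_block) * avail
}

#' Simulate a full ensemble experiment
#'
#' Generates, for each cell ensemble, one 17-amplitude row per 1-Hz sweep
#' over the schedule, with additive Gaussian amplitude noise and a slow
#' multiplicative drift, a matching seal-resistance series, and a
#' ground-truth log of the exact per-sweep effective parameters used.
#' Identical seeds give identical output.
#'
#' @param protocol a validated `sweep_protocol`
#' @param schedule an `experiment_schedule`
#' @param drug_specs list of `drug_kinetics_spec`; each is driven by the
#'   schedule windows sharing its `name` (an empty list simulates a control
#'   experiment)
#' @param cells list of `cell_ensemble_spec` (non-empty)
#' @param seed integer RNG seed (mandatory)
#' @return list of per-ensemble results; each has `amplitudes` (an
#'   `amplitude_matrix`), `seals` (data.frame `sweep_index`, `t0_s`,
#'   `seal_MOhm`) and `truth` (data.frame of per-sweep effective parameters
#'   and per-compound membrane concentrations)
#' @export
simulate_experiment <- function(protocol, schedule, drug_specs, cells, seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  if (!length(cells)) stop("at least one cell ensemble spec is required")
  if (inherits(cells, "cell_ensemble_spec")) cells <- list(cells)
  if (inherits(drug_specs, "drug_kinetics_spec")) {
    drug_specs <- list(drug_specs)
  }
  roles <- pulse_roles(protocol)
  total_s <- schedule_duration_s(schedule)
  sweep_s <- protocol$sweep_period_ms / 1000
  n_sweeps <- floor(total_s / sweep_s)
  t0 <- (seq_len(n_sweeps) - 1) * sweep_s
  cm <- if (length(drug_specs)) {
    do.call(cbind, lapply(drug_specs,
                          function(sp) membrane_concentration(schedule, sp, t0)))
  } else {
    matrix(0, n_sweeps, 0)
  }
  withr::with_seed(as.integer(seed), {
    lapply(cells, function(cell) {
      drift <- 1 + cell$seal_drift_frac * t0 / max(total_s, 1)
      amp <- matrix(NA_real_, n_sweeps, 17)
      truth <- vector("list", n_sweeps)
      for (s in seq_len(n_sweeps)) {
        p <- combine_modulation(cm[s, ], drug_specs, cell)
        amp[s, ] <- sweep_amplitudes(roles, p, cell) * drift[s]
        truth[[s]] <- data.frame(
          sweep_index = s, t0_s = t0[s],
          v_half = p$v_half, k = p$k, tau1 = p$tau1, tau2 = p$tau2,
          a1 = p$a1, a2 = 1 - p$a1 - p$a3, a3 = p$a3, x = p$x,
          tonic_block = p$tonic_block, drift = drift[s]
        )
      }
      truth <- do.call(rbind, truth)
      if (ncol(cm)) {
        cn <- vapply(drug_specs, `[[`, character(1), "name")
        for (j in seq_len(ncol(cm))) truth[[paste0("c_m_", cn[j])]] <- cm[, j]
      }
      amp <- amp + matrix(stats::rnorm(n_sweeps * 17, 0, cell$noise_sd_nA),
                          n_sweeps, 17)
      seals <- data.frame(
        sweep_index = seq_len(n_sweeps), t0_s = t0,
        seal_MOhm = cell$seal_resistance_MOhm * drift +
          stats::rnorm(n_sweeps, 0, 0.01 * cell$seal_resistance_MOhm)
      )
      list(
        amplitudes = amplitude_matrix(amp, t0_s = t0,
                                      well_id = cell$well_id),
        seals = seals,
        truth = truth
      )
    })
  })
}

na_template_peak <- function(render) {
  ta <- render$activation_tau_ms; ti <- render$inactivation_tau_ms
  s_star <- ta * ti / (ti - ta) * log(ti / ta)
  exp(-s_star / ti) - exp(-s_star / ta)
}

#' Render one raw 20-kHz sweep trace
#'
#' Builds a raw current trace from programmed peak amplitudes: a
#' difference-of-exponentials sodium transient at each test pulse (peak
#' scaled to the pulse's amplitude), residual capacitive transients at every
#' potential change proportional to the step size and antisymmetric in its
#' sign, ohmic leak `V / R_seal`, and additive Gaussian noise.
#'
#' @param protocol a validated `sweep_protocol`
#' @param amplitudes 17 signed peak amplitudes (nA), e.g. from
#'   [sweep_amplitudes()]
#' @param render a `trace_render_spec`
#' @param cell a `cell_ensemble_spec` (seal resistance and noise)
#' @param seed optional seed for the noise (omit inside a seeded simulation)
#' @param sweep_index,t0_s trace metadata
#' @return a `sweep_trace`: list with `time_ms`, `current_nA`,
#'   `sweep_index`, `t0_s`, `well_id`, `sampling_rate_khz`
#' @export
render_sweep_trace <- function(protocol, amplitudes, render, cell,
                               seed = NULL, sweep_index = 1L, t0_s = 0) {
  stopifnot(all(is.finite(amplitudes)))
  seg <- protocol$segments
  n_p <- sum(seg$is_test_pulse)
  if (length(amplitudes) != n_p) {
    stop("need one amplitude per test pulse (", n_p, ")")
  }
  fs <- render$sampling_rate_khz
  dur <- sum(seg$duration_ms)
  n <- floor(dur * fs + 1e-9)
  tms <- (seq_len(n) - 1) / fs
  # the stimulus DAC updates on the acquisition clock: quantize all segment
  # boundaries to the nearest sample tick before rendering
  snap <- function(t) floor(t * fs + 0.5 + 1e-9) / fs
  seg_start_q <- snap(seg$start_ms)
  pot <- seg$potential_mV[findInterval(tms, seg_start_q)]
  cur <- pot / cell$seal_resistance_MOhm  # mV / MOhm = nA
  # capacitive transients at every potential change (incl. sweep boundaries)
  bounds <- c(0, seg_start_q[-1], snap(dur))
  before <- c(protocol$holding_potential_mV, seg$potential_mV)
  after <- c(seg$potential_mV, protocol$holding_potential_mV)
  dv <- after - before
  for (i in which(abs(dv) > 0)) {
    t_edge <- bounds[i]
    if (t_edge >= dur) next
    j <- which(tms >= t_edge - 1e-9)
    cur[j] <- cur[j] + render$capacitive_amplitude_nA_per_mV * dv[i] *
      exp(-(tms[j] - t_edge) / render$capacitive_tau_ms)
  }
  # sodium transients, confined to their pulse
  hpk <- na_template_peak(render)
  pulses <- seg[seg$is_test_pulse, ]
  pulses <- pulses[order(pulses$pulse_index), ]
  for (i in seq_len(n_p)) {
    p_on <- snap(pulses$start_ms[i])
    p_off <- snap(pulses$start_ms[i] + pulses$duration_ms[i])
    j <- which(tms >= p_on - 1e-9 & tms < p_off - 1e-9)
    s <- tms[j] - p_on
    h <- (exp(-s / render$inactivation_tau_ms) -
            exp(-s / render$activation_tau_ms)) / hpk
    sign_dir <- if (pulses$potential_mV[i] < render$reversal_potential_mV) {
      1
    } else {
      -1
    }
    cur[j] <- cur[j] + sign_dir * amplitudes[i] * h
  }
  add_noise <- function() {
    if (cell$noise_sd_nA > 0) {
      cur + stats::rnorm(n, 0, cell$noise_sd_nA)
    } else {
      cur
    }
  }
  cur <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  structure(
    list(time_ms = tms, current_nA = cur, sweep_index = sweep_index,
         t0_s = t0_s, well_id = cell$well_id, sampling_rate_khz = fs),
    class = "sweep_trace"
  )
}
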