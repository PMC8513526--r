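# -- sweep-by-sweep parameter tracking and macro-kinetics --------------------
#
# Each 1-Hz sweep yields one SSI fit (Boltzmann on pulses #12-#17) and one
# RFI fit (recovery equation on pulses #1, #6-#12, with the slow time
# constant fixed in automated mode). Second-to-second changes of V1/2, k,
# tau1 and A1 expose the development and removal of drug effects; the
# seconds-scale relaxation of any tracked series around a perfusion window
# gives the macro-dynamics onset/offset time constants.

#' Automated fit configuration for per-sweep tracking
#'
#' @param fixed_tau2_ms fixed slow recovery time constant; see
#'   [fixed_tau2_from_supervised()]
#' @param rfi_model one of `"biexp_fixed_tau2"`, `"biexp"`, `"stepwise"`
#' @param rmse_threshold_pct extension trigger for `"stepwise"`
#' @param bounds fit bounds, see [default_fit_bounds()]
#' @export
sweepwise_config <- function(fixed_tau2_ms = 200,
                             rfi_model = c("biexp_fixed_tau2", "biexp",
                                           "stepwise"),
                             rmse_threshold_pct = 2,
                             bounds = default_fit_bounds()) {
  rfi_model <- match.arg(rfi_model)
  as.list(environment())
}

#' Per-sweep SSI and RFI fit parameters
#'
#' Fits the Boltzmann availability curve (pulses #12--#17 against their
#' pre-pulse potentials) and the recovery curve (pulses #1, #6--#12 against
#' their interpulse intervals) for every sweep of an amplitude matrix.
#' Automated constraints apply (fractions sum to one, `tau1 < tau2`, fixed
#' slow time constant by default); each sweep's fit is initialised from the
#' previous sweep's parameters for time-coherence, with multi-start
#' fallback. Failed sweeps are flagged, never dropped; the last converged
#' parameters seed the next sweep.
#'
#' @param matrix an `amplitude_matrix`
#' @param protocol a validated `sweep_protocol`
#' @param config a [sweepwise_config()]
#' @return data.frame (`parameter_time_series`) with one row per sweep:
#'   `sweep_index`, `t0_s`, SSI parameters (`imax_ssi`, `v_half`, `k`,
#'   `rmse_ssi_pct`, `converged_ssi`), RFI parameters (`imax_rfi`, `a1`,
#'   `a2`, `a3`, `tau1`, `tau2`, `x`, `rmse_rfi_pct`, `converged_rfi`) and
#'   `flagged` for sweeps skipped at extraction.
#' @export
sweepwise_parameters <- function(matrix, protocol,
                                 config = sweepwise_config()) {
  roles <- pulse_roles(protocol)
  ssi_idx <- roles$pulse_index[roles$ssi]
  ssi_v <- roles$ssi_prepulse_mV[roles$ssi]
  rfi_idx <- roles$pulse_index[roles$rfi]
  rfi_tip <- roles$rfi_interval_ms[roles$rfi]
  amp <- matrix$amplitudes
  n <- nrow(amp)
  out <- data.frame(
    sweep_index = seq_len(n), t0_s = matrix$t0_s,
    imax_ssi = NA_real_, v_half = NA_real_, k = NA_real_,
    rmse_ssi_pct = NA_real_, converged_ssi = FALSE,
    imax_rfi = NA_real_, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
    tau1 = NA_real_, tau2 = NA_real_, x = NA_real_,
    rmse_rfi_pct = NA_real_, converged_rfi = FALSE,
    flagged = matrix$flags
  )
  init_ssi <- NULL
  init_rfi <- NULL
  for (s in seq_len(n)) {
    if (out$flagged[s] || anyNA(amp[s, ])) {
      out$flagged[s] <- TRUE
      next
    }
    mags <- abs(amp[s, ])
    ref <- mags[1]
    fb <- tryCatch(
      fit_boltzmann(ssi_v, mags[ssi_idx], init = init_ssi,
                    bounds = config$bounds, reference = ref),
      error = function(e) NULL
    )
    if (!is.null(fb)) {
      out$imax_ssi[s] <- fb$params$imax
      out$v_half[s] <- fb$params$v_half
      out$k[s] <- fb$params$k
      out$rmse_ssi_pct[s] <- fb$diagnostics$rmse_pct
      out$converged_ssi[s] <- fb$diagnostics$converged
      if (fb$diagnostics$converged) init_ssi <- fb$params
    }
    fr <- tryCatch(
      if (config$rfi_model == "stepwise") {
        stepwise_extension(rfi_tip, mags[rfi_idx],
                           rmse_threshold_pct = config$rmse_threshold_pct,
                           fixed_tau2 = config$fixed_tau2_ms,
                           bounds = config$bounds, reference = ref)$fit
      } else {
        fit_recovery(rfi_tip, mags[rfi_idx], model_tag = config$rfi_model,
                     fixed_tau2 = if (config$rfi_model == "biexp_fixed_tau2")
                       config$fixed_tau2_ms else NULL,
                     init = init_rfi, bounds = config$bounds,
                     reference = ref)
      },
      error = function(e) NULL
    )
    if (!is.null(fr)) {
      out$imax_rfi[s] <- fr$params$imax
      out$a1[s] <- fr$params$a1
      out$a2[s] <- fr$params$a2
      out$a3[s] <- fr$params$a3
      out$tau1[s] <- fr$params$tau1
      out$tau2[s] <- fr$params$tau2
      out$x[s] <- fr$params$x
      out$rmse_rfi_pct[s] <- fr$diagnostics$rmse_pct
      out$converged_rfi[s] <- fr$diagnostics$converged
      if (fr$diagnostics$converged) init_rfi <- fr$params
    }
  }
  attr(out, "rfi_model_tag") <- config$rfi_model
  class(out) <- c("parameter_time_series", class(out))
  out
}

#' Three-sweep endpoint averages around each perfusion window
#'
#' For every drug application window, averages the last `n` sweeps before
#' the window and the last `n` sweeps inside it, per pulse. These averaged
#' point sets are what supervised (visually controlled) fits use.
#'
#' @param matrix an `amplitude_matrix`
#' @param schedule an `experiment_schedule`
#' @param n number of consecutive sweeps averaged (3 reference)
#' @return data.frame with one row per window and phase (`pre` / `end`):
#'   `label`, `concentration`, `repetition`, `phase`, `t_last_s`, and mean
#'   amplitude columns `p01`...`p17`
#' @export
endpoint_average <- function(matrix, schedule, n = 3L) {
  w <- drug_windows(schedule)
  if (!nrow(w)) stop("schedule has no drug windows")
  amp <- matrix$amplitudes
  t0 <- matrix$t0_s
  usable <- !matrix$flags
  rows <- list()
  for (i in seq_len(nrow(w))) {
    pre_i <- which(t0 < w$start_s[i] & usable)
    end_i <- which(t0 >= w$start_s[i] &
                     t0 < w$start_s[i] + w$duration_s[i] & usable)
    if (length(pre_i) < n || length(end_i) < n) {
      stop("window '", w$label[i], "' starting at ", w$start_s[i],
           " s has fewer than ", n, " usable sweeps on one side")
    }
    mk <- function(idx, phase) {
      m <- colMeans(amp[idx, , drop = FALSE])
      cbind(
        data.frame(label = w$label[i], concentration = w$concentration[i],
                   repetition = w$repetition[i], phase = phase,
                   t_last_s = max(t0[idx])),
        as.data.frame(as.list(stats::setNames(m, sprintf("p%02d", 1:17))))
      )
    }
    rows[[length(rows) + 1L]] <- mk(utils::tail(pre_i, n), "pre")
    rows[[length(rows) + 1L]] <- mk(utils::tail(end_i, n), "end")
  }
  do.call(rbind, rows)
}

#' Supervised-style fits of endpoint averages
#'
#' Fits the SSI (Boltzmann) and RFI (recovery) curves to each endpoint
#' average from [endpoint_average()], with a free slow time constant as in
#' visually controlled fitting, optionally with the stepwise extension.
#'
#' @inheritParams endpoint_average
#' @param protocol a validated `sweep_protocol`
#' @param stepwise use [stepwise_extension()] for the RFI fit
#' @param rmse_threshold_pct extension trigger
#' @return data.frame with one row per window and phase carrying the fitted
#'   parameters of both curves and their RMSE values
#' @export
endpoint_fits <- function(matrix, protocol, schedule, n = 3L,
                          stepwise = TRUE, rmse_threshold_pct = 2) {
  ep <- endpoint_average(matrix, schedule, n = n)
  roles <- pulse_roles(protocol)
  ssi_idx <- roles$pulse_index[roles$ssi]
  ssi_v <- roles$ssi_prepulse_mV[roles$ssi]
  rfi_idx <- roles$pulse_index[roles$rfi]
  rfi_tip <- roles$rfi_interval_ms[roles$rfi]
  pcols <- sprintf("p%02d", 1:17)
  res <- lapply(seq_len(nrow(ep)), function(i) {
    mags <- abs(as.numeric(ep[i, pcols]))
    ref <- mags[1]
    fb <- fit_boltzmann(ssi_v, mags[ssi_idx], reference = ref)
    fr <- if (stepwise) {
      stepwise_extension(rfi_tip, mags[rfi_idx],
                         rmse_threshold_pct = rmse_threshold_pct,
                         reference = ref)$fit
    } else {
      fit_recovery(rfi_tip, mags[rfi_idx], "biexp", reference = ref)
    }
    data.frame(
      label = ep$label[i], concentration = ep$concentration[i],
      repetition = ep$repetition[i], phase = ep$phase[i],
      amplitude_p1 = ref,
      v_half = fb$params$v_half, k = fb$params$k,
      imax_ssi = fb$params$imax, rmse_ssi_pct = fb$diagnostics$rmse_pct,
      a1 = fr$params$a1, a2 = fr$params$a2, a3 = fr$params$a3,
      tau1 = fr$params$tau1, tau2 = fr$params$tau2, x = fr$params$x,
      rfi_model = fr$diagnostics$model_tag,
      rmse_rfi_pct = fr$diagnostics$rmse_pct
    )
  })
  do.call(rbind, res)
}

#' Macro-dynamics onset/offset time constants around one window
#'
#' Fits a mono-exponential relaxation `y(t) = y_inf + (y0 - y_inf) *
#' exp(-(t - t_start) / tau)` to a tracked series (an amplitude channel or a
#' fitted parameter) within the application window (onset) and within the
#' following wash period (offset). A flat series yields undefined time
#' constants, flagged rather than fitted.
#'
#' @param t0_s timestamps of the series, s
#' @param value tracked values
#' @param window_start_s,window_duration_s application window
#' @param wash_duration_s duration of the wash period following the window
#'   (default: to the end of the series)
#' @param min_points minimum points required per phase
#' @return a `macro_kinetics` list: `onset_tau_s`, `offset_tau_s`, plateau
#'   levels, per-phase RMSE, and `flags` naming undefined phases
#' @export
macro_time_constants <- function(t0_s, value, window_start_s,
                                 window_duration_s,
                                 wash_duration_s = NULL,
                                 min_points = 5L) {
  stopifnot(length(t0_s) == length(value))
  w_end <- window_start_s + window_duration_s
  wash_end <- if (is.null(wash_duration_s)) max(t0_s) + 1 else
    w_end + wash_duration_s
  fit_phase <- function(idx, t_start) {
    tt <- t0_s[idx]; yy <- value[idx]
    keep <- is.finite(yy)
    tt <- tt[keep]; yy <- yy[keep]
    if (length(yy) < min_points) {
      return(list(tau = NA_real_, y0 = NA_real_, y_inf = NA_real_,
                  rmse = NA_real_, flag = "too_few_points"))
    }
    if (stats::sd(yy) < 1e-12 ||
        stats::sd(yy) < 1e-6 * max(abs(yy), 1e-12)) {
      return(list(tau = NA_real_, y0 = yy[1], y_inf = yy[length(yy)],
                  rmse = 0, flag = "flat_series"))
    }
    span <- max(tt) - t_start
    resid <- function(p) {
      p["y_inf"] + (p["y0"] - p["y_inf"]) *
        exp(-(tt - t_start) / p["tau"]) - yy
    }
    starts <- lapply(c(span / 10, span / 3, span), function(tau) {
      c(y0 = yy[1], y_inf = yy[length(yy)], tau = tau)
    })
    lower <- c(y0 = -Inf, y_inf = -Inf, tau = span * 1e-4)
    upper <- c(y0 = Inf, y_inf = Inf, tau = span * 100)
    best <- run_lm(resid, starts, lower, upper)
    if (is.null(best)) {
      return(list(tau = NA_real_, y0 = NA_real_, y_inf = NA_real_,
                  rmse = NA_real_, flag = "fit_failed"))
    }
    p <- best$par
    list(tau = unname(p["tau"]), y0 = unname(p["y0"]),
         y_inf = unname(p["y_inf"]),
         rmse = sqrt(best$ssq / length(yy)), flag = NA_character_)
  }
  onset <- fit_phase(which(t0_s >= window_start_s & t0_s < w_end),
                     window_start_s)
  offset <- fit_phase(which(t0_s >= w_end & t0_s < wash_end), w_end)
  structure(
    list(onset_tau_s = onset$tau, offset_tau_s = offset$tau,
         onset_plateau = onset$y_inf, offset_plateau = offset$y_inf,
         onset_start_level = onset$y0, offset_start_level = offset$y0,
         onset_rmse = onset$rmse, offset_rmse = offset$rmse,
         flags = stats::na.omit(c(onset = onset$flag,
                                  offset = offset$flag))),
    class = "macro_kinetics"
  )
}

#' Per-window macro-kinetics of every pulse channel
#'
#' Applies [macro_time_constants()] to each of the 17 amplitude channels for
#' every drug window of the schedule (the observed macro-dynamics can differ
#' depending on which pulse-evoked current is monitored).
#'
#' @param matrix an `amplitude_matrix`
#' @param schedule an `experiment_schedule`
#' @param pulses pulse channels to analyse (default all 17)
#' @return data.frame with one row per window and pulse: onset/offset taus,
#'   plateau levels and flags
#' @export
macro_kinetics_by_pulse <- function(matrix, schedule, pulses = 1:17) {
  w <- drug_windows(schedule)
  all_w <- schedule$windows
  rows <- list()
  for (i in seq_len(nrow(w))) {
    # wash window that follows this application, if any
    nxt <- all_w[all_w$start_s >= w$start_s[i] + w$duration_s[i] - 1e-9 &
                   all_w$kind == "control", , drop = FALSE]
    wash_dur <- if (nrow(nxt)) nxt$duration_s[1] else NULL
    for (p in pulses) {
      mk <- macro_time_constants(
        matrix$t0_s, abs(matrix$amplitudes[, p]),
        window_start_s = w$start_s[i],
        window_duration_s = w$duration_s[i],
        wash_duration_s = wash_dur
      )
      rows[[length(rows) + 1L]] <- data.frame(
        label = w$label[i], repetition = w$repetition[i], pulse = p,
        onset_tau_s = mk$onset_tau_s, offset_tau_s = mk$offset_tau_s,
        onset_plateau = mk$onset_plateau,
        offset_plateau = mk$offset_plateau,
        flags = paste(mk$flags, collapse = ";")
      )
    }
  }
  do.call(rbind, rows)
}

#' Availability-shift monitor: pulse #17 / pulse #12 amplitude ratio
#'
#' A spontaneous left-shift of the availability curve depresses the
#' depolarized-pre-pulse current (pulse #17) faster than the hyperpolarized
#' one (pulse #12), so their ratio falling over time flags instability.
#' Near-zero denominators are flagged, not divided.
#'
#' @param matrix an `amplitude_matrix`
#' @param eps_nA denominator magnitude below which the ratio is undefined
#' @return data.frame with `sweep_index`, `t0_s`, `ratio`, `flagged`
#' @export
shift_monitor <- function(matrix, eps_nA = 0.05) {
  num <- abs(matrix$amplitudes[, 17])
  den <- abs(matrix$amplitudes[, 12])
  bad <- !is.finite(den) | den < eps_nA | !is.finite(num)
  ratio <- ifelse(bad, NA_real_, num / den)
  data.frame(sweep_index = seq_len(nrow(matrix$amplitudes)),
             t0_s = matrix$t0_s, ratio = ratio, flagged = bad)
}

#' Internal-control comparison of the two schedule repetitions
#'
#' The repeated application sequence serves as an internal control:
#' differences between repetitions of the same compound reveal incomplete
#' recovery or cumulative drift. Compares endpoint-fit parameters pairwise
#' between repetition 1 and 2 per compound and flags windows whose
#' pre-application baselines differ beyond tolerance.
#'
#' @param fits output of [endpoint_fits()]
#' @param amplitude_tol_frac tolerated relative difference of the
#'   pre-application pulse-#1 amplitude
#' @param v_half_tol_mV tolerated difference of the pre-application V1/2
#' @return list with `available` and, when both repetitions exist, a
#'   data.frame `differences` (end-phase parameter differences, repetition
#'   2 minus 1) and a data.frame `baseline_flags` with an
#'   `incomplete_recovery` flag per compound
#' @export
repeat_consistency <- function(fits, amplitude_tol_frac = 0.05,
                               v_half_tol_mV = 2) {
  reps <- sort(unique(fits$repetition))
  if (length(reps) < 2) {
    return(list(available = FALSE,
                reason = "schedule has a single repetition"))
  }
  labels <- unique(fits$label[fits$repetition == 1])
  diffs <- list(); base <- list()
  for (lb in labels) {
    f1e <- fits[fits$label == lb & fits$repetition == 1 &
                  fits$phase == "end", ]
    f2e <- fits[fits$label == lb & fits$repetition == 2 &
                  fits$phase == "end", ]
    f1p <- fits[fits$label == lb & fits$repetition == 1 &
                  fits$phase == "pre", ]
    f2p <- fits[fits$label == lb & fits$repetition == 2 &
                  fits$phase == "pre", ]
    if (!nrow(f1e) || !nrow(f2e)) next
    diffs[[lb]] <- data.frame(
      label = lb,
      d_v_half = f2e$v_half[1] - f1e$v_half[1],
      d_k = f2e$k[1] - f1e$k[1],
      d_a1 = f2e$a1[1] - f1e$a1[1],
      d_tau1 = f2e$tau1[1] - f1e$tau1[1],
      d_amplitude_p1 = f2e$amplitude_p1[1] - f1e$amplitude_p1[1]
    )
    amp_dev <- abs(f2p$amplitude_p1[1] - f1p$amplitude_p1[1]) /
      abs(f1p$amplitude_p1[1])
    vh_dev <- abs(f2p$v_half[1] - f1p$v_half[1])
    base[[lb]] <- data.frame(
      label = lb, baseline_amp_dev_frac = amp_dev,
      baseline_v_half_dev_mV = vh_dev,
      incomplete_recovery = amp_dev > amplitude_tol_frac |
        vh_dev > v_half_tol_mV
    )
  }
  list(available = TRUE,
       differences = do.call(rbind, diffs),
       baseline_flags = do.call(rbind, base))
}
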