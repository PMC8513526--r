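# -- 17-pulse cumulative voltage protocol ------------------------------------
#
# One 1-s sweep holds three assays: pulses #1-#5 probe state-dependent onset
# (SDO) with cumulatively lengthened depolarizations, pulses #6-#12 (plus #1)
# probe recovery from inactivation (RFI) with hyperpolarized gaps of
# 1...64 ms and the 498-ms inter-sweep interval, and pulses #12-#17 probe
# steady-state inactivation (SSI) with pre-pulse potentials -130...-70 mV.
# Times are ms from sweep start; segments are half-open [start, start+dur).

#' Construct the reference 17-pulse cumulative voltage protocol
#'
#' Builds the protocol used for 1 Hz sweep acquisition: five cumulative
#' depolarizations (SDO section), seven recovery test pulses after
#' hyperpolarized gaps of 1--64 ms (RFI section), and five test pulses after
#' 40-ms pre-pulses at -110 to -70 mV (SSI section), book-ended by 10-ms
#' holding margins so that the recorded sweep lasts exactly 522 ms while the
#' hyperpolarized time before pulse #1 of the next sweep is exactly 498 ms.
#' The RFI/SSI test-pulse duration is the single reconstructed duration
#' (95/12 ms) that makes the segment durations total 522 ms.
#'
#' @param overrides named list of timing/potential overrides. Recognised
#'   names: `holding_potential_mV`, `test_potential_mV`, `margin_ms`,
#'   `sdo_pulse_ms` (length 5), `sdo_gap_ms`, `sdo_rfi_separator_ms`,
#'   `rfi_gaps_ms` (length 7), `test_pulse_ms`, `ssi_prepulse_ms`,
#'   `ssi_prepulse_mV` (length 5), `sweep_period_ms`, `sampling_rate_khz`.
#' @return A `sweep_protocol` object: list with `segments` (data.frame with
#'   columns `start_ms`, `duration_ms`, `potential_mV`, `is_test_pulse`,
#'   `pulse_index`), `sweep_period_ms`, `sampling_rate_khz`,
#'   `holding_potential_mV`. Potentials are corrected membrane potentials
#'   (liquid-junction potential already accounted for); use
#'   [apply_junction_offset()] to move to command-potential space.
#' @seealso [pulse_roles()], [step_edges()], [read_protocol_file()]
#' @export
#' @examples
#' p <- build_reference_protocol()
#' sum(p$segments$duration_ms)          # 522
#' sum(p$segments$is_test_pulse)        # 17
build_reference_protocol <- function(overrides = list()) {
  defaults <- list(
    holding_potential_mV = -130,
    test_potential_mV = 0,
    margin_ms = 10,
    sdo_pulse_ms = c(2.5, 5, 15, 45, 2.5),
    sdo_gap_ms = 2.5,
    sdo_rfi_separator_ms = 64,
    rfi_gaps_ms = c(1, 2, 4, 8, 16, 32),
    test_pulse_ms = 95 / 12,
    ssi_prepulse_ms = 40,
    ssi_prepulse_mV = c(-110, -100, -90, -80, -70),
    sweep_period_ms = 1000,
    sampling_rate_khz = 20
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown protocol override(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (length(cfg$sdo_pulse_ms) != 5L) stop("sdo_pulse_ms must have length 5")
  if (length(cfg$rfi_gaps_ms) != 6L) stop("rfi_gaps_ms must have length 6")
  if (length(cfg$ssi_prepulse_mV) != 5L) {
    stop("ssi_prepulse_mV must have length 5")
  }

  hold <- cfg$holding_potential_mV
  vtest <- cfg$test_potential_mV
  dur <- numeric(0); pot <- numeric(0); pix <- integer(0)
  add <- function(d, v, p = NA_integer_) {
    dur <<- c(dur, d); pot <<- c(pot, v); pix <<- c(pix, p)
  }
  add(cfg$margin_ms, hold)
  # SDO: pulses #1-#5 separated by short hyperpolarized gaps
  for (i in 1:5) {
    add(cfg$sdo_pulse_ms[i], vtest, i)
    if (i < 5) add(cfg$sdo_gap_ms, hold)
  }
  # RFI: 64-ms separator, then gaps 1..32 ms before pulses #7-#12
  add(cfg$sdo_rfi_separator_ms, hold)
  add(cfg$test_pulse_ms, vtest, 6L)
  for (i in seq_along(cfg$rfi_gaps_ms)) {
    add(cfg$rfi_gaps_ms[i], hold)
    add(cfg$test_pulse_ms, vtest, 6L + i)
  }
  # SSI: 40-ms pre-pulses directly after the preceding test pulse
  for (i in seq_along(cfg$ssi_prepulse_mV)) {
    add(cfg$ssi_prepulse_ms, cfg$ssi_prepulse_mV[i])
    add(cfg$test_pulse_ms, vtest, 12L + i)
  }
  add(cfg$margin_ms, hold)

  segments <- data.frame(
    start_ms = cumsum(c(0, dur[-length(dur)])),
    duration_ms = dur,
    potential_mV = pot,
    is_test_pulse = !is.na(pix),
    pulse_index = pix
  )
  protocol <- structure(
    list(
      segments = segments,
      sweep_period_ms = cfg$sweep_period_ms,
      sampling_rate_khz = cfg$sampling_rate_khz,
      holding_potential_mV = hold
    ),
    class = "sweep_protocol"
  )
  validate_protocol(protocol)
  protocol
}

#' Validate a sweep protocol
#'
#' Checks that segments have positive durations, tile the sweep without gaps
#' or overlaps, fit inside the sweep period, and that exactly 17 segments are
#' flagged as test pulses with indices 1--17.
#'
#' @param protocol a `sweep_protocol`
#' @param n_pulses expected number of test pulses (17 for the reference)
#' @return the protocol, invisibly, if valid; otherwise an error naming the
#'   offending segment.
#' @export
validate_protocol <- function(protocol, n_pulses = 17L) {
  if (!inherits(protocol, "sweep_protocol")) {
    stop("not a sweep_protocol object")
  }
  seg <- protocol$segments
  needed <- c("start_ms", "duration_ms", "potential_mV", "is_test_pulse",
              "pulse_index")
  if (!all(needed %in% names(seg))) {
    stop("protocol segments missing column(s): ",
         paste(setdiff(needed, names(seg)), collapse = ", "))
  }
  bad <- which(!(seg$duration_ms > 0))
  if (length(bad)) {
    stop("segment ", bad[1], " has non-positive duration (",
         seg$duration_ms[bad[1]], " ms)")
  }
  ends <- seg$start_ms + seg$duration_ms
  if (nrow(seg) > 1) {
    gap <- abs(seg$start_ms[-1] - ends[-nrow(seg)])
    bad <- which(gap > 1e-9)
    if (length(bad)) {
      stop("segments ", bad[1], " and ", bad[1] + 1,
           " do not tile the sweep (gap/overlap of ",
           signif(seg$start_ms[bad[1] + 1] - ends[bad[1]], 4), " ms)")
    }
  }
  if (seg$start_ms[1] != 0) stop("segment 1 must start at 0 ms")
  if (ends[nrow(seg)] > protocol$sweep_period_ms + 1e-9) {
    stop("segments exceed the sweep period (",
         signif(ends[nrow(seg)], 6), " > ", protocol$sweep_period_ms, " ms)")
  }
  tp <- seg$pulse_index[seg$is_test_pulse]
  if (length(tp) != n_pulses || !setequal(tp, seq_len(n_pulses))) {
    stop("protocol must contain exactly ", n_pulses,
         " test pulses indexed 1..", n_pulses, " (found ", length(tp), ")")
  }
  if (is.unsorted(tp, strictly = TRUE)) {
    stop("test pulses must appear in increasing pulse order")
  }
  invisible(protocol)
}

#' @export
print.sweep_protocol <- function(x, ...) {
  seg <- x$segments
  cat("<sweep_protocol> ", sum(seg$is_test_pulse), " test pulses, ",
      nrow(seg), " segments, ", sum(seg$duration_ms),
      " ms recorded / ", x$sweep_period_ms, " ms period, ",
      x$sampling_rate_khz, " kHz\n", sep = "")
  invisible(x)
}

#' Assay role and conditioning history of each pulse
#'
#' Maps every test pulse to its assay memberships and conditioning values:
#' cumulative prior depolarized time for SDO pulses, preceding hyperpolarized
#' interval for RFI pulses (for pulse #1, the hyperpolarized time since the
#' last pulse of the previous sweep), and pre-pulse potential for SSI pulses.
#' Pulse #1 belongs to both the SDO control and the longest RFI point; pulse
#' #12 belongs to both RFI and the most negative SSI point.
#'
#' @param protocol a validated `sweep_protocol` with 17 test pulses
#' @return data.frame with one row per pulse: `pulse_index`, logical `sdo`,
#'   `rfi`, `ssi`, and conditioning columns `sdo_cum_depol_ms`,
#'   `rfi_interval_ms`, `ssi_prepulse_mV` (NA where the role does not apply).
#' @export
pulse_roles <- function(protocol) {
  validate_protocol(protocol)
  seg <- protocol$segments
  p <- seg[seg$is_test_pulse, ]
  p <- p[order(p$pulse_index), ]
  n <- nrow(p)
  roles <- data.frame(
    pulse_index = p$pulse_index,
    sdo = p$pulse_index %in% 1:5,
    rfi = p$pulse_index %in% c(1L, 6:12),
    ssi = p$pulse_index %in% 12:17,
    sdo_cum_depol_ms = NA_real_,
    rfi_interval_ms = NA_real_,
    ssi_prepulse_mV = NA_real_
  )
  ends <- p$start_ms + p$duration_ms
  # conditioning values are derived from the geometry so overrides propagate
  roles$sdo_cum_depol_ms[roles$sdo] <-
    cumsum(c(0, p$duration_ms[1:4]))[p$pulse_index[roles$sdo]]
  gap_before <- c(
    protocol$sweep_period_ms - ends[n] + p$start_ms[1],  # wraps to prev sweep
    p$start_ms[-1] - ends[-n]
  )
  roles$rfi_interval_ms[roles$rfi] <- gap_before[roles$rfi]
  prev_seg_pot <- vapply(which(roles$ssi), function(i) {
    j <- which(seg$is_test_pulse & seg$pulse_index == p$pulse_index[i])
    if (j == 1L) return(protocol$holding_potential_mV)
    seg$potential_mV[j - 1L]
  }, numeric(1))
  roles$ssi_prepulse_mV[roles$ssi] <- prev_seg_pot
  roles
}

#' Onset and offset voltage-step edges of every test pulse
#'
#' Returns the 34 voltage steps of the reference protocol (one onset and one
#' offset edge per test pulse) in strictly increasing time order, with the
#' signed potential change at each edge. These are the edges after which 2-ms
#' sections are cut for capacitive-artifact cancellation.
#'
#' @param protocol a validated `sweep_protocol`
#' @param n_pulses expected test-pulse count (passed to validation)
#' @return data.frame with columns `time_ms`, `delta_mV`, `pulse_index`,
#'   `edge` ("onset"/"offset").
#' @export
step_edges <- function(protocol, n_pulses = sum(protocol$segments$is_test_pulse)) {
  validate_protocol(protocol, n_pulses = n_pulses)
  seg <- protocol$segments
  idx <- which(seg$is_test_pulse)
  onset <- data.frame(
    time_ms = seg$start_ms[idx],
    delta_mV = seg$potential_mV[idx] -
      ifelse(idx > 1, seg$potential_mV[idx - 1], protocol$holding_potential_mV),
    pulse_index = seg$pulse_index[idx],
    edge = "onset"
  )
  after <- ifelse(idx < nrow(seg), seg$potential_mV[pmin(idx + 1, nrow(seg))],
                  protocol$holding_potential_mV)
  offset <- data.frame(
    time_ms = seg$start_ms[idx] + seg$duration_ms[idx],
    delta_mV = after - seg$potential_mV[idx],
    pulse_index = seg$pulse_index[idx],
    edge = "offset"
  )
  out <- rbind(onset, offset)
  out <- out[order(out$time_ms), ]
  rownames(out) <- NULL
  if (is.unsorted(out$time_ms, strictly = TRUE)) {
    stop("step edges are not strictly increasing in time")
  }
  out
}

#' Shift all protocol potentials by a liquid-junction offset
#'
#' Protocol potentials are stored as corrected membrane potentials; the
#' instrument's command potentials differ by the calculated liquid-junction
#' potential. Applying the signed offset converts between the two spaces;
#' timings are unchanged.
#'
#' @param protocol a `sweep_protocol`
#' @param offset_mV signed offset added to every potential (including the
#'   holding potential)
#' @return the shifted `sweep_protocol`
#' @export
apply_junction_offset <- function(protocol, offset_mV) {
  stopifnot(inherits(protocol, "sweep_protocol"), is.numeric(offset_mV),
            length(offset_mV) == 1L, is.finite(offset_mV))
  protocol$segments$potential_mV <- protocol$segments$potential_mV + offset_mV
  protocol$holding_potential_mV <- protocol$holding_potential_mV + offset_mV
  protocol
}

# -- drug-perfusion schedule -------------------------------------------------

new_schedule <- function(windows, repetitions) {
  stopifnot(all(c("label", "concentration", "unit", "start_s", "duration_s")
                %in% names(windows)))
  if (is.null(windows$kind)) {
    windows$kind <- ifelse(windows$label == "control", "control", "drug")
  }
  if (is.null(windows$repetition)) {
    windows <- windows[order(windows$start_s), ]
    rep_i <- integer(nrow(windows))
    seen <- list()
    for (i in seq_len(nrow(windows))) {
      if (windows$kind[i] == "drug") {
        key <- windows$label[i]
        seen[[key]] <- (seen[[key]] %||% 0L) + 1L
        rep_i[i] <- seen[[key]]
      }
    }
    windows$repetition <- rep_i
  }
  windows <- windows[order(windows$start_s), ]
  rownames(windows) <- NULL
  ends <- windows$start_s + windows$duration_s
  if (nrow(windows) > 1 &&
      any(windows$start_s[-1] - ends[-nrow(windows)] < -1e-9)) {
    stop("schedule windows overlap")
  }
  structure(list(windows = windows, repetitions = repetitions),
            class = "experiment_schedule")
}

#' Build the reference drug-perfusion schedule
#'
#' Seven 40-s drug applications separated by wash periods, the whole sequence
#' repeated twice, preceded by a control lead-in. With the default 80-s wash
#' and 20-s lead-in the experiment lasts 1700 s, i.e. 1700 sweeps at 1 Hz.
#'
#' @param labels character vector of exactly 7 compound labels
#' @param concentrations numeric vector (recycled) of applied concentrations
#' @param unit concentration unit label stored in the schedule
#' @param wash_s wash duration between applications (60 or 80 in the
#'   reference design)
#' @param application_s application duration (40 s reference)
#' @param lead_in_s initial control period
#' @param repetitions number of times the 7-application sequence is run
#' @return an `experiment_schedule`: ordered, non-overlapping windows
#'   (`label`, `concentration`, `unit`, `start_s`, `duration_s`, `kind`,
#'   `repetition`) tiling the experiment; wash/lead-in windows carry label
#'   "control".
#' @export
#' @examples
#' sch <- build_reference_schedule(paste0("cmpd", 1:7))
#' sum(sch$windows$kind == "drug")   # 14
build_reference_schedule <- function(labels,
                                     concentrations = 100,
                                     unit = "uM",
                                     wash_s = 80,
                                     application_s = 40,
                                     lead_in_s = 20,
                                     repetitions = 2L) {
  if (length(labels) != 7L) {
    stop("the reference schedule needs exactly 7 compound labels (got ",
         length(labels), ")")
  }
  if (!wash_s %in% c(60, 80)) {
    warning("reference wash periods are 60 or 80 s (got ", wash_s, " s)")
  }
  concentrations <- rep_len(concentrations, 7L)
  rows <- list()
  t <- 0
  push <- function(label, conc, dur, kind, rep_i) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, concentration = conc, unit = unit,
      start_s = t, duration_s = dur, kind = kind, repetition = rep_i
    )
    t <<- t + dur
  }
  push("control", 0, lead_in_s, "control", 0L)
  for (r in seq_len(repetitions)) {
    for (i in 1:7) {
      push(labels[i], concentrations[i], application_s, "drug", r)
      push("control", 0, wash_s, "control", r)
    }
  }
  new_schedule(do.call(rbind, rows), repetitions = repetitions)
}

#' @export
print.experiment_schedule <- function(x, ...) {
  w <- x$windows
  cat("<experiment_schedule> ", sum(w$kind == "drug"), " applications, ",
      x$repetitions, " repetition(s), ", schedule_duration_s(x), " s total\n",
      sep = "")
  invisible(x)
}

#' Total scheduled duration in seconds
#' @param schedule an `experiment_schedule`
#' @export
schedule_duration_s <- function(schedule) {
  w <- schedule$windows
  max(w$start_s + w$duration_s)
}

#' Drug application windows of a schedule
#' @param schedule an `experiment_schedule`
#' @return the subset of windows with `kind == "drug"`
#' @export
drug_windows <- function(schedule) {
  schedule$windows[schedule$windows$kind == "drug", , drop = FALSE]
}
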