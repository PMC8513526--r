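# -- raw trace -> 17 peak amplitudes -----------------------------------------
#
# For every test pulse a 2-ms section is cut after its onset edge and after
# its offset edge. The two sections are summed elementwise: the residual
# capacitive transients at the two edges have opposite sign (proportional to
# the potential step) and cancel; the summed segment is then baseline-shifted
# so it starts at zero, which removes the constant ohmic leak. No P/n leak
# subtraction is used. The peak amplitude is the minimum (inward peak) of the
# corrected segment.

#' Cut onset/offset sections around every test pulse
#'
#' Sections begin at the sample tick nearest to the edge time (voltage steps
#' are issued on the acquisition clock, so a nominal edge time between ticks
#' means the step itself occurred at the nearest tick) and contain
#' `window_ms * sampling_rate` samples.
#'
#' @param trace a `sweep_trace`
#' @param protocol a validated `sweep_protocol`
#' @param window_ms section length (2 ms reference)
#' @return list of 17 pulse-section pairs, each a list with `pulse_index`,
#'   `onset`, `offset` (equal-length numeric vectors)
#' @export
extract_sections <- function(trace, protocol, window_ms = 2) {
  fs <- trace$sampling_rate_khz
  nwin <- round(window_ms * fs)
  edges <- step_edges(protocol,
                      n_pulses = sum(protocol$segments$is_test_pulse))
  n <- length(trace$current_nA)
  section_at <- function(t_edge, pulse) {
    # edges live on the acquisition clock: align to the nearest sample tick
    i0 <- floor(t_edge * fs + 0.5 + 1e-9) + 1
    if (i0 + nwin - 1 > n) {
      stop("trace too short for the 2-ms section after the edge of pulse #",
           pulse, " at ", signif(t_edge, 6), " ms")
    }
    trace$current_nA[i0:(i0 + nwin - 1)]
  }
  pulses <- sort(unique(edges$pulse_index))
  lapply(pulses, function(p) {
    on <- edges[edges$pulse_index == p & edges$edge == "onset", ]
    off <- edges[edges$pulse_index == p & edges$edge == "offset", ]
    list(pulse_index = p,
         onset = section_at(on$time_ms, p),
         offset = section_at(off$time_ms, p))
  })
}

#' Cancel capacitive artifacts and remove the baseline offset
#'
#' Elementwise sum of a pulse's onset and offset sections (antisymmetric
#' capacitive transients cancel), baseline-shifted so the segment starts at
#' zero current. The shift uses the mean of the first `baseline_k` samples
#' (default 1: the first sample). The operation is idempotent.
#'
#' @param pair a pulse-section pair from [extract_sections()]
#' @param baseline_k number of leading samples averaged for the baseline
#' @return corrected current segment (numeric vector)
#' @export
correct_section <- function(pair, baseline_k = 1L) {
  if (length(pair$onset) != length(pair$offset)) {
    stop("onset and offset sections differ in length for pulse #",
         pair$pulse_index)
  }
  s <- pair$onset + pair$offset
  s - mean(s[seq_len(min(baseline_k, length(s)))])
}

#' Peak (minimum) amplitude of a corrected segment
#'
#' @param segment corrected current segment
#' @return list with `value` (signed minimum, nA) and `index` (sample
#'   position of the peak, for QC)
#' @export
peak_amplitude <- function(segment) {
  if (!length(segment)) stop("empty segment")
  i <- which.min(segment)
  list(value = segment[i], index = i)
}

#' Build the peak-amplitude matrix of one ensemble
#'
#' Runs section extraction, capacitive cancellation and minima extraction on
#' every sweep of one ensemble. Sweeps whose extraction fails are flagged
#' (amplitudes `NA`), never silently dropped.
#'
#' @param traces list of `sweep_trace` objects from one well, in sweep order
#' @param protocol a validated `sweep_protocol`
#' @param window_ms section length, ms
#' @param baseline_k leading samples averaged for the baseline shift
#' @return an `amplitude_matrix`
#' @export
build_amplitude_matrix <- function(traces, protocol, window_ms = 2,
                                   baseline_k = 1L) {
  if (!length(traces)) stop("no traces supplied")
  n_p <- sum(protocol$segments$is_test_pulse)
  amp <- matrix(NA_real_, length(traces), 17)
  flags <- logical(length(traces))
  t0 <- vapply(traces, `[[`, numeric(1), "t0_s")
  for (i in seq_along(traces)) {
    res <- tryCatch({
      pairs <- extract_sections(traces[[i]], protocol, window_ms)
      vapply(pairs, function(pr) {
        peak_amplitude(correct_section(pr, baseline_k))$value
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(res) || length(res) != n_p) {
      flags[i] <- TRUE
    } else {
      amp[i, seq_len(n_p)] <- res
    }
  }
  amplitude_matrix(amp, t0_s = t0, well_id = traces[[1]]$well_id,
                   flags = flags)
}
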