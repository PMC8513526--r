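# -- ensemble quality control ------------------------------------------------
#
# Exclusion rules for ~20-cell ensemble recordings, where only the aggregate
# seal resistance is observable: (1) control current amplitude below 2 nA,
# (2) overall seal resistance below 5 MOhm, (3) a gradual seal loss larger
# than 20 % over the experiment, (4) a sudden amplitude drop concurrent with
# a seal drop (loss of a cell from the ensemble). From the passing ensembles
# of each zone the most stable ones (by seal stability) are selected.

#' Default QC thresholds
#'
#' The amplitude and seal floors and the gradual-loss fraction follow the
#' published exclusion rules; the sudden-drop magnitudes are explicit
#' defaults (the rule is stated without magnitudes) and are surfaced here so
#' reports can show them.
#'
#' @param min_amplitude_nA minimum control peak amplitude (magnitude)
#' @param min_seal_MOhm minimum overall (mean) seal resistance
#' @param max_seal_loss_frac maximum tolerated fitted gradual seal decline,
#'   as a fraction of the initial seal
#' @param sudden_amp_drop_frac amplitude drop between consecutive sweeps
#'   that counts as sudden
#' @param sudden_seal_drop_frac concurrent seal drop (within the window)
#' @param sudden_window_sweeps window length for concurrency, sweeps
#' @export
qc_thresholds <- function(min_amplitude_nA = 2,
                          min_seal_MOhm = 5,
                          max_seal_loss_frac = 0.2,
                          sudden_amp_drop_frac = 0.2,
                          sudden_seal_drop_frac = 0.1,
                          sudden_window_sweeps = 3L) {
  as.list(environment())
}

robust_trend_decline <- function(t, y) {
  # fitted fractional decline over the observation span; robust to steps
  fit <- tryCatch(suppressWarnings(MASS::rlm(y ~ t, maxit = 50)),
                  error = function(e) stats::lm(y ~ t))
  b <- stats::coef(fit)
  y0 <- b[1] + b[2] * min(t)
  y1 <- b[1] + b[2] * max(t)
  if (y0 <= 0) return(0)
  (y0 - y1) / y0
}

#' Evaluate the exclusion rules for one ensemble
#'
#' @param record list with `well_id`, `amplitude` (pulse #1 peak series,
#'   signed or magnitudes, nA), `seal` (MOhm series of equal length), `t0_s`
#'   (optional timestamps) and optionally `control_idx` (logical/integer
#'   index of control-period sweeps used for the amplitude criterion;
#'   default: the first 30 sweeps)
#' @param thresholds a [qc_thresholds()] list
#' @return a `qc_verdict`: list with `well_id`, `passed`, `reasons` (subset
#'   of `low_amplitude`, `low_seal`, `seal_loss`, `sudden_drop`) and
#'   `stability_score` (inverse coefficient of variation of the seal
#'   series; higher = more stable)
#' @export
evaluate_ensemble <- function(record, thresholds = qc_thresholds()) {
  amp <- abs(record$amplitude)
  seal <- record$seal
  if (length(amp) != length(seal)) {
    stop("amplitude and seal series differ in length")
  }
  if (!length(amp)) stop("empty series")
  t <- record$t0_s %||% (seq_along(seal) - 1)
  ctrl <- record$control_idx %||% seq_len(min(30L, length(amp)))
  reasons <- character(0)
  if (mean(amp[ctrl], na.rm = TRUE) < thresholds$min_amplitude_nA) {
    reasons <- c(reasons, "low_amplitude")
  }
  if (mean(seal, na.rm = TRUE) < thresholds$min_seal_MOhm) {
    reasons <- c(reasons, "low_seal")
  }
  if (length(seal) >= 3 &&
      robust_trend_decline(t, seal) > thresholds$max_seal_loss_frac) {
    reasons <- c(reasons, "seal_loss")
  }
  w <- thresholds$sudden_window_sweeps
  n <- length(amp)
  sudden <- FALSE
  if (n >= 2) {
    drop_amp <- which(amp[-1] < (1 - thresholds$sudden_amp_drop_frac) *
                        amp[-n])
    for (i in drop_amp) {
      j <- i:min(i + w - 1L, n)
      if (any(seal[j] < (1 - thresholds$sudden_seal_drop_frac) * seal[i],
              na.rm = TRUE)) {
        sudden <- TRUE
        break
      }
    }
  }
  if (sudden) reasons <- c(reasons, "sudden_drop")
  cv <- stats::sd(seal, na.rm = TRUE) / mean(seal, na.rm = TRUE)
  structure(
    list(well_id = record$well_id, passed = !length(reasons),
         reasons = reasons,
         stability_score = if (is.finite(cv) && cv > 0) 1 / cv else Inf),
    class = "qc_verdict"
  )
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat("<qc_verdict> ", x$well_id, ": ",
      if (x$passed) "pass" else paste("fail:", paste(x$reasons,
                                                     collapse = ", ")),
      " (stability ", signif(x$stability_score, 3), ")\n", sep = "")
  invisible(x)
}

#' Select the most stable passing ensembles of a zone
#'
#' @param verdicts list of `qc_verdict` objects for one zone
#' @param n number of ensembles to choose (6 reference)
#' @return character vector of chosen `well_id`s: the `n` passing ensembles
#'   with the highest stability score, ties broken deterministically by
#'   `well_id`. If fewer than `n` pass, all passing ids are returned with a
#'   warning.
#' @export
select_top <- function(verdicts, n = 6L) {
  passing <- Filter(function(v) isTRUE(v$passed), verdicts)
  if (!length(passing)) {
    warning("no passing ensembles in this zone")
    return(character(0))
  }
  ids <- vapply(passing, `[[`, character(1), "well_id")
  score <- vapply(passing, `[[`, numeric(1), "stability_score")
  ord <- order(-score, ids)
  if (length(passing) < n) {
    warning("only ", length(passing), " passing ensembles (requested ", n,
            "); returning all of them")
    return(ids[ord])
  }
  ids[ord][seq_len(n)]
}

#' Write a QC report
#'
#' One row per ensemble with the verdict, reasons, stability score and the
#' thresholds used (as comment-line header, since the sudden-drop magnitudes
#' are configurable defaults rather than published values).
#'
#' @param verdicts list of `qc_verdict`
#' @param path file path
#' @param thresholds thresholds used (recorded in the header)
#' @export
write_qc_report <- function(verdicts, path, thresholds = qc_thresholds()) {
  df <- data.frame(
    well_id = vapply(verdicts, `[[`, character(1), "well_id"),
    passed = vapply(verdicts, `[[`, logical(1), "passed"),
    reasons = vapply(verdicts,
                     function(v) paste(v$reasons, collapse = ";"),
                     character(1)),
    stability_score = vapply(verdicts, `[[`, numeric(1), "stability_score")
  )
  write_with_meta(df, path,
                  meta = thresholds[vapply(thresholds, is.numeric,
                                           logical(1))])
}
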