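# -- on-disk artifacts -------------------------------------------------------
#
# All interchange is plain CSV (the instrument's own export path): traces,
# protocol descriptions, schedules, per-ensemble amplitude matrices, seal
# series and fit tables. Metadata rides in leading "#"-comment lines.
# Readers reject rather than silently drop malformed rows.

#' Peak-amplitude matrix of one cell ensemble
#'
#' @param amplitudes numeric matrix, one row per sweep, 17 columns (signed
#'   peak amplitudes, inward negative)
#' @param t0_s sweep start times (s), strictly increasing
#' @param well_id ensemble identifier
#' @param flags logical vector marking sweeps whose extraction failed
#'   (flagged rows are kept, never dropped)
#' @return an `amplitude_matrix`
#' @export
amplitude_matrix <- function(amplitudes, t0_s, well_id = "W01",
                             flags = rep(FALSE, nrow(amplitudes))) {
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != 17L) {
    stop("an amplitude matrix must have exactly 17 pulse columns (got ",
         ncol(amplitudes), ")")
  }
  if (length(t0_s) != nrow(amplitudes)) {
    stop("t0_s length must match the number of sweeps")
  }
  if (is.unsorted(t0_s, strictly = TRUE)) {
    stop("sweep times t0_s must be strictly increasing")
  }
  colnames(amplitudes) <- sprintf("p%02d", 1:17)
  structure(list(amplitudes = amplitudes, t0_s = as.numeric(t0_s),
                 well_id = well_id, flags = flags),
            class = "amplitude_matrix")
}

#' @export
print.amplitude_matrix <- function(x, ...) {
  cat("<amplitude_matrix> well ", x$well_id, ": ", nrow(x$amplitudes),
      " sweeps x 17 pulses, ", sum(x$flags), " flagged\n", sep = "")
  invisible(x)
}

#' @export
dim.amplitude_matrix <- function(x) dim(x$amplitudes)

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0) stop(what, " file is empty: ", path)
  n_comment <- length(read_meta_lines(path))
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                      blank.lines.skip = TRUE, skip = n_comment),
    error = function(e) stop("cannot parse ", what, " file ", path, ": ",
                             conditionMessage(e))
  )
  if (!nrow(dt) || !ncol(dt)) stop(what, " file has no data rows: ", path)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    bad <- which(is.na(v) & !is.na(dt[[col]]) & dt[[col]] != "NA")
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' of ", what, " file ",
           path, " at data row ", bad[1])
    }
  }
  dt
}

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 20L, warn = FALSE)
  n <- 0L
  while (n < length(lines) && startsWith(lines[n + 1L], "#")) n <- n + 1L
  lines[seq_len(n)]
}

read_meta_comments <- function(path) {
  lines <- read_meta_lines(path)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ",")[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  out
}

write_with_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(paste0("# ", k, ",", meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a protocol description file
#'
#' CSV with columns `segment_index`, `start_ms`, `duration_ms`,
#' `potential_mV`, `pulse_index` (empty for non-pulse segments) and leading
#' comment lines carrying `sweep_period_ms`, `sampling_rate_khz` and
#' `holding_potential_mV`. Rows may appear in any order; the reader sorts by
#' start time and revalidates (non-tiling or overlapping segments are
#' rejected).
#'
#' @param protocol a validated `sweep_protocol`
#' @param path file path
#' @return `write_protocol_file()` the path, invisibly;
#'   `read_protocol_file()` a validated `sweep_protocol`.
#' @export
write_protocol_file <- function(protocol, path) {
  validate_protocol(protocol,
                    n_pulses = sum(protocol$segments$is_test_pulse))
  seg <- protocol$segments
  df <- data.frame(segment_index = seq_len(nrow(seg)),
                   start_ms = seg$start_ms, duration_ms = seg$duration_ms,
                   potential_mV = seg$potential_mV,
                   pulse_index = seg$pulse_index)
  write_with_meta(df, path, list(
    sweep_period_ms = protocol$sweep_period_ms,
    sampling_rate_khz = protocol$sampling_rate_khz,
    holding_potential_mV = protocol$holding_potential_mV
  ))
}

#' @rdname write_protocol_file
#' @export
read_protocol_file <- function(path) {
  meta <- read_meta_comments(path)
  df <- read_csv_checked(path, c("segment_index", "start_ms", "duration_ms",
                                 "potential_mV"), "protocol")
  if (!"pulse_index" %in% names(df)) df$pulse_index <- NA_integer_
  df <- df[order(df$start_ms), ]
  protocol <- structure(
    list(
      segments = data.frame(
        start_ms = as.numeric(df$start_ms),
        duration_ms = as.numeric(df$duration_ms),
        potential_mV = as.numeric(df$potential_mV),
        is_test_pulse = !is.na(df$pulse_index),
        pulse_index = as.integer(df$pulse_index)
      ),
      sweep_period_ms = meta$sweep_period_ms %||% 1000,
      sampling_rate_khz = meta$sampling_rate_khz %||% 20,
      holding_potential_mV = meta$holding_potential_mV %||% -130
    ),
    class = "sweep_protocol"
  )
  validate_protocol(protocol,
                    n_pulses = sum(protocol$segments$is_test_pulse))
  protocol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an experiment schedule file
#'
#' CSV with columns `label`, `concentration`, `unit`, `start_s`,
#' `duration_s`. Window kind (control vs drug) is derived from the label on
#' read; repetition indices are recomputed from repeated labels.
#'
#' @param schedule an `experiment_schedule`
#' @param path file path
#' @export
write_schedule_file <- function(schedule, path) {
  w <- schedule$windows
  utils::write.csv(
    w[, c("label", "concentration", "unit", "start_s", "duration_s")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_file
#' @export
read_schedule_file <- function(path) {
  df <- read_csv_checked(path, c("concentration", "start_s", "duration_s"),
                         "schedule")
  if (!all(c("label", "unit") %in% names(df))) {
    stop("schedule file ", path, " is missing column(s): ",
         paste(setdiff(c("label", "unit"), names(df)), collapse = ", "))
  }
  df$kind <- ifelse(df$label == "control", "control", "drug")
  df <- df[order(df$start_s), ]
  rep_i <- integer(nrow(df))
  seen <- list()
  for (i in seq_len(nrow(df))) {
    if (df$kind[i] == "drug") {
      key <- df$label[i]
      seen[[key]] <- (seen[[key]] %||% 0L) + 1L
      rep_i[i] <- seen[[key]]
    }
  }
  df$repetition <- rep_i
  new_schedule(df, repetitions = max(c(rep_i, 1L)))
}

#' Write / read a per-ensemble peak-amplitude matrix
#'
#' CSV with columns `sweep_index`, `t0_s`, `p01`...`p17`. Flagged sweeps are
#' written with `NA` amplitudes; on read any row containing `NA` is flagged.
#' Writing refuses matrices without exactly 17 pulse columns.
#'
#' @param matrix an `amplitude_matrix`
#' @param path file path
#' @param well_id ensemble identifier for the read matrix (default: the
#'   file name stem)
#' @export
write_amplitude_matrix <- function(matrix, path) {
  if (!inherits(matrix, "amplitude_matrix")) {
    stop("not an amplitude_matrix (17 pulse columns are required)")
  }
  amp <- matrix$amplitudes
  amp[matrix$flags, ] <- NA_real_
  df <- data.frame(sweep_index = seq_len(nrow(amp)), t0_s = matrix$t0_s, amp)
  data.table::fwrite(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_amplitude_matrix
#' @export
read_amplitude_matrix <- function(path, well_id = NULL) {
  df <- read_csv_checked(path, c("sweep_index", "t0_s",
                                 sprintf("p%02d", 1:17)), "amplitude")
  df <- df[order(df$t0_s), ]
  amp <- as.matrix(df[, sprintf("p%02d", 1:17)])
  if (is.null(well_id)) {
    well_id <- sub("\\.csv$", "", basename(path))
  }
  amplitude_matrix(amp, t0_s = df$t0_s, well_id = well_id,
                   flags = apply(amp, 1, anyNA))
}

#' Write / read a seal-resistance series
#'
#' CSV with columns `sweep_index`, `t0_s`, `seal_MOhm`.
#'
#' @param seals data.frame with those columns
#' @param path file path
#' @export
write_seal_series <- function(seals, path) {
  stopifnot(all(c("sweep_index", "t0_s", "seal_MOhm") %in% names(seals)))
  utils::write.csv(seals[, c("sweep_index", "t0_s", "seal_MOhm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seal_series
#' @export
read_seal_series <- function(path) {
  df <- read_csv_checked(path, c("sweep_index", "t0_s", "seal_MOhm"),
                         "seal series")
  df[order(df$t0_s), c("sweep_index", "t0_s", "seal_MOhm")]
}

#' Write / read raw sweep traces
#'
#' CSV with a `sweep_index` column, a `time_ms` column (time within the
#' sweep) and one `current_nA_<well>` column per well. Leading comment lines
#' carry `sampling_rate_khz` and `sweep_period_s`. The reader returns one
#' `sweep_trace` per sweep and well and rejects files with inconsistent
#' sweep lengths, naming the offending sweep.
#'
#' @param traces list of `sweep_trace` objects (possibly several wells)
#' @param path file path
#' @export
write_trace_file <- function(traces, path) {
  if (inherits(traces, "sweep_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces to write")
  wells <- unique(vapply(traces, `[[`, character(1), "well_id"))
  sweeps <- sort(unique(vapply(traces, `[[`, numeric(1), "sweep_index")))
  fs <- traces[[1]]$sampling_rate_khz
  blocks <- lapply(sweeps, function(s) {
    rows <- NULL
    for (w in wells) {
      tr <- Filter(function(x) x$sweep_index == s && x$well_id == w, traces)
      if (!length(tr)) stop("missing trace for sweep ", s, ", well ", w)
      tr <- tr[[1]]
      if (is.null(rows)) {
        rows <- data.frame(sweep_index = s, time_ms = tr$time_ms)
      }
      rows[[paste0("current_nA_", w)]] <- tr$current_nA
    }
    rows
  })
  df <- do.call(rbind, blocks)
  tmp <- paste0(path, ".body")
  con <- file(path, "w")
  writeLines(paste0("# sampling_rate_khz,", fs), con)
  sweep_s <- traces[[1]]$t0_s
  writeLines(paste0("# sweep_period_s,",
                    if (length(sweeps) > 1) {
                      t0s <- vapply(traces, `[[`, numeric(1), "t0_s")
                      diff(sort(unique(t0s)))[1]
                    } else 1), con)
  close(con)
  data.table::fwrite(df, tmp)
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

#' @rdname write_trace_file
#' @export
read_trace_file <- function(path) {
  meta <- read_meta_comments(path)
  df <- read_csv_checked(path, c("sweep_index", "time_ms"), "trace")
  wells <- grep("^current_nA_", names(df), value = TRUE)
  if (!length(wells)) {
    stop("trace file ", path, " has no current_nA_<well> columns")
  }
  fs <- meta$sampling_rate_khz %||% 20
  period_s <- meta$sweep_period_s %||% 1
  sweeps <- sort(unique(df$sweep_index))
  lens <- vapply(sweeps, function(s) sum(df$sweep_index == s), numeric(1))
  if (length(unique(lens)) > 1) {
    bad <- sweeps[which(lens != stats::median(lens))[1]]
    stop("inconsistent sample count in trace file ", path,
         " at sweep ", bad)
  }
  out <- list()
  for (s in sweeps) {
    rows <- df[df$sweep_index == s, ]
    rows <- rows[order(rows$time_ms), ]
    for (w in wells) {
      if (anyNA(rows[[w]])) {
        stop("missing sample(s) in trace file ", path, " at sweep ", s,
             ", column ", w)
      }
      out[[length(out) + 1L]] <- structure(
        list(time_ms = rows$time_ms, current_nA = rows[[w]],
             sweep_index = s, t0_s = (s - 1) * period_s,
             well_id = sub("^current_nA_", "", w), sampling_rate_khz = fs),
        class = "sweep_trace"
      )
    }
  }
  out
}

#' Write a per-sweep fit-parameter table
#'
#' One row per sweep and fitted model with columns `sweep_index`,
#' `model_tag`, `Imax`, `V12`, `k`, `A1`, `A2`, `A3`, `tau1`, `tau2`, `x`,
#' `rmse_pct`, `converged` (parameters that a model does not have are `NA`).
#'
#' @param series output of [sweepwise_parameters()]
#' @param path file path
#' @export
write_fits_table <- function(series, path) {
  ssi <- data.frame(
    sweep_index = series$sweep_index, model_tag = "boltzmann",
    Imax = series$imax_ssi, V12 = series$v_half, k = series$k,
    A1 = NA_real_, A2 = NA_real_, A3 = NA_real_,
    tau1 = NA_real_, tau2 = NA_real_, x = NA_real_,
    rmse_pct = series$rmse_ssi_pct, converged = series$converged_ssi
  )
  rfi <- data.frame(
    sweep_index = series$sweep_index,
    model_tag = attr(series, "rfi_model_tag") %||% "biexp_fixed_tau2",
    Imax = series$imax_rfi, V12 = NA_real_, k = NA_real_,
    A1 = series$a1, A2 = series$a2, A3 = series$a3,
    tau1 = series$tau1, tau2 = series$tau2, x = series$x,
    rmse_pct = series$rmse_rfi_pct, converged = series$converged_rfi
  )
  out <- rbind(ssi, rfi)
  out <- out[order(out$sweep_index), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Converter stub for the instrument's native binary format
#'
#' The acquisition software's native `DataAcquisition*.ISD` binary container
#' is proprietary and undocumented; the supported interchange is the CSV
#' export path. This stub exists so that pipelines fail with a clear message
#' rather than a parse error.
#'
#' @param path path to an `.ISD` file
#' @export
read_isd_file <- function(path) {
  stop("unsupported format: native .ISD binaries are not parsed; ",
       "export traces as CSV and use read_trace_file()")
}
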