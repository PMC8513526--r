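# -- reproducible pipeline: simulate -> extract -> qc -> fit -> dynamics -----

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic-experiment
#' analysis run. A seed is mandatory (every stochastic stage derives from
#' it); thresholds are checked against their documented ranges up front so
#' an invalid configuration refuses before any stage runs.
#'
#' @param out_dir run directory (created if absent)
#' @param seed integer RNG seed
#' @param n_ensembles number of simulated cell ensembles
#' @param drugs list of `drug_kinetics_spec`
#' @param schedule an `experiment_schedule` (default: reference schedule
#'   labelled with the drug names, recycled over the 7 slots)
#' @param protocol a `sweep_protocol`
#' @param cells optional list of `cell_ensemble_spec`; default ensembles
#'   vary amplitude and seal around the reference values
#' @param render_traces also render and re-extract raw 20-kHz traces for the
#'   first `render_sweeps` sweeps (slow; the amplitude-level path is exact
#'   by construction)
#' @param render_sweeps how many sweeps to render when `render_traces`
#' @param qc a [qc_thresholds()] list
#' @param fit a [sweepwise_config()] list
#' @param select_n ensembles selected per zone
#' @return validated `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            seed,
                            n_ensembles = 4L,
                            drugs = list(lidocaine_like_spec(),
                                         riluzole_like_spec()),
                            schedule = NULL,
                            protocol = build_reference_protocol(),
                            cells = NULL,
                            render_traces = FALSE,
                            render_sweeps = 3L,
                            qc = qc_thresholds(),
                            fit = sweepwise_config(),
                            select_n = 6L) {
  if (missing(seed) || !is.finite(seed)) {
    stop("pipeline_config: a seed is mandatory")
  }
  if (is.null(schedule)) {
    labels <- rep_len(vapply(drugs, `[[`, character(1), "name"), 7L)
    concs <- rep_len(vapply(drugs, `[[`, numeric(1),
                            "applied_concentration_uM"), 7L)
    schedule <- build_reference_schedule(labels, concentrations = concs)
  }
  if (is.null(cells)) {
    cells <- lapply(seq_len(n_ensembles), function(i) {
      cell_ensemble_spec(
        well_id = sprintf("W%02d", i),
        control_amplitude_nA = 9.5 * (0.8 + 0.1 * (i %% 4)),
        seal_resistance_MOhm = 8.75 * (0.9 + 0.05 * (i %% 3))
      )
    })
  }
  chk <- function(ok, what) if (!ok) stop("invalid configuration: ", what)
  chk(qc$min_amplitude_nA >= 0, "qc min_amplitude_nA must be >= 0")
  chk(qc$min_seal_MOhm >= 0, "qc min_seal_MOhm must be >= 0")
  chk(qc$max_seal_loss_frac > 0 && qc$max_seal_loss_frac < 1,
      "qc max_seal_loss_frac must be in (0, 1)")
  chk(fit$fixed_tau2_ms > 0, "fit fixed_tau2_ms must be > 0")
  chk(fit$rmse_threshold_pct > 0, "fit rmse_threshold_pct must be > 0")
  structure(as.list(environment())[c(
    "out_dir", "seed", "n_ensembles", "drugs", "schedule", "protocol",
    "cells", "render_traces", "render_sweeps", "qc", "fit", "select_n"
  )], class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; drugs are
#' given as a list of preset names (`lidocaine_like`, `riluzole_like`) or of
#' full [drug_kinetics_spec()] argument lists.
#'
#' @param path YAML file
#' @param out_dir,seed overrides of the file's values
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  drugs <- lapply(y$drugs %||% list(), function(d) {
    if (is.character(d)) {
      switch(d,
             lidocaine_like = lidocaine_like_spec(),
             riluzole_like = riluzole_like_spec(),
             stop("unknown drug preset: ", d))
    } else {
      do.call(drug_kinetics_spec, d)
    }
  })
  args <- list(
    out_dir = out_dir %||% y$out_dir,
    seed = seed %||% y$seed,
    n_ensembles = y$n_ensembles %||% 4L,
    render_traces = isTRUE(y$render_traces),
    render_sweeps = y$render_sweeps %||% 3L
  )
  if (length(drugs)) args$drugs <- drugs
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$fit)) args$fit <- do.call(sweepwise_config, y$fit)
  do.call(pipeline_config, args)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%OS1 "), ...)
  writeLines(msg, con)
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Stages: simulate ensemble amplitude matrices and seal series over the
#' schedule (optionally rendering and re-extracting raw traces for the
#' first sweeps); apply the QC exclusion rules and select the most stable
#' ensembles; run per-sweep automated fits; compute endpoint fits,
#' per-pulse macro-kinetics, the availability-shift monitor and the
#' repetition internal control. Every intermediate artifact is written as
#' CSV into the run directory together with a plain-text log; identical
#' configurations and seeds produce identical files.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list with the run directory, QC verdicts, chosen
#'   wells, and per-well result paths
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline expects a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  abort <- function(stage, e, artifact) {
    stop("pipeline stage '", stage, "' failed (", conditionMessage(e),
         "); artifacts under ", artifact)
  }
  log_line(logf, "seed ", config$seed, ", ", config$n_ensembles,
           " ensembles, ", length(config$drugs), " compounds")

  # -- simulate
  sim <- tryCatch(
    simulate_experiment(config$protocol, config$schedule, config$drugs,
                        config$cells, seed = config$seed),
    error = function(e) abort("simulate", e, config$out_dir)
  )
  write_protocol_file(config$protocol,
                      file.path(config$out_dir, "protocol.csv"))
  write_schedule_file(config$schedule,
                      file.path(config$out_dir, "schedule.csv"))
  wells <- vapply(config$cells, `[[`, character(1), "well_id")
  for (i in seq_along(sim)) {
    w <- wells[i]
    write_amplitude_matrix(sim[[i]]$amplitudes,
                           file.path(config$out_dir,
                                     paste0("amplitudes_", w, ".csv")))
    write_seal_series(sim[[i]]$seals,
                      file.path(config$out_dir, paste0("seals_", w,
                                                       ".csv")))
    utils::write.csv(sim[[i]]$truth,
                     file.path(config$out_dir, paste0("truth_", w, ".csv")),
                     row.names = FALSE)
  }
  log_line(logf, "simulated ", nrow(sim[[1]]$amplitudes$amplitudes),
           " sweeps per ensemble")

  # -- optional raw-trace round trip for the first sweeps
  if (config$render_traces) {
    render <- trace_render_spec()
    cell <- config$cells[[1]]
    ns <- min(config$render_sweeps, nrow(sim[[1]]$amplitudes$amplitudes))
    traces <- withr::with_seed(config$seed + 1L, lapply(seq_len(ns),
      function(s) {
        render_sweep_trace(config$protocol,
                           sim[[1]]$amplitudes$amplitudes[s, ],
                           render, cell, sweep_index = s,
                           t0_s = sim[[1]]$amplitudes$t0_s[s])
      }))
    write_trace_file(traces, file.path(config$out_dir, "traces_demo.csv"))
    rex <- build_amplitude_matrix(traces, config$protocol)
    write_amplitude_matrix(rex, file.path(config$out_dir,
                                          "amplitudes_reextracted.csv"))
    log_line(logf, "rendered and re-extracted ", ns, " sweeps")
  }

  # -- qc
  verdicts <- lapply(seq_along(sim), function(i) {
    evaluate_ensemble(list(
      well_id = wells[i],
      amplitude = sim[[i]]$amplitudes$amplitudes[, 1],
      seal = sim[[i]]$seals$seal_MOhm,
      t0_s = sim[[i]]$seals$t0_s
    ), config$qc)
  })
  write_qc_report(verdicts, file.path(config$out_dir, "qc_report.csv"),
                  config$qc)
  chosen <- withCallingHandlers(
    select_top(verdicts, n = config$select_n),
    warning = function(w) {
      log_line(logf, "qc warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  log_line(logf, "qc passed: ",
           sum(vapply(verdicts, `[[`, logical(1), "passed")), "/",
           length(verdicts), "; chosen: ", paste(chosen, collapse = " "))

  # -- per-sweep fits and dynamics for the chosen wells
  results <- list()
  for (w in chosen) {
    i <- match(w, wells)
    series <- tryCatch(
      sweepwise_parameters(sim[[i]]$amplitudes, config$protocol,
                           config$fit),
      error = function(e) abort("fit", e, config$out_dir)
    )
    write_fits_table(series,
                     file.path(config$out_dir, paste0("fits_", w, ".csv")))
    ef <- tryCatch(
      endpoint_fits(sim[[i]]$amplitudes, config$protocol, config$schedule),
      error = function(e) abort("dynamics", e, config$out_dir)
    )
    utils::write.csv(ef, file.path(config$out_dir,
                                   paste0("endpoint_fits_", w, ".csv")),
                     row.names = FALSE)
    mk <- macro_kinetics_by_pulse(sim[[i]]$amplitudes, config$schedule,
                                  pulses = c(1, 7, 12, 17))
    utils::write.csv(mk, file.path(config$out_dir,
                                   paste0("macro_", w, ".csv")),
                     row.names = FALSE)
    sm <- shift_monitor(sim[[i]]$amplitudes)
    utils::write.csv(sm, file.path(config$out_dir,
                                   paste0("shift_monitor_", w, ".csv")),
                     row.names = FALSE)
    rc <- repeat_consistency(ef)
    if (isTRUE(rc$available)) {
      utils::write.csv(rc$baseline_flags,
                       file.path(config$out_dir,
                                 paste0("internal_control_", w, ".csv")),
                       row.names = FALSE)
    }
    results[[w]] <- list(series = series, endpoint_fits = ef,
                         macro = mk, internal_control = rc)
    log_line(logf, "analysed well ", w)
  }
  log_line(logf, "done")
  invisible(list(out_dir = config$out_dir, verdicts = verdicts,
                 chosen = chosen, results = results))
}

#' Write a small bundled synthetic dataset
#'
#' Two ensembles, a 200-s schedule with two drug windows, raw traces for the
#' first sweeps, amplitude matrices, seal series, protocol, schedule and
#' ground truth -- enough to exercise every reader and the documentation
#' examples. Byte-identical across runs for the same seed.
#'
#' @param seed integer seed
#' @param dir output directory
#' @return invisibly, the directory
#' @export
make_fixtures <- function(seed = 42L, dir = tempfile("napdyn_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- build_reference_protocol()
  windows <- data.frame(
    label = c("control", "lidocaine_like", "control", "riluzole_like",
              "control"),
    concentration = c(0, 300, 0, 100, 0),
    unit = "uM",
    start_s = c(0, 40, 80, 120, 160),
    duration_s = c(40, 40, 40, 40, 40)
  )
  schedule <- new_schedule(windows, repetitions = 1L)
  drugs <- list(lidocaine_like_spec(), riluzole_like_spec())
  cells <- list(
    cell_ensemble_spec(well_id = "F01"),
    cell_ensemble_spec(well_id = "F02", control_amplitude_nA = 6,
                       seal_resistance_MOhm = 10)
  )
  sim <- simulate_experiment(protocol, schedule, drugs, cells, seed = seed)
  write_protocol_file(protocol, file.path(dir, "protocol.csv"))
  write_schedule_file(schedule, file.path(dir, "schedule.csv"))
  for (i in seq_along(sim)) {
    w <- cells[[i]]$well_id
    write_amplitude_matrix(sim[[i]]$amplitudes,
                           file.path(dir, paste0("amplitudes_", w,
                                                 ".csv")))
    write_seal_series(sim[[i]]$seals,
                      file.path(dir, paste0("seals_", w, ".csv")))
    utils::write.csv(sim[[i]]$truth,
                     file.path(dir, paste0("truth_", w, ".csv")),
                     row.names = FALSE)
  }
  render <- trace_render_spec()
  traces <- withr::with_seed(seed + 1L, lapply(1:2, function(s) {
    render_sweep_trace(protocol, sim[[1]]$amplitudes$amplitudes[s, ],
                       render, cells[[1]], sweep_index = s,
                       t0_s = sim[[1]]$amplitudes$t0_s[s])
  }))
  write_trace_file(traces, file.path(dir, "traces_F01.csv"))
  invisible(dir)
}
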