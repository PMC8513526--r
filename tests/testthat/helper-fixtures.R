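# shared fixtures, built in code

ref_protocol <- function() build_reference_protocol()

# short three-phase schedule: control / one drug window / wash
short_schedule <- function(drug_label = "drugA", conc = 100,
                           lead = 40, app = 40, wash = 40) {
  w <- data.frame(
    label = c("control", drug_label, "control"),
    concentration = c(0, conc, 0), unit = "uM",
    start_s = c(0, lead, lead + app),
    duration_s = c(lead, app, wash)
  )
  napdyn:::new_schedule(w, repetitions = 1L)
}

# two-repetition schedule with a single compound
two_rep_schedule <- function(drug_label = "drugA", conc = 100,
                             lead = 30, app = 30, wash = 40) {
  w <- data.frame(
    label = c("control", drug_label, "control", drug_label, "control"),
    concentration = c(0, conc, 0, conc, 0), unit = "uM",
    start_s = cumsum(c(0, lead, app, wash, app)),
    duration_s = c(lead, app, wash, app, wash)
  )
  napdyn:::new_schedule(w, repetitions = 2L)
}

quiet_cell <- function(...) cell_ensemble_spec(noise_sd_nA = 0, ...)

# brute-force grid oracles: the nonlinear shape parameters are gridded
# exhaustively and the amplitude parameters solved linearly per grid point,
# so the oracle shares no code path with the LM fits.
grid_oracle_boltzmann <- function(Vp, I, v_half_grid, k_grid) {
  best <- list(ssq = Inf)
  for (vh in v_half_grid) for (k in k_grid) {
    g <- 1 / (1 + exp((Vp - vh) / k))
    imax <- sum(g * I) / sum(g * g)
    ssq <- sum((imax * g - I)^2)
    if (ssq < best$ssq) {
      best <- list(ssq = ssq, imax = imax, v_half = vh, k = k)
    }
  }
  best
}

grid_oracle_biexp <- function(tip, I, tau1_grid, tau2_grid) {
  best <- list(ssq = Inf)
  for (t1 in tau1_grid) for (t2 in tau2_grid) {
    if (t1 >= t2) next
    f1 <- 1 - exp(-tip / t1)
    f2 <- 1 - exp(-tip / t2)
    X <- cbind(f1, f2)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, I)),
                   error = function(e) NULL)
    if (is.null(cf) || any(cf < 0)) next
    ssq <- sum((X %*% cf - I)^2)
    if (ssq < best$ssq) {
      best <- list(ssq = ssq, imax = sum(cf), a1 = cf[1] / sum(cf),
                   tau1 = t1, tau2 = t2)
    }
  }
  best
}
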