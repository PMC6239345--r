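# Calibration of the three maximal conductances against the model's
# published operating anchors, and the figure-level study pipelines: light
# sweeps with per-conductance freeze variants, frozen/accelerated
# inactivation studies, and paired modulation comparisons at matched light
# conductance.

#' Calibrated maximal conductances
#'
#' The maximal conductances of Shaker, Shab and the Novel conductance are
#' free parameters of the membrane model. The shipped defaults are the
#' output of [calibrate_gbar()] with the standard anchor set (dark resting
#' potential -68 mV, dark input resistance 290 MOhm, dark bandwidth 26 Hz,
#' energy cost 5.6e8 ATP/s at -36 mV) and the default membrane parameters.
#'
#' The fit is deterministic (fixed-start Nelder-Mead); the four anchors
#' drive the Novel maximal conductance to zero, i.e. they carry no
#' information that supports a nonzero value (see the methods vignette).
#'
#' @return Named numeric vector `c(shaker, shab, novel)`, nS.
#' @export
gbar_default <- function() {
  c(shaker = 16.401325, shab = 53.041633, novel = 0)
}

#' Standard calibration anchors
#'
#' @return Named numeric vector: `V_rest_mV` (-68), `R_in_MOhm` (290, "just
#'   below 300"), `bandwidth_Hz` (26, dark), `cost_hl_ATP_s` (5.6e8 at
#'   -36 mV).
#' @export
calibration_anchors <- function() {
  c(V_rest_mV = -68, R_in_MOhm = 290, bandwidth_Hz = 26, cost_hl_ATP_s = 5.6e8)
}

# Evaluate the four anchor quantities for one gbar triple.
.anchor_values <- function(gbar, membrane, V_high = -36) {
  ch <- build_channel_set(modulation_state(), g_max = gbar)
  dark <- tryCatch(find_dark_rest(ch, membrane), error = function(e) NULL)
  if (is.null(dark)) return(NULL)
  sp <- membrane_impedance(dark)
  bw <- suppressWarnings(as.numeric(bandwidth(sp)))
  hi <- solve_balance_at_voltage(V_high, ch, membrane)
  c(V_rest_mV = dark$V, R_in_MOhm = input_resistance(dark),
    bandwidth_Hz = bw, cost_hl_ATP_s = energy_cost(hi))
}

#' Calibrate the maximal conductances
#'
#' Derivative-free (Nelder-Mead, fixed start, deterministic) minimisation of
#' the summed squared relative anchor errors over the log of the three
#' maximal conductances. Any subset of the standard anchors may be used.
#'
#' @param anchors named numeric vector, a subset of [calibration_anchors()].
#' @param membrane a [membrane_params()].
#' @param start starting gbar triple, nS.
#' @param maxit maximum Nelder-Mead iterations.
#' @return An object of class `calibration_result`: fitted `gbar`, achieved
#'   anchor values, relative residuals, objective value, convergence code
#'   and a `failed` flag (any |relative residual| > 5%).
#' @export
calibrate_gbar <- function(anchors = calibration_anchors(),
                           membrane = membrane_params(),
                           start = c(shaker = 20, shab = 20, novel = 20),
                           maxit = 500) {
  stopifnot(all(names(anchors) %in% names(calibration_anchors())),
            length(anchors) >= 1)
  obj <- function(lg) {
    gbar <- stats::setNames(exp(lg), c("shaker", "shab", "novel"))
    av <- .anchor_values(gbar, membrane)
    if (is.null(av)) return(1e6)
    rel <- (av[names(anchors)] - anchors) / anchors
    sum(rel^2)
  }
  fit <- stats::optim(log(unname(start)), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  gbar <- stats::setNames(exp(fit$par), c("shaker", "shab", "novel"))
  av <- .anchor_values(gbar, membrane)
  rel <- (av[names(anchors)] - anchors) / anchors
  structure(list(gbar = gbar, achieved = av, anchors = anchors,
                 residuals = rel, value = fit$value,
                 convergence = fit$convergence,
                 failed = any(abs(rel) > 0.05)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  gbar (nS):",
      paste(sprintf("%s = %.4f", names(x$gbar), x$gbar), collapse = ", "), "\n")
  for (nm in names(x$anchors)) {
    cat(sprintf("  %s: target %.4g, achieved %.4g (%.2f%%)\n",
                nm, x$anchors[nm], x$achieved[nm], 100 * x$residuals[nm]))
  }
  cat(if (x$failed) "  status: FAILED (residual > 5%)\n" else "  status: converged\n")
  invisible(x)
}

#' Sweep study: metrics across light levels and freeze variants
#'
#' For every grid voltage, computes the metrics of the full active model,
#' of the all-frozen passive equivalent, and of the three one-channel-active
#' variants (the other two channels frozen).
#'
#' @param channels channel set from [build_channel_set()].
#' @param membrane a [membrane_params()].
#' @param V_grid voltages, mV; defaults to [standard_grid()].
#' @param f frequency grid, Hz.
#' @return A `data.frame`, one row per voltage x variant.
#' @export
run_sweep_study <- function(channels, membrane = membrane_params(),
                            V_grid = standard_grid(channels, membrane),
                            f = default_freq_grid()) {
  variants <- list(full = freeze_none(), passive = freeze_all(),
                   shaker_only = freeze_all_but("shaker"),
                   shab_only = freeze_all_but("shab"),
                   novel_only = freeze_all_but("novel"))
  rows <- list()
  for (V in V_grid) {
    op <- solve_balance_at_voltage(V, channels, membrane)
    for (nm in names(variants)) {
      rows[[length(rows) + 1L]] <- metrics_record(op, variants[[nm]], f,
                                                  label = nm)
    }
  }
  do.call(rbind, rows)
}

#' Frozen- and accelerated-inactivation study
#'
#' For each reference voltage, builds a channel set whose inactivation gates
#' are pinned at the reference steady-state values, re-solves every grid
#' operating point under that set, and records bandwidth and energy cost;
#' also sweeps the model with inactivation accelerated to activation speed.
#'
#' @inheritParams run_sweep_study
#' @param reference_V voltages (mV) at which inactivation is frozen;
#'   defaults to the grid itself.
#' @return A `data.frame` with columns `variant` (`frozen_at_<V>` or
#'   `accelerated` or `intact`), `V_mV`, `bandwidth_Hz`,
#'   `energy_cost_ATP_s`.
#' @export
run_freeze_inactivation_study <- function(channels,
                                          membrane = membrane_params(),
                                          V_grid = standard_grid(channels, membrane),
                                          reference_V = V_grid,
                                          f = default_freq_grid()) {
  rows <- list()
  add <- function(variant, op, freeze = freeze_none(), accel = FALSE) {
    sp <- membrane_impedance(op, freeze, f)
    if (accel) {
      op2 <- op
      op2$channels <- accelerate_channel_inactivation(op$channels)
      sp <- membrane_impedance(op2, freeze, f)
    }
    bw <- suppressWarnings(as.numeric(bandwidth(sp)))
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, V_mV = op$V, bandwidth_Hz = bw,
      energy_cost_ATP_s = energy_cost(op), stringsAsFactors = FALSE)
  }
  for (V in V_grid) add("intact", solve_balance_at_voltage(V, channels, membrane))
  for (Vref in reference_V) {
    frozen <- lapply(channels, freeze_channel_inactivation, V_ref = Vref)
    attr(frozen, "modulation") <- attr(channels, "modulation")
    for (V in V_grid)
      add(sprintf("frozen_at_%g", Vref),
          solve_balance_at_voltage(V, frozen, membrane))
  }
  accel_ch <- accelerate_channel_inactivation(channels)
  for (V in V_grid) {
    op <- solve_balance_at_voltage(V, accel_ch, membrane)
    add("accelerated", op)
  }
  do.call(rbind, rows)
}

#' Modulation study at matched light conductance
#'
#' For each unmodulated operating point on the grid, holds the light
#' conductance fixed, re-equilibrates under each modulation, and emits
#' paired metrics with relative changes.
#'
#' @inheritParams run_sweep_study
#' @param modulations named list of [modulation_state()]s; default:
#'   serotonin, PIP2 depletion, Shab scaled by 0.5 and by 2.
#' @param g_max unmodulated maximal conductances, nS.
#' @return A `data.frame`, one row per voltage x modulation, with the
#'   unmodulated and modulated bandwidth, peak gain, peak contrast gain and
#'   energy cost, plus relative changes.
#' @export
run_modulation_study <- function(channels, membrane = membrane_params(),
                                 V_grid = standard_grid(channels, membrane),
                                 modulations = list(
                                   serotonin = modulation_state(serotonin = TRUE),
                                   pip2 = modulation_state(pip2_depleted = TRUE),
                                   shab_half = modulation_state(shab_scale = 0.5),
                                   shab_double = modulation_state(shab_scale = 2)),
                                 g_max = gbar_default(),
                                 f = default_freq_grid()) {
  rows <- list()
  mod_sets <- lapply(modulations, build_channel_set, g_max = g_max)
  for (V in V_grid) {
    op0 <- solve_balance_at_voltage(V, channels, membrane)
    m0 <- metrics_record(op0, f = f, label = "unmodulated")
    for (nm in names(mod_sets)) {
      op1 <- re_equilibrate(op0, mod_sets[[nm]], membrane)
      m1 <- metrics_record(op1, f = f, label = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        modulation = nm, V_ref_mV = op0$V, V_mod_mV = op1$V,
        g_light_nS = op0$g_light,
        bandwidth_Hz = m0$bandwidth_Hz, bandwidth_mod_Hz = m1$bandwidth_Hz,
        d_bandwidth_rel = m1$bandwidth_Hz / m0$bandwidth_Hz - 1,
        peak_gain_MOhm = m0$peak_gain_MOhm,
        peak_gain_mod_MOhm = m1$peak_gain_MOhm,
        d_peak_gain_rel = m1$peak_gain_MOhm / m0$peak_gain_MOhm - 1,
        peak_contrast_gain_mV = m0$peak_contrast_gain_mV,
        peak_contrast_gain_mod_mV = m1$peak_contrast_gain_mV,
        energy_cost_ATP_s = m0$energy_cost_ATP_s,
        energy_cost_mod_ATP_s = m1$energy_cost_ATP_s,
        d_energy_rel = m1$energy_cost_ATP_s / m0$energy_cost_ATP_s - 1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
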