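# Steady-state ionic balance of the photoreceptor membrane: the light
# conductance, Na+/K+ pump current and Na+/Ca2+ exchanger current that hold
# any depolarisation self-consistent, the dark resting potential, and
# re-equilibration after a channel modulation at fixed light conductance.

#' Membrane parameters of the R1-6 photoreceptor model
#'
#' @param capacitance_pF membrane capacitance, pF.
#' @param E_K potassium reversal potential, mV.
#' @param E_L reversal potential of the light-induced current, mV.
#' @param g_K_leak potassium leak conductance, nS.
#' @param g_L_leak depolarising leak conductance (reversal `E_L`), nS.
#' @param na_frac,ca_frac Na+ and Ca2+ fractions of the light-induced
#'   current; must sum to 1.
#' @param pump_K_in,pump_Na_out Na+/K+ ATPase stoichiometry per ATP
#'   hydrolysed (2 K+ in, 3 Na+ out: net charge 1 e per cycle).
#' @param exch_Na_in,exch_Ca_out Na+/Ca2+ exchanger stoichiometry per cycle
#'   (3 Na+ in, 1 Ca2+ out: net charge 1 e per cycle).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(capacitance_pF = 50, E_K = -85, E_L = 5,
                            g_K_leak = 2.1, g_L_leak = 0.803,
                            na_frac = 0.74, ca_frac = 0.26,
                            pump_K_in = 2, pump_Na_out = 3,
                            exch_Na_in = 3, exch_Ca_out = 1) {
  stopifnot(capacitance_pF > 0, g_K_leak >= 0, g_L_leak >= 0)
  if (abs(na_frac + ca_frac - 1) > 1e-12)
    stop("na_frac and ca_frac must sum to 1")
  q_pump <- pump_Na_out - pump_K_in        # net charge out per pump cycle
  q_exch <- exch_Na_in - 2 * exch_Ca_out   # net charge in per exchanger cycle
  if (q_pump <= 0 || q_exch <= 0)
    stop("pump/exchanger stoichiometry must transport net charge")
  structure(list(capacitance_pF = capacitance_pF, E_K = E_K, E_L = E_L,
                 g_K_leak = g_K_leak, g_L_leak = g_L_leak,
                 na_frac = na_frac, ca_frac = ca_frac,
                 pump_K_in = pump_K_in, pump_Na_out = pump_Na_out,
                 exch_Na_in = exch_Na_in, exch_Ca_out = exch_Ca_out,
                 q_pump = q_pump, q_exch = q_exch),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf(paste0("<membrane_params> C = %g pF, E_K = %g mV, E_L = %g mV, ",
                     "g_K_leak = %g nS, g_L_leak = %g nS\n"),
              x$capacitance_pF, x$E_K, x$E_L, x$g_K_leak, x$g_L_leak))
  invisible(x)
}

#' Solve the ionic balance at a fixed voltage
#'
#' At a voltage `V` with all gates at their steady-state values, the three
#' ionic-balance conditions (net K+, Na+ and Ca2+ currents each zero, with
#' the Na+/K+ pump and Na+/Ca2+ exchanger restoring the fluxes) form a
#' linear system in the light conductance `g_light`, pump current `I_P` and
#' exchanger current `I_E`, solved in closed form. Because the depolarising
#' conductance includes `g_light` itself, the system is solved
#' simultaneously, not sequentially.
#'
#' @param V membrane voltage, mV.
#' @param channels channel set from [build_channel_set()].
#' @param membrane a [membrane_params()].
#' @return An object of class `operating_point`: voltage, `g_light` (nS),
#'   `I_P` and `I_E` (pA), per-channel conductances and gate values, total
#'   K-type and L-type conductances, and a `feasible` flag (`FALSE` when the
#'   solved `g_light` is negative, i.e. `V` below the dark resting
#'   potential).
#' @export
solve_balance_at_voltage <- function(V, channels, membrane = membrane_params()) {
  stopifnot(length(V) == 1L, is.finite(V))
  mb <- membrane
  g_ch <- .set_conductances(channels, V)
  g_K <- sum(g_ch) + mb$g_K_leak
  # K balance: g_K (E_K - V) + (K_in/q_pump) I_P = 0
  cP <- mb$pump_K_in / mb$q_pump
  I_P <- -g_K * (mb$E_K - V) / cP
  # Ca balance: ca_frac g_L (E_L - V) + (2 Ca_out/q_exch) I_E = 0
  cE <- 2 * mb$exch_Ca_out / mb$q_exch
  # Na balance: na_frac g_L (E_L - V) - (Na_out/q_pump) I_P - (Na_in/q_exch) I_E = 0
  # substituting I_E = -(ca_frac/cE) g_L (E_L - V):
  aL <- mb$na_frac + (mb$exch_Na_in / mb$q_exch) * mb$ca_frac / cE
  dl <- mb$E_L - V
  g_L <- if (abs(dl) < 1e-12) Inf else
    (mb$pump_Na_out / mb$q_pump) * I_P / (aL * dl)
  I_E <- -(mb$ca_frac / cE) * g_L * dl
  g_light <- g_L - mb$g_L_leak
  gates <- lapply(channels, steady_gates, V = V)
  res <- c(
    K = g_K * (mb$E_K - V) + cP * I_P,
    Na = mb$na_frac * g_L * dl - (mb$pump_Na_out / mb$q_pump) * I_P -
      (mb$exch_Na_in / mb$q_exch) * I_E,
    Ca = mb$ca_frac * g_L * dl + cE * I_E
  )
  structure(list(V = V, g_light = g_light, I_P = I_P, I_E = I_E,
                 gates = gates, g_channels = g_ch,
                 g_K_total = g_K, g_L_total = g_L,
                 residuals_pA = res,
                 feasible = g_light >= -1e-9,
                 channels = channels, membrane = mb),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> V = %.3f mV, g_light = %.4f nS, I_P = %.3f pA, I_E = %.3f pA%s\n",
              x$V, x$g_light, x$I_P, x$I_E,
              if (x$feasible) "" else " [infeasible: g_light < 0]"))
  g <- x$g_channels
  cat("  g:", paste(sprintf("%s = %.4f nS", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

#' Dark resting potential
#'
#' Finds the unique voltage at which the ionic balance admits zero light
#' conductance, by Brent bracketing on the solved `g_light(V)`.
#'
#' @inheritParams solve_balance_at_voltage
#' @param bracket search interval in mV.
#' @param tol residual tolerance on `g_light` at the root, nS.
#' @return The dark [operating_point].
#' @export
find_dark_rest <- function(channels, membrane = membrane_params(),
                           bracket = c(-90, -30), tol = 1e-9) {
  gfun <- function(V) solve_balance_at_voltage(V, channels, membrane)$g_light
  lo <- gfun(bracket[1]); hi <- gfun(bracket[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop(sprintf(paste0("no sign change of g_light over [%g, %g] mV ",
                        "(g_light = %.4g and %.4g nS)"),
                 bracket[1], bracket[2], lo, hi))
  root <- stats::uniroot(gfun, interval = bracket, tol = 1e-12)
  op <- solve_balance_at_voltage(root$root, channels, membrane)
  if (abs(op$g_light) > tol)
    stop(sprintf("dark-rest root did not converge: |g_light| = %.3g nS",
                 abs(op$g_light)))
  # the dark point has zero light conductance by definition; clamp the
  # root-finder remainder (< tol) away
  op$g_light <- 0
  op$feasible <- TRUE
  op
}

#' Operating points along a light-depolarisation sweep
#'
#' @inheritParams solve_balance_at_voltage
#' @param V_grid voltages in mV, at or above the dark resting potential.
#' @return List of [operating_point]s (class `operating_sweep`); points below
#'   the dark resting potential are flagged infeasible.
#' @export
sweep_light_levels <- function(V_grid, channels, membrane = membrane_params()) {
  ops <- lapply(V_grid, solve_balance_at_voltage, channels = channels,
                membrane = membrane)
  structure(ops, class = "operating_sweep")
}

#' @export
as.data.frame.operating_sweep <- function(x, ...) {
  do.call(rbind, lapply(x, function(op) {
    data.frame(V_mV = op$V, g_light_nS = op$g_light, I_P_pA = op$I_P,
               I_E_pA = op$I_E,
               g_shaker_nS = op$g_channels[["shaker"]],
               g_shab_nS = op$g_channels[["shab"]],
               g_novel_nS = op$g_channels[["novel"]],
               feasible = op$feasible)
  }))
}

#' Standard voltage grid of the study
#'
#' The dark resting potential of the supplied channel set followed by the
#' depolarisations named throughout the analysis: -59, -52, -44, -41 and
#' -36 mV (the chosen maximum steady-state depolarisation).
#'
#' @inheritParams solve_balance_at_voltage
#' @return Numeric vector of voltages, mV.
#' @export
standard_grid <- function(channels, membrane = membrane_params()) {
  c(find_dark_rest(channels, membrane)$V, -59, -52, -44, -41, -36)
}

#' Re-equilibrate after a channel modulation
#'
#' Keeps the light (and leak) conductance at its reference value and finds
#' the new steady-state voltage under a modulated channel set; the pump and
#' exchanger currents change accordingly.
#'
#' @param reference an [operating_point] solved under the unmodulated
#'   channels.
#' @param modulated_channels channel set built under the new
#'   [modulation_state()].
#' @inheritParams solve_balance_at_voltage
#' @param bracket voltage search interval, mV.
#' @return The modulated [operating_point] (carries the reference voltage as
#'   attribute `V_reference`).
#' @export
re_equilibrate <- function(reference, modulated_channels,
                           membrane = membrane_params(),
                           bracket = c(-90, -15)) {
  stopifnot(inherits(reference, "operating_point"))
  target <- reference$g_light
  f <- function(V) {
    solve_balance_at_voltage(V, modulated_channels, membrane)$g_light - target
  }
  root <- stats::uniroot(f, interval = bracket, tol = 1e-12)
  op <- solve_balance_at_voltage(root$root, modulated_channels, membrane)
  attr(op, "V_reference") <- reference$V
  op
}
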