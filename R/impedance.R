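# Small-signal membrane impedance from the equivalent RrLC circuit: each
# voltage-dependent conductance component contributes a steady resistance R,
# an activation branch (r, L) and - if it inactivates - an inactivation
# branch (r_h, L_h) with negative element values, all shunting the membrane
# capacitance together with the leaks and the light conductance.
#
# Element units: R, r, r_h in GOhm (1/nS); L, L_h in GOhm*s; tau in s.

#' Freeze specification for gating variables
#'
#' Selects which gating variables are kept fixed at their operating-point
#' steady-state values when computing impedance or dynamics. A frozen gate
#' contributes its steady conductance but no feedback branch.
#'
#' @param shaker,shab,novel character vectors, any of `"m"` (activation) and
#'   `"h"` (all inactivation modes of that channel).
#' @return An object of class `freeze_spec`.
#' @export
freeze_spec <- function(shaker = character(), shab = character(),
                        novel = character()) {
  chk <- function(x) {
    x <- as.character(x)
    if (!all(x %in% c("m", "h"))) stop("freeze entries must be 'm' or 'h'")
    unique(x)
  }
  structure(list(shaker = chk(shaker), shab = chk(shab), novel = chk(novel)),
            class = "freeze_spec")
}

#' @rdname freeze_spec
#' @export
freeze_none <- function() freeze_spec()

#' @rdname freeze_spec
#' @export
freeze_all <- function() freeze_spec(c("m", "h"), c("m", "h"), c("m", "h"))

#' @rdname freeze_spec
#' @export
freeze_inactivation <- function() freeze_spec("h", "h", "h")

#' Freeze every channel except one
#'
#' @param active name of the channel left active (`"shaker"`, `"shab"` or
#'   `"novel"`).
#' @rdname freeze_spec
#' @export
freeze_all_but <- function(active = c("shaker", "shab", "novel")) {
  active <- match.arg(active)
  fs <- freeze_all()
  fs[[active]] <- character()
  fs
}

.is_frozen <- function(freeze, channel_name, gate) {
  gate %in% freeze[[channel_name]]
}

#' RrLC elements of one conductance component
#'
#' For a component with maximal conductance `gbar_k = fraction * g_max`,
#' activation `m^gamma` and (optionally) a single inactivation mode `h`, the
#' linearised elements at an operating point are
#' `R = 1/(gbar_k m^gamma h)`,
#' `r = 1/((V - E_K) gbar_k h d(m_inf^gamma)/dV)`, `L = tau_m r`,
#' `r_h = 1/((V - E_K) gbar_k m^gamma dh_inf/dV)`, `L_h = tau_h r_h`.
#' For a K+ conductance above `E_K`, `r` and `L` are positive while `r_h`
#' and `L_h` are negative. A zero slope or `V = E_K` makes a branch
#' resistance infinite: the branch is reported absent, never as a division
#' error. Frozen gates likewise remove their branch.
#'
#' @param channel a [channel_model()].
#' @param comp index of the inactivation component.
#' @param op an [operating_point].
#' @param freeze_m,freeze_h logical; drop the corresponding branch.
#' @return List with `R`, `r`, `L`, `r_h`, `L_h` (GOhm, GOhm*s; `NA` for
#'   absent branches), `tau_m_s`, `tau_h_s`, `g_steady_nS`, and the branch
#'   conductances `inv_r_nS`, `inv_rh_nS` (0 for absent branches).
#' @export
branch_elements <- function(channel, comp, op, freeze_m = FALSE,
                            freeze_h = FALSE) {
  stopifnot(inherits(channel, "channel_model"), inherits(op, "operating_point"))
  V <- op$V
  E <- channel$reversal
  cc <- channel$components[[comp]]
  gbar_k <- channel$g_max * cc$fraction
  m <- gating_value(channel$activation, V)
  gam <- channel$gamma
  h <- if (is.null(cc$h)) 1 else gating_value(cc$h, V)
  g_steady <- gbar_k * m^gam * h
  drive <- V - E
  R <- if (g_steady > 0) 1 / g_steady else Inf

  inv_r <- 0; tau_m_s <- NA_real_
  if (!freeze_m && gbar_k > 0) {
    dmg <- gam * m^(gam - 1) * gating_slope(channel$activation, V)
    inv_r <- drive * gbar_k * h * dmg
    tau_m_s <- gating_tau(channel$activation, V) * 1e-3
  }
  inv_rh <- 0; tau_h_s <- NA_real_
  if (!freeze_h && !is.null(cc$h) && !isTRUE(cc$frozen) && gbar_k > 0) {
    dh <- gating_slope(cc$h, V)
    inv_rh <- drive * gbar_k * m^gam * dh
    tau_h_s <- gating_tau(cc$h, V) * 1e-3
  }
  r <- if (inv_r != 0) 1 / inv_r else NA_real_
  r_h <- if (inv_rh != 0) 1 / inv_rh else NA_real_
  list(R = R, r = r, L = if (is.na(r)) NA_real_ else tau_m_s * r,
       r_h = r_h, L_h = if (is.na(r_h)) NA_real_ else tau_h_s * r_h,
       tau_m_s = tau_m_s, tau_h_s = tau_h_s,
       g_steady_nS = g_steady, inv_r_nS = inv_r, inv_rh_nS = inv_rh)
}

#' Impedance of one RrLC component
#'
#' `1/Z_c(f) = 1/R + (1/r)/(1 + i 2 pi f tau_m) + (1/r_h)/(1 + i 2 pi f tau_h)`,
#' with absent branches contributing nothing.
#'
#' @param branch output of [branch_elements()].
#' @param f frequency, Hz (vectorised, `>= 0`).
#' @return Complex impedance in GOhm.
#' @export
component_impedance <- function(branch, f) {
  Y <- .component_admittance(branch, f)
  1 / Y
}

# Complex admittance (nS) of one component at frequencies f.
.component_admittance <- function(branch, f) {
  w <- 2i * pi * f
  Y <- rep(1 / branch$R, length(f)) + 0i
  if (!is.na(branch$r) && branch$inv_r_nS != 0)
    Y <- Y + branch$inv_r_nS / (1 + w * branch$tau_m_s)
  if (!is.na(branch$r_h) && branch$inv_rh_nS != 0)
    Y <- Y + branch$inv_rh_nS / (1 + w * branch$tau_h_s)
  Y
}

# All branch-element sets of an operating point under a freeze spec.
.op_branches <- function(op, freeze = freeze_none()) {
  out <- list()
  for (nm in names(op$channels)) {
    ch <- op$channels[[nm]]
    fm <- .is_frozen(freeze, nm, "m")
    fh <- .is_frozen(freeze, nm, "h")
    for (k in seq_along(ch$components)) {
      out[[length(out) + 1L]] <- branch_elements(ch, k, op, fm, fh)
    }
  }
  out
}

#' Default logarithmic frequency grid
#'
#' 400 points, 0.1-1000 Hz; resolves both the sub-2 Hz amplification window
#' and the corner region.
#'
#' @return Numeric vector of frequencies, Hz.
#' @export
default_freq_grid <- function() 10^seq(log10(0.1), log10(1000), length.out = 400)

#' Membrane impedance spectrum
#'
#' Total small-signal impedance of the photoreceptor at an operating point:
#' the component admittances of all (unfrozen) conductance branches, the two
#' leak conductances, the steady light conductance and the capacitive
#' admittance in parallel. The pump and exchanger are fixed currents and do
#' not load the membrane.
#'
#' @param op an [operating_point].
#' @param freeze a [freeze_spec()].
#' @param f frequency grid, Hz (non-empty).
#' @return An object of class `impedance_spectrum`: `f` (Hz), complex `Z`
#'   (GOhm), the DC total conductance `g_total_nS` (chord conductance: all
#'   steady conductances plus leaks plus light), voltage and provenance.
#'   Carries a closure `zfun(f)` for exact off-grid evaluation.
#' @export
membrane_impedance <- function(op, freeze = freeze_none(),
                               f = default_freq_grid()) {
  stopifnot(inherits(op, "operating_point"))
  if (length(f) == 0) stop("frequency grid must be non-empty")
  mb <- op$membrane
  branches <- .op_branches(op, freeze)
  g_shunt <- mb$g_K_leak + mb$g_L_leak + max(op$g_light, 0)
  C <- mb$capacitance_pF
  zfun <- function(f) {
    Y <- g_shunt + 2i * pi * f * C * 1e-3  # nS; f Hz * pF -> 1e-3 nS
    for (b in branches) Y <- Y + .component_admittance(b, f)
    1 / Y
  }
  g_total <- g_shunt + sum(vapply(branches, `[[`, numeric(1), "g_steady_nS"))
  structure(list(f = f, Z = zfun(f), V = op$V, g_total_nS = g_total,
                 freeze = freeze, zfun = zfun, op = op),
            class = "impedance_spectrum")
}

#' Passive-equivalent impedance spectrum
#'
#' Shortcut for [membrane_impedance()] with every gating variable frozen: a
#' pure RC membrane with the operating point's total conductance and the
#' membrane capacitance.
#'
#' @inheritParams membrane_impedance
#' @return An `impedance_spectrum`.
#' @export
passive_equivalent <- function(op, f = default_freq_grid()) {
  membrane_impedance(op, freeze_all(), f)
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<impedance_spectrum> V = %.2f mV, %d frequencies ",
                     "[%.3g, %.3g] Hz, |Z(min f)| = %.1f MOhm\n"),
              x$V, length(x$f), min(x$f), max(x$f), 1000 * abs(x$Z[1])))
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(f_Hz = x$f, Re_Z_GOhm = Re(x$Z), Im_Z_GOhm = Im(x$Z),
             abs_Z_MOhm = 1000 * abs(x$Z))
}

#' Input resistance
#'
#' The low-frequency limit of the active membrane impedance (all branches
#' included), evaluated at 0.001 Hz.
#'
#' @inheritParams membrane_impedance
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(op, freeze = freeze_none()) {
  sp <- membrane_impedance(op, freeze, f = 1e-3)
  1000 * abs(sp$Z[1])
}

# ---- pole analysis ----------------------------------------------------------

# Polynomial helpers: coefficient vectors in increasing powers of s.
.poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Poles of the membrane impedance
#'
#' The total admittance Y(s) is a rational function of the complex frequency
#' s; the poles of Z = 1/Y are the zeros of Y's numerator polynomial. A
#' stable linearisation has every pole in the open left half-plane.
#'
#' @inheritParams membrane_impedance
#' @return Complex vector of poles (rad/s).
#' @export
impedance_poles <- function(op, freeze = freeze_none()) {
  mb <- op$membrane
  branches <- .op_branches(op, freeze)
  g_shunt <- mb$g_K_leak + mb$g_L_leak + max(op$g_light, 0)
  # collect terms: each is c/(1 + s*tau); plus constant g0 and s*C
  taus <- c(); coefs <- c()
  g0 <- g_shunt
  for (b in branches) {
    g0 <- g0 + 1 / b$R
    if (!is.na(b$r) && b$inv_r_nS != 0) {
      taus <- c(taus, b$tau_m_s); coefs <- c(coefs, b$inv_r_nS)
    }
    if (!is.na(b$r_h) && b$inv_rh_nS != 0) {
      taus <- c(taus, b$tau_h_s); coefs <- c(coefs, b$inv_rh_nS)
    }
  }
  C_nS_s <- mb$capacitance_pF * 1e-3  # nS * s
  den <- 1
  for (tt in taus) den <- .poly_mul(den, c(1, tt))
  num <- .poly_mul(c(g0, C_nS_s), den)
  for (i in seq_along(taus)) {
    d_i <- 1
    for (j in seq_along(taus)) if (j != i) d_i <- .poly_mul(d_i, c(1, taus[j]))
    term <- coefs[i] * d_i
    num[seq_along(term)] <- num[seq_along(term)] + term
  }
  polyroot(num)
}
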