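# Hodgkin-Huxley gating mathematics of the three voltage-dependent K+
# conductances of Drosophila R1-6 photoreceptors: Shaker, Shab and the
# "Novel" conductance, plus their neuromodulated variants.
#
# Units: voltage mV, time constants ms, conductances nS.

# x / (1 - exp(-x/s)): the linear-over-exponential factor common to HH rate
# formulas. Removable singularity at x = 0 (limit s), guarded within 1e-9 mV.
.lininv <- function(x, s) {
  out <- ifelse(abs(x) < 1e-9, s, x / (1 - exp(-x / s)))
  out
}

# Rising logistic sigma(V) = 1/(1 + exp((vh - V)/s)) and its derivative.
.logis_up <- function(V, vh, s) 1 / (1 + exp((vh - V) / s))
.dlogis_up <- function(V, vh, s) {
  p <- .logis_up(V, vh, s)
  p * (1 - p) / s
}
# Falling logistic 1/(1 + exp((vh + V)/s)) (inactivation style) and derivative.
.logis_down <- function(V, vh, s) 1 / (1 + exp((vh + V) / s))
.dlogis_down <- function(V, vh, s) {
  p <- .logis_down(V, vh, s)
  -p * (1 - p) / s
}

#' Construct a gating scheme
#'
#' A gating scheme bundles the steady-state curve, voltage-dependent time
#' constant and the closed-form derivative of the steady-state curve for one
#' Hodgkin-Huxley gating variable.
#'
#' @param inf function of voltage (mV) returning the steady-state value in
#'   (0, 1).
#' @param tau function of voltage (mV) returning the time constant in ms.
#' @param dinf function of voltage (mV) returning d(inf)/dV in 1/mV.
#' @param type `"activation"` (monotonically increasing steady state) or
#'   `"inactivation"` (decreasing).
#' @param label short identifier used in printouts.
#' @return An object of class `gating_scheme`.
#' @export
gating_scheme <- function(inf, tau, dinf, type = c("activation", "inactivation"),
                          label = "") {
  type <- match.arg(type)
  stopifnot(is.function(inf), is.function(tau), is.function(dinf))
  structure(list(inf = inf, tau = tau, dinf = dinf, type = type, label = label),
            class = "gating_scheme")
}

#' Evaluate a gating scheme
#'
#' @param scheme a [gating_scheme()].
#' @param V membrane voltage in mV (finite, vectorised).
#' @return `gating_value()` the steady-state value (dimensionless, in (0,1));
#'   `gating_tau()` the time constant in ms; `gating_slope()` the derivative
#'   of the steady-state curve in 1/mV.
#' @export
gating_value <- function(scheme, V) {
  stopifnot(inherits(scheme, "gating_scheme"), all(is.finite(V)))
  scheme$inf(V)
}

#' @rdname gating_value
#' @export
gating_tau <- function(scheme, V) {
  stopifnot(inherits(scheme, "gating_scheme"), all(is.finite(V)))
  scheme$tau(V)
}

#' @rdname gating_value
#' @export
gating_slope <- function(scheme, V) {
  stopifnot(inherits(scheme, "gating_scheme"), all(is.finite(V)))
  scheme$dinf(V)
}

# ---- Shaker -----------------------------------------------------------------

# Shaker activation: m_inf = sigma^(1/3), fast tau with a removable
# singularity at V = -59.6 mV. Serotonin replaces the steady-state curve and
# evaluates the time constant 31.4 mV rightward.
.shaker_m_scheme <- function(serotonin = FALSE) {
  tau_base <- function(V) {
    1 / (0.00817 * exp(-(V + 1.62) / 24.7) + 0.0581 * .lininv(V + 59.6, 4.50))
  }
  if (!serotonin) {
    inf <- function(V) .logis_up(V, -23.7, 12.8)^(1 / 3)
    dinf <- function(V) {
      p <- .logis_up(V, -23.7, 12.8)
      (1 / 3) * p^(1 / 3 - 1) * .dlogis_up(V, -23.7, 12.8)
    }
    tau <- tau_base
  } else {
    inf <- function(V) .logis_up(V, 11.7, 12.9)^(1 / 3)
    dinf <- function(V) {
      p <- .logis_up(V, 11.7, 12.9)
      (1 / 3) * p^(1 / 3 - 1) * .dlogis_up(V, 11.7, 12.9)
    }
    tau <- function(V) tau_base(V - 31.4)
  }
  gating_scheme(inf, tau, dinf, "activation", "Shaker m")
}

# Shaker inactivation h1 (the 87% that does inactivate): double-logistic
# steady state, tau with a removable singularity at V = 13.5 mV.
.shaker_h_scheme <- function(serotonin = FALSE) {
  tau_base <- function(V) {
    1 / (0.230 * exp(-(V + 193.0) / 31.3) + 0.0437 * .lininv(V - 13.5, 11.1))
  }
  if (!serotonin) {
    inf <- function(V) 0.8 * .logis_down(V, 55.3, 3.9) + 0.2 * .logis_down(V, 74.8, 10.7)
    dinf <- function(V) 0.8 * .dlogis_down(V, 55.3, 3.9) + 0.2 * .dlogis_down(V, 74.8, 10.7)
    tau <- tau_base
  } else {
    inf <- function(V) 0.8 * .logis_down(V, 27.1, 4.3) + 0.2 * .logis_down(V, 52.9, 10.5)
    dinf <- function(V) 0.8 * .dlogis_down(V, 27.1, 4.3) + 0.2 * .dlogis_down(V, 52.9, 10.5)
    tau <- function(V) tau_base(V - 25)
  }
  gating_scheme(inf, tau, dinf, "inactivation", "Shaker h1")
}

# ---- Shab -------------------------------------------------------------------

# Shab activation: m_inf = sigma^(1/2). PIP2 depletion shifts the steady-state
# curve 10 mV leftward (argument V + 10), time constants untouched. Serotonin
# replaces the steady-state curve and shifts the time constant 13.7 mV.
.shab_m_scheme <- function(serotonin = FALSE, pip2 = FALSE) {
  dv <- if (pip2) 10 else 0
  tau_base <- function(V) {
    1 / (0.116 * exp(-(V + 25.7) / 32.2) + 0.00659 * .lininv(V + 23.8, 1.35))
  }
  if (!serotonin) {
    inf <- function(V) .logis_up(V + dv, -1, 9.1)^(1 / 2)
    dinf <- function(V) {
      p <- .logis_up(V + dv, -1, 9.1)
      (1 / 2) * p^(-1 / 2) * .dlogis_up(V + dv, -1, 9.1)
    }
    tau <- tau_base
  } else {
    inf <- function(V) .logis_up(V + dv, 12.7, 9.5)^(1 / 2)
    dinf <- function(V) {
      p <- .logis_up(V + dv, 12.7, 9.5)
      (1 / 2) * p^(-1 / 2) * .dlogis_up(V + dv, 12.7, 9.5)
    }
    tau <- function(V) tau_base(V - 13.7)
  }
  gating_scheme(inf, tau, dinf, "activation", "Shab m")
}

# Shab inactivation: both modes share one steady-state curve; the fast mode
# has a voltage-dependent tau, the slow mode a constant 3000 ms.
.shab_h_scheme <- function(mode = c("fast", "slow"), serotonin = FALSE) {
  mode <- match.arg(mode)
  if (!serotonin) {
    inf <- function(V) .logis_down(V, 25.7, 6.4)
    dinf <- function(V) .dlogis_down(V, 25.7, 6.4)
    shift <- 0
  } else {
    inf <- function(V) .logis_down(V, 15.7, 7.2)
    dinf <- function(V) .dlogis_down(V, 15.7, 7.2)
    shift <- 10
  }
  tau <- if (mode == "fast") {
    function(V) 335 * exp((V - shift) / 71.3) + 73.2
  } else {
    function(V) rep(3000, length(V))
  }
  gating_scheme(inf, tau, dinf, "inactivation",
                paste0("Shab h", if (mode == "fast") "1" else "2"))
}

# ---- Novel ------------------------------------------------------------------

# Non-inactivating conductance found in shaker,shab double mutants; very slow
# Gaussian-peaked activation time constant (peak 178 ms at -19.4 mV).
.novel_m_scheme <- function() {
  inf <- function(V) .logis_up(V, -1, 9.1)^(1 / 2)
  dinf <- function(V) {
    p <- .logis_up(V, -1, 9.1)
    (1 / 2) * p^(-1 / 2) * .dlogis_up(V, -1, 9.1)
  }
  tau <- function(V) 13 + 165 * exp(-2 * ((V + 19.4) / 30)^2)
  gating_scheme(inf, tau, dinf, "activation", "Novel m")
}

# ---- Channel models ---------------------------------------------------------

#' Modulation state of the K+ conductances
#'
#' @param serotonin logical; apply the serotonin shifts to Shaker and Shab
#'   (steady-state curves replaced by the shifted fits; time constants
#'   evaluated at shifted voltages: Shaker activation -31.4 mV, Shaker
#'   inactivation -25 mV, Shab activation -13.7 mV, Shab fast inactivation
#'   -10 mV).
#' @param pip2_depleted logical; apply the PIP2-depletion (light-dependent
#'   modulation) 10 mV leftward shift of the Shab steady-state activation
#'   curve.
#' @param shab_scale positive multiplier on the maximal Shab conductance
#'   (calmodulin modulation); 1 leaves it untouched.
#' @return An object of class `modulation_state`.
#' @export
modulation_state <- function(serotonin = FALSE, pip2_depleted = FALSE,
                             shab_scale = 1.0) {
  stopifnot(is.logical(serotonin), length(serotonin) == 1L, !is.na(serotonin),
            is.logical(pip2_depleted), length(pip2_depleted) == 1L,
            !is.na(pip2_depleted),
            is.numeric(shab_scale), length(shab_scale) == 1L,
            is.finite(shab_scale))
  if (shab_scale <= 0) stop("shab_scale must be > 0")
  structure(list(serotonin = serotonin, pip2_depleted = pip2_depleted,
                 shab_scale = shab_scale),
            class = "modulation_state")
}

#' @export
print.modulation_state <- function(x, ...) {
  cat("Modulation: serotonin=", x$serotonin,
      ", pip2_depleted=", x$pip2_depleted,
      ", shab_scale=", x$shab_scale, "\n", sep = "")
  invisible(x)
}

#' Construct a channel model
#'
#' A channel is `g = g_max * h * m^gamma`, where the composite inactivation
#' `h` is a fraction-weighted sum over inactivation components (a component
#' with `h = NULL` does not inactivate and contributes its fraction as a
#' constant).
#'
#' @param name channel identifier.
#' @param g_max maximal conductance, nS (>= 0).
#' @param gamma activation exponent (1, 2 or 3).
#' @param activation a [gating_scheme()] for the activation variable.
#' @param components list of `list(fraction =, h =)` inactivation components;
#'   fractions must sum to 1.
#' @param reversal reversal potential, mV.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(name, g_max, gamma, activation, components,
                          reversal = -85) {
  if (!is.numeric(g_max) || length(g_max) != 1L || !is.finite(g_max) || g_max < 0)
    stop("g_max must be a single non-negative number")
  if (!gamma %in% c(1L, 2L, 3L)) stop("gamma must be 1, 2 or 3")
  stopifnot(inherits(activation, "gating_scheme"))
  fr <- vapply(components, function(cc) cc$fraction, numeric(1))
  if (any(fr < 0 | fr > 1)) stop("component fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-12) stop("component fractions must sum to 1")
  structure(list(name = name, g_max = g_max, gamma = as.integer(gamma),
                 activation = activation, components = components,
                 reversal = reversal),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> %s: g_max = %.4g nS, gamma = %d, %d component(s)\n",
              x$name, x$g_max, x$gamma, length(x$components)))
  invisible(x)
}

#' Build the Shaker, Shab and Novel channel set
#'
#' Assembles the three voltage-dependent K+ channels of the R1-6
#' photoreceptor under a given modulation state. Modulations compose: with
#' both serotonin and PIP2 depletion active, the serotonin Shab activation
#' curve is evaluated with the PIP2-shifted voltage argument.
#'
#' @param modulation a [modulation_state()].
#' @param g_max named numeric vector `c(shaker =, shab =, novel =)` of
#'   maximal conductances in nS; defaults to the calibrated values
#'   [gbar_default()]. `shab_scale` multiplies the Shab entry.
#' @param E_K potassium reversal potential, mV.
#' @return Named list of three [channel_model()] objects
#'   (`shaker`, `shab`, `novel`).
#' @export
build_channel_set <- function(modulation = modulation_state(),
                              g_max = gbar_default(), E_K = -85) {
  if (!inherits(modulation, "modulation_state"))
    stop("modulation must be a modulation_state")
  g_max <- g_max[c("shaker", "shab", "novel")]
  if (anyNA(g_max)) stop("g_max must be named: shaker, shab, novel")
  if (any(g_max < 0)) stop("g_max values must be non-negative")
  ser <- modulation$serotonin
  pip2 <- modulation$pip2_depleted
  shaker <- channel_model(
    "Shaker", unname(g_max["shaker"]), 3L, .shaker_m_scheme(ser),
    components = list(
      list(fraction = 0.13, h = NULL),
      list(fraction = 0.87, h = .shaker_h_scheme(ser))
    ), reversal = E_K)
  shab <- channel_model(
    "Shab", unname(g_max["shab"]) * modulation$shab_scale, 2L,
    .shab_m_scheme(ser, pip2),
    components = list(
      list(fraction = 0.7, h = .shab_h_scheme("fast", ser)),
      list(fraction = 0.3, h = .shab_h_scheme("slow", ser))
    ), reversal = E_K)
  novel <- channel_model(
    "Novel", unname(g_max["novel"]), 1L, .novel_m_scheme(),
    components = list(list(fraction = 1, h = NULL)), reversal = E_K)
  out <- list(shaker = shaker, shab = shab, novel = novel)
  attr(out, "modulation") <- modulation
  out
}

#' Steady-state gate values of a channel
#'
#' @param channel a [channel_model()].
#' @param V voltage, mV.
#' @return List with `m` (activation value) and `h` (numeric vector, one
#'   entry per inactivation component; 1 for non-inactivating components).
#' @export
steady_gates <- function(channel, V) {
  stopifnot(inherits(channel, "channel_model"), length(V) == 1L, is.finite(V))
  h <- vapply(channel$components, function(cc) {
    if (is.null(cc$h)) 1 else gating_value(cc$h, V)
  }, numeric(1))
  list(m = gating_value(channel$activation, V), h = h)
}

#' Channel conductance at given gate values
#'
#' `g = g_max * m^gamma * sum_k fraction_k * h_k`, additive over the
#' inactivation components.
#'
#' @param channel a [channel_model()].
#' @param gates list with `m` and `h` as returned by [steady_gates()].
#' @return Conductance in nS, guaranteed in `[0, g_max]`.
#' @export
channel_conductance <- function(channel, gates) {
  stopifnot(inherits(channel, "channel_model"))
  m <- gates$m
  h <- gates$h
  if (length(h) != length(channel$components))
    stop("one h value per inactivation component is required")
  if (any(c(m, h) < 0) || any(c(m, h) > 1))
    stop("gate values must lie in [0, 1]")
  fr <- vapply(channel$components, function(cc) cc$fraction, numeric(1))
  channel$g_max * m^channel$gamma * sum(fr * h)
}

# Steady-state conductance of every channel in a set, named nS vector.
.set_conductances <- function(channels, V) {
  vapply(channels, function(ch) channel_conductance(ch, steady_gates(ch, V)),
         numeric(1))
}

#' Freeze the inactivation gates of a channel at reference values
#'
#' Returns a channel whose inactivation components are pinned to the values
#' they take at the reference voltage: their steady-state curves become
#' constants with zero slope, so they contribute neither dynamics nor an
#' inactivation branch to the linearised impedance.
#'
#' @param channel a [channel_model()].
#' @param V_ref reference voltage (mV) supplying the frozen values, or
#'   `h_ref` directly.
#' @param h_ref optional numeric vector of frozen values (overrides `V_ref`).
#' @return A [channel_model()] with constant inactivation.
#' @export
freeze_channel_inactivation <- function(channel, V_ref = NULL, h_ref = NULL) {
  stopifnot(inherits(channel, "channel_model"))
  if (is.null(h_ref)) {
    stopifnot(!is.null(V_ref))
    h_ref <- steady_gates(channel, V_ref)$h
  }
  comps <- channel$components
  for (k in seq_along(comps)) {
    if (is.null(comps[[k]]$h)) next
    hk <- h_ref[k]
    comps[[k]]$h <- gating_scheme(
      inf = local({ v <- hk; function(V) rep(v, length(V)) }),
      tau = function(V) rep(1, length(V)),
      dinf = function(V) rep(0, length(V)),
      type = "inactivation",
      label = paste0(comps[[k]]$h$label, " (frozen)"))
    comps[[k]]$frozen <- TRUE
  }
  channel$components <- comps
  channel
}

#' Accelerate inactivation to activation speed
#'
#' Replaces the inactivation time constants of each channel by that channel's
#' activation time constant, leaving all steady-state curves untouched. Used
#' to model hypothetical conductances whose inactivation is as fast as their
#' activation.
#'
#' @param channels channel set from [build_channel_set()].
#' @return Channel set with modified inactivation kinetics.
#' @export
accelerate_channel_inactivation <- function(channels) {
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    tau_m <- ch$activation$tau
    for (k in seq_along(ch$components)) {
      hk <- ch$components[[k]]$h
      if (is.null(hk) || isTRUE(ch$components[[k]]$frozen)) next
      ch$components[[k]]$h <- gating_scheme(hk$inf, tau_m, hk$dinf,
                                            "inactivation",
                                            paste0(hk$label, " (accelerated)"))
    }
    channels[[nm]] <- ch
  }
  channels
}
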