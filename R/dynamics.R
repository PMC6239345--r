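# Time-domain Hodgkin-Huxley integration of the photoreceptor membrane:
# current-pulse responses with selective gate freezing and (optionally)
# inactivation accelerated to activation speed, plus a multisine small-signal
# impedance estimator used as the independent oracle for the analytic RrLC
# linearisation.
#
# The pump and exchanger currents are held at their steady-state values
# during dynamics; injected depolarising current is positive.

#' Current-pulse protocol
#'
#' @param amplitude_nA injected current amplitude, nA (depolarising
#'   positive).
#' @param duration_ms pulse duration, ms (> 0).
#' @param pre_ms,post_ms margins before and after the pulse, ms.
#' @param dt_ms fixed integration step, ms.
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(amplitude_nA = 0.01, duration_ms = 150,
                           pre_ms = 20, post_ms = 150, dt_ms = 0.01) {
  stopifnot(duration_ms > 0, dt_ms > 0, pre_ms >= 0, post_ms >= 0)
  structure(list(amplitude_nA = amplitude_nA, duration_ms = duration_ms,
                 pre_ms = pre_ms, post_ms = post_ms, dt_ms = dt_ms),
            class = "pulse_protocol")
}

# Build the dynamical system at an operating point: initial state (voltage
# plus unfrozen gates), right-hand side for deSolve, and bookkeeping.
.build_dyn <- function(op, freeze = freeze_none(),
                       accelerate_inactivation = FALSE) {
  mb <- op$membrane
  chans <- op$channels
  spec <- list(); y0 <- c(V = op$V)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    g0 <- op$gates[[nm]]
    fm <- .is_frozen(freeze, nm, "m")
    fh <- .is_frozen(freeze, nm, "h")
    s <- list(g_max = ch$g_max, gamma = ch$gamma, E = ch$reversal,
              minf = ch$activation$inf, mtau = ch$activation$tau,
              m_state = NA_integer_, m_fixed = g0$m,
              fr = vapply(ch$components, `[[`, numeric(1), "fraction"),
              h_state = rep(NA_integer_, length(ch$components)),
              h_fixed = g0$h, hinf = vector("list", length(ch$components)),
              htau = vector("list", length(ch$components)))
    if (!fm) {
      y0 <- c(y0, stats::setNames(g0$m, paste0(nm, ".m")))
      s$m_state <- length(y0)
    }
    for (k in seq_along(ch$components)) {
      cc <- ch$components[[k]]
      if (is.null(cc$h) || isTRUE(cc$frozen) || fh) next
      y0 <- c(y0, stats::setNames(g0$h[k], paste0(nm, ".h", k)))
      s$h_state[k] <- length(y0)
      s$hinf[[k]] <- cc$h$inf
      s$htau[[k]] <- if (accelerate_inactivation) ch$activation$tau else cc$h$tau
    }
    spec[[nm]] <- s
  }
  g_shunt_L <- mb$g_L_leak + max(op$g_light, 0)
  I_const <- -(op$I_P + op$I_E)  # pA, fixed during dynamics
  C <- mb$capacitance_pF
  rhs <- function(t, y, parms) {
    V <- y[1]
    dy <- numeric(length(y))
    I <- mb$g_K_leak * (mb$E_K - V) + g_shunt_L * (mb$E_L - V) + I_const +
      parms$iinj(t)
    for (s in spec) {
      m <- if (is.na(s$m_state)) s$m_fixed else y[s$m_state]
      h <- s$h_fixed
      for (k in seq_along(s$fr)) {
        if (!is.na(s$h_state[k])) h[k] <- y[s$h_state[k]]
      }
      I <- I + s$g_max * m^s$gamma * sum(s$fr * h) * (s$E - V)
      if (!is.na(s$m_state))
        dy[s$m_state] <- (s$minf(V) - m) / s$mtau(V)
      for (k in seq_along(s$fr)) {
        if (!is.na(s$h_state[k]))
          dy[s$h_state[k]] <- (s$hinf[[k]](V) - h[k]) / s$htau[[k]](V)
      }
    }
    dy[1] <- I / C  # pA / pF = mV / ms
    list(dy)
  }
  list(y0 = y0, rhs = rhs)
}

#' Simulate a current-pulse response
#'
#' Integrates `C dV/dt = sum g_x (E_x - V) - I_P - I_E + I_inj(t)` together
#' with first-order kinetics for every unfrozen gating variable, using a
#' fixed-step 4th-order Runge-Kutta scheme. Frozen gates stay at the
#' operating-point values; `accelerate_inactivation` substitutes each
#' channel's activation time constant for its inactivation time constants.
#'
#' @param op an [operating_point].
#' @param protocol a [pulse_protocol()].
#' @param freeze a [freeze_spec()].
#' @param accelerate_inactivation logical.
#' @return An object of class `voltage_trace`: `time_ms`, `V_mV`, a matrix
#'   of gate trajectories, and the protocol.
#' @export
simulate_pulse <- function(op, protocol = pulse_protocol(),
                           freeze = freeze_none(),
                           accelerate_inactivation = FALSE) {
  stopifnot(inherits(op, "operating_point"), inherits(protocol, "pulse_protocol"))
  p <- protocol
  amp_pA <- p$amplitude_nA * 1000
  dyn <- .build_dyn(op, freeze, accelerate_inactivation)
  # integrate the three constant-input segments separately so the pulse
  # edges never fall inside a Runge-Kutta step
  segs <- list(c(0, p$pre_ms, 0),
               c(p$pre_ms, p$pre_ms + p$duration_ms, amp_pA),
               c(p$pre_ms + p$duration_ms,
                 p$pre_ms + p$duration_ms + p$post_ms, 0))
  y <- dyn$y0
  out <- NULL
  for (s in segs) {
    if (s[2] <= s[1]) next
    times <- seq(s[1], s[2], by = p$dt_ms)
    iamp <- s[3]
    sol <- deSolve::ode(y = y, times = times, func = dyn$rhs,
                        parms = list(iinj = function(t) iamp), method = "rk4")
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }
  gates <- out[, -(1:2), drop = FALSE]
  structure(list(time_ms = out[, 1], V_mV = out[, "V"], gates = gates,
                 protocol = p, op = op, freeze = freeze,
                 accelerate_inactivation = accelerate_inactivation),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples over %.1f ms, V in [%.2f, %.2f] mV\n",
              length(x$time_ms), max(x$time_ms), min(x$V_mV), max(x$V_mV)))
  invisible(x)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  data.frame(t_ms = x$time_ms, V_mV = x$V_mV, x$gates)
}

#' End-of-pulse voltage deflection
#'
#' Voltage at the end of the injected pulse minus the pre-pulse baseline.
#'
#' @param trace a `voltage_trace` from [simulate_pulse()].
#' @return Deflection in mV.
#' @export
pulse_deflection <- function(trace) {
  p <- trace$protocol
  t_end <- p$pre_ms + p$duration_ms
  i <- which.min(abs(trace$time_ms - t_end))
  trace$V_mV[i] - trace$V_mV[1]
}

#' Estimate the impedance from a small-signal simulation
#'
#' Drives the full nonlinear model with a periodic multisine current of
#' small amplitude (Schroeder phases, deterministic), integrates from the
#' steady state through a settle window plus an integer number of periods,
#' and takes the ratio of the voltage and current Fourier coefficients at
#' the stimulated bins over the final window (the settle window absorbs the
#' stimulus-onset transient, which otherwise leaks a broadband bias into
#' every bin). Serves as an independent oracle for [membrane_impedance()].
#'
#' @param op an [operating_point].
#' @param freeze a [freeze_spec()].
#' @param freqs target frequencies, Hz; snapped to multiples of
#'   `1/duration_s`. Default: 40 log-spaced points over 2-500 Hz.
#' @param amplitude_pA peak current amplitude (small-signal; <= 2 pA
#'   recommended).
#' @param duration_s analysed record length, s (sets the frequency
#'   resolution).
#' @param settle_s discarded initial window, s.
#' @param dt_ms integration step, ms.
#' @param accelerate_inactivation logical, as in [simulate_pulse()].
#' @param check_linearity reject the estimate if off-bin (harmonic and
#'   intermodulation) voltage power exceeds 5% of the stimulated-bin power.
#' @return An `impedance_spectrum` with fields `f` and complex `Z` (GOhm);
#'   no off-grid closure.
#' @export
estimate_impedance_from_simulation <- function(op, freeze = freeze_none(),
                                               freqs = NULL, amplitude_pA = 2,
                                               duration_s = 1, settle_s = 1,
                                               dt_ms = 0.02,
                                               accelerate_inactivation = FALSE,
                                               check_linearity = TRUE) {
  stopifnot(inherits(op, "operating_point"))
  f0 <- 1 / duration_s
  if (is.null(freqs)) freqs <- 10^seq(log10(2), log10(500), length.out = 40)
  bins <- sort(unique(pmax(1, round(freqs / f0))))
  f_j <- bins * f0
  N <- round(duration_s * 1000 / dt_ms)
  N_settle <- round(settle_s * 1000 / dt_ms)
  t_ms <- (0:(N_settle + N)) * dt_ms
  phases <- -pi * seq_along(bins) * (seq_along(bins) - 1) / length(bins)
  raw <- function(t) {
    tt <- t * 1e-3
    s <- 0
    for (j in seq_along(bins)) s <- s + sin(2 * pi * f_j[j] * tt + phases[j])
    s
  }
  keep <- N_settle + (1:N)  # final integer-period window
  i_samp <- vapply(t_ms[keep], raw, numeric(1))
  scale <- amplitude_pA / max(abs(i_samp))
  i_samp <- i_samp * scale
  iinj <- function(t) scale * raw(t)
  dyn <- .build_dyn(op, freeze, accelerate_inactivation)
  sol <- deSolve::ode(y = dyn$y0, times = t_ms, func = dyn$rhs,
                      parms = list(iinj = iinj), method = "rk4")
  v <- sol[keep, "V"]
  v <- v - mean(v)
  i_c <- i_samp - mean(i_samp)
  V_f <- stats::fft(v)
  I_f <- stats::fft(i_c)
  Z <- V_f[bins + 1] / I_f[bins + 1]  # mV / pA = GOhm
  if (check_linearity) {
    # second harmonic of each stimulated tone relative to its fundamental
    # (only at harmonic bins that are not themselves stimulated)
    h2 <- 2 * bins + 1
    ok <- !(2 * bins) %in% bins & h2 <= length(V_f)
    if (any(ok)) {
      ratio <- max(abs(V_f[h2[ok]]) / abs(V_f[bins[ok] + 1]))
      if (ratio > 0.05)
        stop("response is visibly nonlinear at this stimulus amplitude (",
             sprintf("2nd harmonic %.1f%% of fundamental", 100 * ratio),
             "); reduce amplitude_pA")
    }
  }
  structure(list(f = f_j, Z = Z, V = op$V, freeze = freeze, zfun = NULL,
                 amplitude_pA = amplitude_pA, duration_s = duration_s),
            class = "impedance_spectrum")
}
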