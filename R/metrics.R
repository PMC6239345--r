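# Summary quantities of one operating point: 3 dB bandwidth above the 2 Hz
# floor, peak gain, gain-bandwidth product, contrast gain and its bandwidth
# product, and the ATP cost of the Na+/K+ pump current.

.ELEMENTARY_CHARGE <- 1.602176634e-19  # coulomb

# magnitude (MOhm for impedance, mV for contrast gain) as a function of f
.mag_fun <- function(spectrum) {
  if (!is.null(spectrum$zfun)) {
    scale <- if (inherits(spectrum, "contrast_gain_spectrum")) spectrum$scale_mV else 1000
    zf <- spectrum$zfun
    function(f) scale * abs(zf(f))
  } else {
    # grid-only spectrum (e.g. simulation estimate): log-log interpolation
    lf <- log(spectrum$f); lm <- log(abs(spectrum$Z))
    function(f) {
      if (inherits(spectrum, "contrast_gain_spectrum"))
        stop("grid-only contrast spectra are not supported")
      1000 * exp(stats::approx(lf, lm, xout = log(f), rule = 2)$y)
    }
  }
}

#' Bandwidth of a spectrum
#'
#' The highest frequency at which the magnitude falls to a fixed fraction of
#' its maximum over frequencies >= `f_floor` (default 2 Hz, the
#' low-frequency floor excluding slow-inactivation amplification), located
#' by bisection between grid points to 0.01 Hz. The default cutoff fraction
#' is 1/2 (half-amplitude, -6 dB): with the model's capacitance and
#' steady-state conductances this convention reproduces the published
#' operating bandwidths of both the active and the frozen (RC) membrane,
#' whereas a -3 dB cutoff sits a factor ~1.7 below them; see the methods
#' vignette. For a pure RC membrane the half-amplitude bandwidth is
#' `sqrt(3)` times the corner frequency `g/(2 pi C)`.
#'
#' @param spectrum an `impedance_spectrum` or `contrast_gain_spectrum`.
#' @param f_floor low-frequency floor, Hz.
#' @param threshold cutoff fraction of the in-band peak magnitude (1/2 for
#'   half-amplitude; use `1/sqrt(2)` for a -3 dB reading).
#' @param tol bisection tolerance, Hz.
#' @return Bandwidth in Hz. If the magnitude never falls below the threshold
#'   within the grid, the maximum grid frequency is returned with a warning
#'   and attribute `censored = TRUE`.
#' @export
bandwidth <- function(spectrum, f_floor = 2, threshold = 0.5, tol = 0.01) {
  f <- spectrum$f
  keep <- f >= f_floor
  if (!any(keep)) stop("spectrum does not cover frequencies above the floor")
  fg <- f[keep]
  if (fg[1] > f_floor) fg <- c(f_floor, fg)
  mag <- .mag_fun(spectrum)
  mg <- mag(fg)
  ipk <- which.max(mg)
  # refine the in-band peak between neighbouring grid points
  lo <- fg[max(1, ipk - 1)]; hi <- fg[min(length(fg), ipk + 1)]
  pk <- stats::optimize(mag, c(lo, hi), maximum = TRUE, tol = 1e-4)
  peak <- max(pk$objective, mg[ipk])
  thr <- peak * threshold
  below <- which(mg < thr)
  below <- below[below > ipk]
  if (length(below) == 0) {
    warning("magnitude never falls below 1/sqrt(2) of peak within the grid; ",
            "reporting the maximum grid frequency")
    return(structure(max(fg), censored = TRUE, peak = peak))
  }
  i2 <- min(below)
  root <- stats::uniroot(function(x) mag(x) - thr,
                         interval = c(fg[i2 - 1], fg[i2]), tol = tol)
  structure(root$root, peak = peak, censored = FALSE)
}

#' Peak gain of a spectrum
#'
#' Maximum magnitude over frequencies >= `f_floor`; MOhm for impedance
#' spectra, mV per unit contrast for contrast-gain spectra.
#'
#' @inheritParams bandwidth
#' @return Peak magnitude.
#' @export
peak_gain <- function(spectrum, f_floor = 2) {
  attr(bandwidth(spectrum, f_floor), "peak")
}

#' Gain-bandwidth product
#'
#' Product of the in-band peak magnitude and the bandwidth: MOhm*Hz for
#' impedance spectra (GBWP), mV*Hz for contrast-gain spectra (cGBWP). For a
#' passive RC membrane the GBWP is `sqrt(3)/(2 pi C)` regardless of the
#' conductance.
#'
#' @inheritParams bandwidth
#' @return Gain-bandwidth product.
#' @export
gbwp <- function(spectrum, f_floor = 2, threshold = 0.5) {
  bw <- suppressWarnings(bandwidth(spectrum, f_floor, threshold))
  as.numeric(bw) * attr(bw, "peak")
}

#' Contrast gain spectrum
#'
#' In the simplified transduction model the light conductance follows
#' contrast instantaneously, so a small contrast modulation is equivalent to
#' an injected current `g_light (E_L - V) c(t)` and the contrast gain is
#' `T(f) = g_light (E_L - V) Z(f)`, in mV per unit contrast. In the dark
#' (`g_light = 0`) the gain is identically zero.
#'
#' @param op the [operating_point] the spectrum was computed at.
#' @param spectrum an `impedance_spectrum` at the same operating point.
#' @return An object of class `contrast_gain_spectrum` (fields as the input
#'   spectrum; `scale_mV` holds `g_light * (E_L - V)` in pA).
#' @export
contrast_gain <- function(op, spectrum) {
  stopifnot(inherits(op, "operating_point"),
            inherits(spectrum, "impedance_spectrum"))
  scale <- max(op$g_light, 0) * (op$membrane$E_L - op$V)  # nS * mV = pA
  out <- spectrum
  out$scale_mV <- scale
  out$T <- scale * spectrum$Z  # mV per unit contrast (complex)
  class(out) <- c("contrast_gain_spectrum", class(spectrum))
  out
}

#' ATP cost of the pump current
#'
#' The Na+/K+ ATPase hydrolyses one ATP per net elementary charge moved, so
#' the energy cost of an operating point is `|I_P| / e`.
#'
#' @param op an [operating_point].
#' @return ATP molecules hydrolysed per second.
#' @export
energy_cost <- function(op) {
  stopifnot(inherits(op, "operating_point"))
  abs(op$I_P) * 1e-12 / .ELEMENTARY_CHARGE
}

#' ATP cost of a passive membrane matching a target bandwidth
#'
#' Builds a passive membrane whose bandwidth (under the same cutoff
#' convention, default half-amplitude) equals the target: its RC corner is
#' `B / sqrt(1/threshold^2 - 1)`, so its total conductance is
#' `g_total = 2 pi C B / sqrt(1/threshold^2 - 1)`. That conductance is then
#' partitioned into a K-type and an L-type (light-like) part so that the
#' ionic balance holds at the requested voltage, and the resulting pump cost
#' is returned.
#'
#' @param target_bandwidth_Hz bandwidth to match, Hz.
#' @param V membrane voltage, mV.
#' @param membrane a [membrane_params()].
#' @param threshold bandwidth cutoff fraction, as in [bandwidth()]; with
#'   `threshold = 1/sqrt(2)` the corner equals the target bandwidth.
#' @return ATP/s. Errors if no non-negative conductance partition exists.
#' @export
passive_same_bandwidth_cost <- function(target_bandwidth_Hz, V,
                                        membrane = membrane_params(),
                                        threshold = 0.5) {
  mb <- membrane
  fc <- target_bandwidth_Hz / sqrt(1 / threshold^2 - 1)
  g_total <- 2 * pi * mb$capacitance_pF * 1e-3 * fc  # nS
  # ionic balance fixes the ratio g_L/g_K = cNaP/(cK aL) * (V-E_K)/(E_L-V)
  cP <- mb$pump_K_in / mb$q_pump
  cE <- 2 * mb$exch_Ca_out / mb$q_exch
  aL <- mb$na_frac + (mb$exch_Na_in / mb$q_exch) * mb$ca_frac / cE
  ratio <- (mb$pump_Na_out / mb$q_pump) * (V - mb$E_K) /
    (cP * aL * (mb$E_L - V))
  g_K <- g_total / (1 + ratio)
  g_L <- g_total - g_K
  if (g_K < 0 || g_L < 0)
    stop("no feasible non-negative conductance partition at this voltage")
  I_P <- g_K * (V - mb$E_K) / cP
  abs(I_P) * 1e-12 / .ELEMENTARY_CHARGE
}

#' Metrics record for one operating point
#'
#' Computes the full summary row: bandwidth, peak gain, GBWP, peak contrast
#' gain, cGBWP and energy cost, under a given freeze specification.
#'
#' @param op an [operating_point].
#' @param freeze a [freeze_spec()].
#' @param f frequency grid, Hz.
#' @param label optional tag stored in the record.
#' @return A one-row `data.frame`.
#' @export
metrics_record <- function(op, freeze = freeze_none(), f = default_freq_grid(),
                           label = "") {
  sp <- membrane_impedance(op, freeze, f)
  bw <- suppressWarnings(bandwidth(sp))
  tg <- contrast_gain(op, sp)
  pk_T <- if (tg$scale_mV > 0) peak_gain(tg) else 0
  bw_T <- if (tg$scale_mV > 0) suppressWarnings(as.numeric(bandwidth(tg))) else NA_real_
  data.frame(label = label, V_mV = op$V, g_light_nS = op$g_light,
             bandwidth_Hz = as.numeric(bw),
             peak_gain_MOhm = attr(bw, "peak"),
             gbwp_MOhm_Hz = as.numeric(bw) * attr(bw, "peak"),
             peak_contrast_gain_mV = pk_T,
             contrast_bandwidth_Hz = bw_T,
             cgbwp_mV_Hz = if (is.na(bw_T)) 0 else bw_T * pk_T,
             energy_cost_ATP_s = energy_cost(op),
             stringsAsFactors = FALSE)
}
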