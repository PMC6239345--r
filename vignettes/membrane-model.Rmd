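---
title: "The photoreceptor membrane model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The photoreceptor membrane model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymembrane)
```

## The model

`flymembrane` models the soma membrane of a *Drosophila melanogaster* R1-6
photoreceptor as a single electrical compartment. Three voltage-dependent K+
conductances — the fast, partially inactivating Shaker current, the slower
two-mode-inactivating Shab current, and a very slow non-inactivating "Novel"
current — sit in parallel with a K+ leak (2.1 nS), a depolarising leak
(0.803 nS, reversal +5 mV), the light-induced conductance, the membrane
capacitance (50 pF), and two transporters: the Na+/K+ ATPase (2 K+ in, 3 Na+
out, 1 ATP per cycle) and the Na+/Ca2+ exchanger (3 Na+ in, 1 Ca2+ out).
Each voltage-dependent conductance follows Hodgkin-Huxley kinetics,

$$ g = \bar g \, h \, m^{\gamma}, \qquad
   \dot x = \frac{x_\infty(V) - x}{\tau_x(V)}, $$

with $\gamma = 3$ (Shaker), $2$ (Shab), $1$ (Novel, no inactivation).
Composite inactivation is a fraction-weighted sum: Shaker has a
non-inactivating fraction $\xi = 0.13$ ($h = \xi + (1-\xi)h_1$); Shab has a
fast and a slow inactivation mode ($h = 0.7\,h_1 + 0.3\,h_2$, the slow mode
with a fixed 3000 ms time constant). The steady-state curves are logistic
functions raised to $1/\gamma$; the time constants are sums of the usual
exponential and linear-over-exponential rate terms. The rate terms have
removable singularities (Shaker activation at $-59.6$ mV, Shaker
inactivation at $+13.5$ mV, Shab activation at $-23.8$ mV); they are
evaluated by their analytic limit inside a guard band of $10^{-9}$ mV, and
continuity there is tested.

### The steady state

The light-induced current is carried 74% by Na+ and 26% by Ca2+, the K+
conductances carry only K+, and at steady state the pump and exchanger
return every ionic flux. Zeroing the net K+, Na+ and Ca2+ currents gives a
linear system in the light conductance $g_{light}$, pump current $I_P$ and
exchanger current $I_E$ at any voltage — linear because the gates are at
their steady-state values, but solved simultaneously since the depolarising
conductance includes $g_{light}$ itself. Consequences worth knowing:

* the total K-type conductance at any voltage is fixed by the voltage alone
  ($g_K = 1.13\, g_L (E_L - V) / (1.5\,(V - E_K))$ with
  $g_L = g_{light} + g_{L,leak}$), so the dark resting potential pins the
  dark conductance budget regardless of how $\bar g$ is split between
  channels;
* the pump current, and hence the ATP cost $|I_P|/e$, follows directly:
  $I_P = g_K (V - E_K)/2$.

The dark resting potential is the root of $g_{light}(V) = 0$, found by
Brent bracketing on $[-90, -30]$ mV to $10^{-12}$; re-equilibration after a
channel modulation holds $g_{light}$ fixed and root-finds the new voltage
the same way. The pump and exchanger are ideal current sources (no voltage
dependence of their own); their slow kinetics confine any feedback they
produce to well below the analysis band.

### The small-signal equivalent circuit

Linearising an inactivating conductance around an operating point yields,
for each component, a steady resistance $R = 1/(\bar g_k m^\gamma h)$, an
activation branch $r = 1/[(V-E_K)\,\bar g_k h \,\mathrm d(m_\infty^\gamma)/\mathrm dV]$
with inductance $L = \tau_m r$, and an inactivation branch
$r_h = 1/[(V-E_K)\,\bar g_k m^\gamma \,\mathrm dh_\infty/\mathrm dV]$ with
$L_h = \tau_h r_h$ — the inactivation elements are negative above $E_K$.
Channels with composite inactivation are split into components that are
either non-inactivating or single-mode before linearising. The whole-cell
impedance puts every component admittance in parallel with the two leaks,
the steady light conductance and the capacitive admittance $i2\pi f C$.
The light conductance is included as a shunt even though it is not a leak
in the narrow sense: it loads the membrane exactly like one at fixed light,
and the contrast-gain construction (below) presumes it. Derivatives of the
steady-state curves are closed-form and verified against central finite
differences at $10^{-5}$ relative tolerance.

Because the inactivation branches are negative, the circuit is not
passive; instead of asserting a non-negative real admittance the test suite
asserts stability — every pole of $Z(s)$ in the open left half-plane — at
every standard operating point, via the exact numerator polynomial of the
rational admittance.

Freezing a gating variable means removing its branch while keeping its
steady conductance inside $R$: freezing everything leaves a pure RC
membrane with the same total conductance and capacitance (the "passive
equivalent"), and freezing selectively separates negative feedback
(activation) from positive feedback (inactivation).

### Contrast gain and energy

In the simplified transduction model the light conductance follows contrast
instantaneously, $g_{light}(t) = \bar g_{light}(1 + c(t))$, so a small
contrast modulation is an injected current $\bar g_{light}(E_L - V)c(t)$
and the contrast gain is $T(f) = \bar g_{light}(E_L - V) Z(f)$ — an upper
bound on the real photoreceptor, which band-limits the light current. The
energy cost of an operating point is $|I_P|/e$ in ATP/s. Summary metrics
are the bandwidth and in-band peak of $|Z|$ (or $|T|$), their product
(GBWP, cGBWP), and cost comparisons against passive membranes.

## The bandwidth convention

Gain and bandwidth are measured above a 2 Hz floor, excluding the
low-frequency amplification produced by slow inactivation, which the intact
eye filters out anyway. The cutoff fraction is the package's one genuinely
open convention, and it matters. The steady-state balance fixes the dark
membrane at about 3.4 nS total; with 50 pF that is an RC corner of 10.8 Hz
and a -3 dB bandwidth of ~11 Hz for the frozen membrane, roughly half the
published operating figure for the dark photoreceptor (about 20 Hz passive,
26 Hz active), and no admissible conductance set closes that factor of two.
The half-amplitude (-6 dB) cutoff — $\sqrt 3$ times the corner for an RC
membrane — reproduces the published dark values on both the active and the
passive side and keeps the high-light figures consistent with the
cost-pinned conductance budget. `bandwidth()` therefore defaults to
`threshold = 0.5`, with the -3 dB reading available as
`threshold = 1/sqrt(2)`. Two consequences propagate: the passive GBWP
constant is $\sqrt 3 / (2\pi C) \approx 5513\ \mathrm{M\Omega\,Hz}$, and
the bandwidth-matched passive membrane used for cost comparisons is built
with corner $B/\sqrt 3$ so that its own half-amplitude bandwidth equals the
target $B$.

## Calibration of the maximal conductances

The three maximal conductances are not fixed by the channel kinetics; they
are free parameters. Rather than invent values silently, the package fits
them (`calibrate_gbar()`) by deterministic fixed-start Nelder-Mead on the
log-conductances, minimising summed squared relative errors on four
operating anchors of the same model: dark resting potential $-68$ mV, dark
input resistance 290 MOhm, dark bandwidth 26 Hz, and energy cost
$5.6\times10^8$ ATP/s at $-36$ mV. The optimum is reproducible from any
tried start: $\bar g_{Shaker} = 16.40$ nS, $\bar g_{Shab} = 53.04$ nS,
$\bar g_{Novel} \to 0$. Two residuals (input resistance $-12\%$, dark
bandwidth $-10\%$) exceed the 5% convergence criterion and the result is
flagged accordingly — the four anchors are not exactly satisfiable in this
parameterisation, and the fit reports the compromise rather than hiding it.
That the Novel conductance is driven to zero means the anchor set carries
no information supporting a nonzero value; its kinetics remain in the
package and any study can be run with a nonzero $\bar g_{Novel}$, but the
shipped default (`gbar_default()`) records the fit as it is.

## Numerical choices

* **Units.** mV, ms, nS, pA, pF internally (1 nS mV = 1 pA; pF/nS = ms);
  conversions to SI only at the impedance (GOhm, s) and energy (coulomb)
  boundaries.
* **Integration.** Fixed-step classical Runge-Kutta (`deSolve`, method
  `"rk4"`), default step 0.01 ms against gate time constants of 3-3000 ms.
  Pulse protocols integrate the pre/pulse/post segments separately so the
  discontinuous stimulus never falls inside a step; a step-halving test
  keeps the end-pulse voltage stable to $10^{-3}$ mV.
* **Impedance estimator.** The independent check of the analytic
  linearisation drives the full nonlinear model with a deterministic
  Schroeder-phase multisine (peak 2 pA), discards a 1 s settle window —
  stimulus-onset transients otherwise leak a broadband bias of a few
  percent into every bin — and takes Fourier-coefficient ratios over an
  integer number of periods. A second-harmonic check rejects stimuli large
  enough to drive the gates visibly nonlinear.
* **Frequency grid.** 400 log-spaced points over 0.1-1000 Hz; bandwidth is
  located by bisection between grid points to 0.01 Hz, and peak gain by
  local refinement, so doubling the grid density moves nothing by more than
  0.1%.
* **Degenerate inputs.** Voltages below the dark resting potential make the
  solved light conductance negative: the operating point is returned with
  `feasible = FALSE` rather than an error. A zero slope or $V = E_K$ makes
  a branch resistance infinite: the branch is reported absent, never as a
  division error.

## What the model does not cover

The phototransduction cascade is reduced to an instantaneous conductance
follower, so contrast gains are theoretical maxima: real quantum-bump
filtering attenuates both very low and high frequencies. The axon and any
spatial structure are absent; so are channel noise, ion-concentration
dynamics, pump saturation and temperature dependence. The serotonin edits
substitute the published shifted steady-state fits and rigidly shift the
time-constant curves; any shape change of the time constants beyond a shift
is not represented. All quantitative statements the package makes about
published operating numbers are conditional on the documented calibration,
since the underlying maximal conductances were never printed.
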