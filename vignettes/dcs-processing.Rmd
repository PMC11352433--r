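---
title: "From photon counts to blood flow: the dcsflow processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From photon counts to blood flow: the dcsflow processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsflow)
```

## The measurement and the model

Diffuse correlation spectroscopy (DCS) infers microvascular blood flow
from the temporal speckle fluctuations of multiply scattered coherent
light. A long-coherence laser illuminates tissue; a single-mode fiber
feeds the detected speckle to a photon-counting detector (APD), so the
raw data are photon arrival events. Moving scatterers — chiefly red blood
cells — decorrelate the detected field, and the decay rate of the
normalized intensity autocorrelation \(g_2(\tau)\) encodes the flow.

`dcsflow` implements the standard continuous-wave analysis for a
semi-infinite homogeneous medium. The field autocorrelation is

\[
g_1(\tau) \;=\; \frac{1}{H}\!\left[
  \frac{e^{-r_1 K(\tau)}}{r_1} - \frac{e^{-r_b K(\tau)}}{r_b}\right],
\qquad K(\tau) = \sqrt{A + B\,\alpha D_B\,\tau},
\]

with \(A = 3\mu_s'\mu_a\), \(\kappa_0 = 2\pi n/\lambda\),
\(B = 6\mu_s'^2\kappa_0^2\), \(z_0 = 1/\mu_s'\),
\(r_1 = \sqrt{z_0^2+\rho^2}\),
\(z_b = \tfrac{2}{3\mu_s'}\tfrac{1+R_{\mathrm{eff}}}{1-R_{\mathrm{eff}}}\),
\(r_b = \sqrt{(2z_b+z_0)^2+\rho^2}\) and
\(H = e^{-r_1\sqrt A}/r_1 - e^{-r_b\sqrt A}/r_b\), so that
\(g_1(0)=1\) exactly. The measurable intensity correlation follows from
the Siegert relation, \(g_2(\tau) = 1 + \beta g_1(\tau)^2\). Two
parameters are free in the fit: the blood flow index
\(\alpha D_B\) (cm²/s) and the coherence factor \(\beta\); everything
else is fixed by the optics and geometry (`derive_constants()`).

Two conventions are deliberate and exposed rather than hidden:

* **Wave number.** \(\kappa_0\) uses the in-medium wavelength,
  \(\kappa_0 = 2\pi n_{\mathrm{medium}}/\lambda_{\mathrm{vac}}\), with
  \(n_{\mathrm{medium}} = 1.4\) by default (a standard soft-tissue
  value). This is the common choice in the DCS literature; since
  \(B \propto \kappa_0^2\), a different convention rescales fitted
  \(\alpha D_B\) by \(n^2\) — worth keeping in mind when comparing
  absolute BFI values across instruments and codes.
* **Boundary reflection.** \(R_{\mathrm{eff}}\) defaults to the standard
  diffuse-optics polynomial in the relative index
  \(n = n_{\mathrm{in}}/n_{\mathrm{out}}\):
  \(R_{\mathrm{eff}} \approx -1.440n^{-2}+0.710n^{-1}+0.668+0.0636n\)
  (0.5295 at \(n=1.4\)). Instruments that adopt a different fixed value
  (e.g. the exact Fresnel-integral 0.493) can set `reff_override`.

Because of these conventions, two correct implementations can disagree on
absolute BFI by tens of percent while agreeing perfectly on relative
changes; all validation in this package is therefore self-consistent
(synthetic truth in, recovery out) rather than anchored to any published
absolute value.

## The multi-tau correlator

Photon events are binned into 1 µs counts (`bin_events()`, half-open
bins). The correlator estimates \(g_2\) on a quasi-logarithmic schedule
(`delay_schedule()`): a linear first stage of 16 lags at the base bin,
then stages of 8 lags each at successively doubled bin widths, continuing
contiguously (lags 9–16 of each doubled stage). The two presets are 80
delays (max lag 4.096 ms — physiological flows and liquid phantoms) and
120 delays (max lag 131 ms — the slow decay of a static phantom).

Per lag \(k\) within a stage, with \(M_s\) usable pairs,

\[
g_2(k) = \frac{M_s \sum_i n_i n_{i+k}}
  {\bigl(\sum_i n_i\bigr)\bigl(\sum_i n_{i+k}\bigr)} ,
\]

the sums running over the same index range (symmetric normalization, no
wraparound or padding). This choice makes a constant input give
\(g_2 \equiv 1\) exactly and makes the estimator invariant under integer
rescaling of the counts. Coarsening is by pairwise **summation**, not
averaging: with integer counts every accumulator is integer-valued and
exact in double precision, which is what lets the streaming multi-tau
path (`multitau_correlate()`, compiled) agree with the direct
\(O(NL)\) reference (`brute_force_correlate()`) to strict tolerance —
the equivalence is asserted over hundreds of random Poisson, bursty and
constant series in the test suite. A schedule needs
\((k_{\max}+8)\cdot 2^{n_{\mathrm{stages}}}\) base bins (6144 for 80
delays, 196 608 for 120); shorter inputs are refused with the minimum
named.

Lags where a monitor sum is zero (an all-dark window) yield `NaN`, which
the downstream validity gate converts into a missing BFI rather than an
abort.

## The analyzer

`nelder_mead_fit()` minimizes the mean squared error between the
measured curve and the model over **all** scheduled lags
(`correlation_mse()`), mirroring a hardware analyzer's decomposition:
MSE evaluation, best/good/worst sorting (ties broken toward smaller
\(\alpha D_B\) for determinism), candidate-point calculation
(`propose_points()`: reflect/expand/contract/shrink with the classical
coefficients \(\alpha_r=1, \gamma=2, \rho_c=0.5, \sigma=0.5\)), the
standard acceptance decision, and a termination check.

Numerical choices:

* The simplex lives in \((\beta, \log_{10}\alpha D_B)\): the flow index
  spans decades, and log coordinates keep the triangle well-conditioned
  across that range. Candidates are clipped to box bounds
  (\(\beta \in (0, 1.2]\), \(\alpha D_B \in [10^{-12}, 10^{-5}]\)
  cm²/s) that bracket phantom and physiological values and prevent
  overflow in the model.
* Termination: relative MSE spread
  \(|f_w - f_b|/\max(f_b, 10^{-30}) < 10^{-4}\), or 100 iterations. On
  noiseless curves the spread criterion cannot fire (the best MSE falls
  toward zero), so the fit runs its full budget — 100 iterations
  recover noiseless parameters to ~\(10^{-11}\) relative, far inside the
  0.1 % the package asserts. A simplex that collapses to zero area on a
  bound is treated as converged at its best vertex.
* The default initial simplex, \((\beta,\alpha D_B) = (0.40,10^{-9}),
  (0.55,10^{-8}), (0.45,5\times10^{-8})\), spans the expected range —
  the practical safeguard against Nelder–Mead's local minima; it is
  configurable per application, and the test suite cross-checks fits
  against both a dense grid search and an independent general-purpose
  simplex optimizer.

Before fitting, `validate_curve()` applies the processor-style sanity
gate: the first point (nominal \(1+\beta\)) must lie in
\((1.05, 2.0)\) and the tail within 0.1 of 1. The bounds are
configurable placeholders — reference hardware does not publish its
ranges — and windows failing the gate become missing values with the
reason recorded, never a stream abort.

## The synthetic photon stream

`simulate_photon_stream()` makes the whole chain testable with no
instrument. Each of \(M\) detected modes is a complex circular Gaussian
process whose autocorrelation equals the model \(g_1\); summing mode
intensities gives fully developed speckle with intercept
\(\beta = 1/M\) **exactly** (integer mode counts only — arbitrary
\(\beta\) would need mode weighting and is deliberately out of scope).
Detection is doubly stochastic: Poisson counts per 1 µs bin with mean
proportional to the instantaneous intensity, scaled to the realized
trace mean so the stream hits the requested count rate; an optional
uniform dark-count rate is available (default 0 — dead time and
afterpulsing are not modeled).

The field is synthesized in independent blocks by circulant embedding
(FFT of the covariance sequence, eigenvalue clipping at zero): block
lengths are at least 100 decorrelation times (clamped to
\(2^{10}\)–\(2^{19}\) samples), so the covariance support fits and the
bias from uncorrelated block boundaries is below lag/block — about 1 %
at the largest scheduled lag, and negligible wherever \(g_1\) is
appreciably nonzero. Nonstationary profiles (cuff occlusion, pulsatile)
are handled quasi-statically: each block uses the BFI at its midpoint,
with blocks additionally capped at 1/16 of the modulation timescale.
This is valid because physiological modulation (~1 Hz) is 4–5 orders of
magnitude slower than speckle decorrelation (tens of µs); it would not
be valid for, say, ultrasound-modulated flow.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: detector dead time and
afterpulsing (which distort the first lags at high rates), dark counts
(off by default), source intensity drift, room-light leakage, motion
artifacts, and layered or heterogeneous tissue (the model and the
generator share the same semi-infinite assumption, so model mismatch is
invisible here by construction).

Scenario presets (`scenario_preset()`) encode the standard validation
protocols: a static solid phantom (BFI \(10^{-10}\) cm²/s, the 120-delay
use case), a four-step liquid-phantom viscosity series with strictly
decreasing BFI (\(1.5\times10^{-10}\) down to
\(4\times10^{-11}\) cm²/s, the scale such phantoms measure at), a cuff-ischemia timeline (10 s baseline,
25 s occlusion at 6 % of baseline flow, hyperemic overshoot at 2× then
relaxation), and sinusoidal pulsatile modulation (default 1.45 Hz, 35 %
fractional amplitude about \(1.2\times10^{-8}\) cm²/s). Count rate
defaults to \(10^5\) counts/s — typical DCS practice at 1 cm
separation; published instrument descriptions rarely state theirs.

## The windowed pipeline

`run_pipeline()` cuts the count stream into non-overlapping windows of
\(1/\mathrm{rate}\) seconds aligned to the stream start (1 Hz and 50 Hz
are the presets of interest), and per window runs correlate → gate →
fit. A 20 ms window at 50 Hz holds the 80-delay schedule (max lag
4.096 ms) with margin; the 120-delay schedule is refused at 50 Hz
because its largest lag exceeds the window. Missing BFIs are written as
empty CSV fields and never silently interpolated — except inside
`bfi_spectrum()`, where interpolation is explicit and flagged.

`moving_average()` is the centered box filter used to read pulsatile
waveforms from fast BFI traces (15 points at 50 Hz attenuates a 1.45 Hz
line to ~0.72 of its amplitude — enough to see the pulse clearly while
blunting it less than a wider filter would). `bfi_spectrum()` takes the
magnitude spectrum of the mean-removed segment (minimum 4 s) and
reports the largest peak above 0.5 Hz, excluding DC and the drift band.

## Problem sizes used in validation

The shipped tests validate at sizes a desk machine handles comfortably
while preserving every structural property of the full protocols:
correlator equivalence on ~100 random series of \(7\times10^3\)–\(10^5\)
bins (plus \(2.2\times10^5\)–\(3\times10^5\) for the 120-delay preset);
end-to-end constant-flow recovery on four 30 s streams (30 one-second
windows each, the 30-window phantom protocol) with a 15 % tolerance on
the decade-spanning means and strict monotonicity across them; 60 s of
50 Hz pulsatile data (3000 fits) for the spectral peak; and a 60 s cuff
timeline at 1 Hz. `scripts/acceptance.R` recomputes the same kinds of
quantities at slightly smaller sizes from a caller-supplied seed.

## Known limitations

* Absolute BFI depends on the \(\kappa_0\) and \(R_{\mathrm{eff}}\)
  conventions above; cross-instrument comparisons should fix both.
* The analyzer fits all lags of the schedule; fitting a selected segment
  of the curve (as some software packages do) is intentionally not
  offered.
* Single channel, autocorrelation only; cross-correlation between two
  detectors is not implemented.
* The fit is a local simplex search: with pathological initial
  simplices (collinear, or far outside the bounds) it degrades
  gracefully (degenerate input is refused; collapsed simplices return
  their best vertex) but no global search is attempted.
* The simulator's quasi-static approximation breaks down if flow
  modulation approaches the decorrelation timescale.
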