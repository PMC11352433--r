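# dcsflow

A complete software processing chain for **diffuse correlation
spectroscopy (DCS)** — the optical technique that monitors microvascular
blood flow from the temporal speckle fluctuations of multiply scattered
coherent light. `dcsflow` takes photon arrival events (or pre-binned
photon counts), estimates the normalized intensity autocorrelation
g₂(τ) with a multi-tau correlator, and fits the semi-infinite solution
of the correlation diffusion equation to extract the **blood flow index**
(BFI, αD_B) and the coherence factor β. A synthetic speckle photon-stream
simulator makes the entire chain testable and calibratable with no
instrument.

Who it is for: researchers building or validating DCS instrumentation
(software or hardware correlators and fitters), and anyone who needs a
transparent, test-covered reference for the standard CW-DCS analysis.

## The model

The field autocorrelation of light remitted from a semi-infinite dynamic
medium is

    g1(τ) = [ exp(−r1·K(τ))/r1 − exp(−rb·K(τ))/rb ] / H,
    K(τ)  = sqrt(A + B·αD_B·τ)

with A = 3µs′µa, κ₀ = 2πn/λ, B = 6µs′²κ₀², z₀ = 1/µs′,
r1 = sqrt(z₀² + ρ²), zb = (2/3µs′)(1+Reff)/(1−Reff),
rb = sqrt((2zb + z₀)² + ρ²), and H chosen so g1(0) = 1. The measured
intensity correlation follows the Siegert relation g₂ = 1 + β·g1².
The analyzer fits (β, αD_B) by Nelder–Mead minimization of the mean
squared error over the full multi-tau lag schedule (80 delays for
physiological decays, 120 for slow solid-phantom decays), after a
validity gate on the curve's intercept and tail.

## Worked example

Simulate five seconds of speckle photon counts at a known flow, then run
the full chain back over them:

```r
library(dcsflow)

optics <- optical_config(mu_a = 0.1, mu_s_prime = 10, rho = 1)  # cm^-1, cm
spec <- simulation_spec(optics, flow_constant(1.2e-8), duration = 5,
                        mean_count_rate = 1e5, n_modes = 2, seed = 7)
counts <- simulate_photon_stream(spec)
counts
#> <photon_count_series> 5000000 bins x 1e-06 s (5 s), 499148 counts (9.983e+04 counts/s)

curve <- multitau_correlate(counts, correlator_preset(80))
curve
#> <correlation_curve> 80 lags, tau 1e-06..0.0041 s, g2[1] = 1.471, g2[end] = 1

fit <- nelder_mead_fit(curve, derive_constants(optics))
fit
#> <fit_result> alpha_db = 1.209e-08 cm^2/s, beta = 0.4932, mse = 1.64e-05, 28 iterations (tolerance)

bfi <- run_pipeline(counts, pipeline_config(optics, measurement_rate = 1))
bfi
#> <bfi_time_series> 5 windows at 1 Hz, 5 fitted (0 missing)
#>   alpha_db: mean 1.21e-08 cm^2/s, range 1.15e-08..1.232e-08
```

The simulated truth was αD_B = 1.2×10⁻⁸ cm²/s with β = 1/2 (two
detected modes): the single-curve fit recovers 1.209×10⁻⁸ cm²/s and
β = 0.493, and the windowed 1 Hz pipeline averages 1.21×10⁻⁸ cm²/s over
five windows — sub-percent recovery at a realistic 10⁵ counts/s.

Scenario presets reproduce standard validation protocols:
`scenario_preset("cuff_ischemia")` (10 s baseline, 25 s occlusion,
reactive hyperemia), `"pulsatile"` (sinusoidal modulation at a heart-rate
frequency, resolvable from 50 Hz windows via `bfi_spectrum()`),
`"solid_phantom"` and `"liquid_phantom_series"`.

## Command line

A thin CLI over the same functions is installed at
`<library>/dcsflow/exec/dcsflow`:

```sh
dcsflow simulate  --scenario pulsatile --duration 10 --seed 1 --output counts.csv
dcsflow correlate --input counts.csv --preset 80 --output corr.csv
dcsflow pipeline  --input counts.csv --config config.yml --rate 50 --smooth 15 --output bfi.csv
dcsflow spectrum  --input bfi.csv --output spectrum.csv
```

`config.yml` is a flat key-value file (see `?load_config`;
`write_config()` emits one).

## Further reading

The methods vignette (`vignettes/dcs-processing.Rmd`) documents the
model conventions (in-medium wave number, effective reflection
coefficient), the symmetric multi-tau normalization, the simplex
numerics, what the speckle simulator does and does not emulate, and the
package's known limitations.
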