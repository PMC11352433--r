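#' Time-varying flow profiles for the simulator
#'
#' A flow profile prescribes the instantaneous blood flow index
#' `alpha_db(t)` used by the speckle synthesizer. Three shapes are
#' provided: constant, piecewise-constant (cuff occlusion protocols) and
#' sinusoidally modulated (pulsatile flow).
#'
#' @param alpha_db constant BFI, cm^2/s.
#' @return An object of class `flow_profile` with fields `type`,
#'   `alpha_at` (a function of time in seconds), and the range
#'   `alpha_range`.
#' @export
flow_constant <- function(alpha_db) {
  stopifnot(alpha_db > 0)
  structure(
    list(type = "constant",
         alpha_at = function(t) rep.int(alpha_db, length(t)),
         alpha_range = c(alpha_db, alpha_db),
         timescale = Inf),
    class = "flow_profile"
  )
}

#' @rdname flow_constant
#' @param breaks segment start times, seconds; the first must be 0.
#' @param values BFI per segment, cm^2/s; the last segment extends to the
#'   end of the simulation.
#' @export
flow_piecewise <- function(breaks, values) {
  stopifnot(length(breaks) == length(values), breaks[1] == 0,
            all(diff(breaks) > 0), all(values > 0))
  structure(
    list(type = "piecewise",
         alpha_at = function(t) {
           values[findInterval(t, breaks, rightmost.closed = FALSE)]
         },
         alpha_range = range(values),
         timescale = min(diff(breaks))),
    class = "flow_profile"
  )
}

#' @rdname flow_constant
#' @param mean_alpha_db mean BFI about which the flow oscillates, cm^2/s.
#' @param freq_hz modulation frequency, Hz (heart rate for pulsatile flow).
#' @param frac_amplitude fractional modulation amplitude in `[0, 1)`.
#' @export
flow_sinusoid <- function(mean_alpha_db, freq_hz, frac_amplitude = 0.3) {
  stopifnot(mean_alpha_db > 0, freq_hz > 0,
            frac_amplitude >= 0, frac_amplitude < 1)
  structure(
    list(type = "sinusoid",
         alpha_at = function(t) {
           mean_alpha_db * (1 + frac_amplitude * sin(2 * pi * freq_hz * t))
         },
         alpha_range = mean_alpha_db * (1 + c(-1, 1) * frac_amplitude),
         timescale = 1 / freq_hz),
    class = "flow_profile"
  )
}

#' Specification of a synthetic DCS photon stream
#'
#' Describes everything needed to emulate the photon stream an APD would
#' deliver from a semi-infinite dynamic medium: optics, a flow profile,
#' the detected mode count (which sets the coherence factor beta = 1 /
#' n_modes), the mean count rate, and sampling steps.
#'
#' @param optics an [optical_config()].
#' @param flow_profile a [flow_constant()], [flow_piecewise()] or
#'   [flow_sinusoid()].
#' @param duration total stream duration, seconds.
#' @param mean_count_rate mean detected photon rate, counts/s (default
#'   1e5, typical for CW-DCS at 1 cm separation).
#' @param n_modes number of independent speckle modes summed on the
#'   detector; the intensity correlation intercept is `1/n_modes`.
#' @param field_dt sampling step of the underlying speckle field,
#'   seconds; must resolve the fastest decorrelation (<= tau_c / 10).
#' @param bin_width photon-count bin width, seconds (default 1e-6, the
#'   hardware time bin); must be an integer divisor or multiple of
#'   `field_dt`.
#' @param dark_rate uniform dark-count rate added to the stream, counts/s.
#' @param seed RNG seed making the stream reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(optics, flow_profile, duration,
                            mean_count_rate = 1e5, n_modes = 2,
                            field_dt = 1e-6, bin_width = 1e-6,
                            dark_rate = 0, seed = 1) {
  stopifnot(inherits(optics, "optical_config"),
            inherits(flow_profile, "flow_profile"),
            duration > 0, mean_count_rate > 0, n_modes >= 1,
            n_modes == floor(n_modes), field_dt > 0, bin_width > 0,
            dark_rate >= 0)
  ratio <- field_dt / bin_width
  if (abs(ratio - round(ratio)) > 1e-9 &&
      abs(1 / ratio - round(1 / ratio)) > 1e-9) {
    stop("field_dt must be an integer multiple or divisor of bin_width")
  }
  structure(
    list(optics = optics, flow_profile = flow_profile,
         duration = duration, mean_count_rate = mean_count_rate,
         n_modes = as.integer(n_modes), field_dt = field_dt,
         bin_width = bin_width, dark_rate = dark_rate,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Half-decay decorrelation time of the semi-infinite model
#'
#' The lag at which `g1` has fallen to one half, solved from the model
#' (monotone in the decay argument, so a one-dimensional root).
#'
#' @param constants a [derive_constants()] result.
#' @param alpha_db BFI, cm^2/s (> 0).
#' @return Decorrelation time in seconds.
#' @export
decorrelation_time <- function(constants, alpha_db) {
  stopifnot(alpha_db > 0)
  f <- function(K) {
    (exp(-constants$r1 * K) / constants$r1 -
       exp(-constants$rb * K) / constants$rb) / constants$H - 0.5
  }
  K0 <- sqrt(constants$A)
  upper <- K0 + 1
  while (f(upper) > 0) upper <- upper * 2
  K_half <- stats::uniroot(f, c(K0, upper), tol = 1e-12)$root
  (K_half^2 - constants$A) / (constants$B * alpha_db)
}

# Circulant-embedding synthesis of one block of the complex speckle field
# for n_modes modes at a fixed alpha_db; returns the summed intensity
# (mean n_modes). `lam` caches the circulant eigenvalues.
block_eigenvalues <- function(constants, alpha_db, n_block, dt) {
  j <- 0:(n_block - 1L)
  lags <- pmin(j, n_block - j) * dt
  # covariance sequence on the circle; g1 support << block length
  cv <- g1_model_unsorted(constants, alpha_db, lags)
  lam <- Re(fft(cv))
  pmax(lam, 0)
}

# g1 without the strictly-increasing-taus precondition (internal).
g1_model_unsorted <- function(constants, alpha_db, taus) {
  K <- sqrt(constants$A + constants$B * alpha_db * taus)
  g1 <- (exp(-constants$r1 * K) / constants$r1 -
           exp(-constants$rb * K) / constants$rb) / constants$H
  pmax(g1, 0)
}

synthesize_block <- function(lam, n_modes) {
  n <- length(lam)
  s <- sqrt(lam / n)
  intensity <- numeric(n)
  for (m in seq_len(n_modes)) {
    z <- complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
    E <- fft(s * z)
    intensity <- intensity + Re(E)^2 + Im(E)^2
  }
  intensity
}

#' Synthesize a speckle intensity trace
#'
#' Generates the detected intensity of `n_modes` independent, fully
#' developed speckle modes, each a complex circular Gaussian process whose
#' field autocorrelation equals [g1_model()] at the instantaneous flow
#' state. Blocks of the field are synthesized by circulant embedding
#' (FFT-based, exact up to the truncated covariance tail); nonstationary
#' profiles are handled quasi-statically, each block using the BFI at its
#' midpoint — valid because physiological modulation (~1 Hz) is orders of
#' magnitude slower than speckle decorrelation (tens of microseconds).
#' The ensemble intensity autocorrelation of the output is
#' `1 + (1/n_modes) g1^2`.
#'
#' Uses the current RNG state; seed via [simulate_photon_stream()] or
#' `set.seed()` for reproducibility.
#'
#' @param spec a [simulation_spec()].
#' @return A list with `intensity` (mean-normalized, arbitrary units),
#'   `dt` (the field sampling step) and `n_block` (synthesis block
#'   length, samples).
#' @export
synthesize_speckle_intensity <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  constants <- derive_constants(spec$optics)
  tc_fast <- decorrelation_time(constants, spec$flow_profile$alpha_range[2])
  tc_slow <- decorrelation_time(constants, spec$flow_profile$alpha_range[1])
  if (spec$field_dt > tc_fast / 10) {
    stop(sprintf(
      "field_dt = %g s is too coarse: the fastest decorrelation time is %g s (need field_dt <= tau_c / 10)",
      spec$field_dt, tc_fast))
  }
  n_total <- round(spec$duration / spec$field_dt)
  # block >= 100 decorrelation times so the covariance support fits, but
  # short against any flow modulation (quasi-static approximation)
  n_block <- 2^ceiling(log2(100 * tc_slow / spec$field_dt))
  if (is.finite(spec$flow_profile$timescale)) {
    n_mod_cap <- 2^floor(log2(
      spec$flow_profile$timescale / 16 / spec$field_dt))
    n_block <- min(n_block, max(n_mod_cap, 2^10))
  }
  n_block <- min(max(n_block, 2^10), 2^19)

  intensity <- numeric(n_total)
  constant_flow <- spec$flow_profile$type == "constant"
  lam <- NULL
  pos <- 0L
  while (pos < n_total) {
    n_this <- min(n_block, n_total - pos)
    t_mid <- (pos + n_this / 2) * spec$field_dt
    if (is.null(lam) || !constant_flow) {
      a_mid <- spec$flow_profile$alpha_at(t_mid)
      lam <- block_eigenvalues(constants, a_mid, n_block, spec$field_dt)
    }
    block <- synthesize_block(lam, spec$n_modes)
    intensity[(pos + 1L):(pos + n_this)] <- block[seq_len(n_this)]
    pos <- pos + n_this
  }
  list(intensity = intensity / spec$n_modes, dt = spec$field_dt,
       n_block = n_block)
}

#' Sample photon counts from an intensity trace
#'
#' Draws photon counts per `bin_width` bin from a Poisson law with mean
#' proportional to the local intensity (doubly stochastic detection), the
#' proportionality scaled to the realized trace mean so the stream's mean
#' count rate matches `mean_count_rate`. An optional uniform dark-count
#' rate is added.
#'
#' Uses the current RNG state (see [simulate_photon_stream()]).
#'
#' @param field output of [synthesize_speckle_intensity()] (or any list
#'   with nonnegative `intensity` and `dt`).
#' @param spec the [simulation_spec()].
#' @return A [photon_count_series()] at `spec$bin_width`.
#' @export
sample_photon_counts <- function(field, spec) {
  stopifnot(all(field$intensity >= 0))
  intensity <- field$intensity
  if (field$dt > spec$bin_width) {
    rep_each <- round(field$dt / spec$bin_width)
    intensity <- rep(intensity, each = rep_each)
  } else if (field$dt < spec$bin_width) {
    agg <- round(spec$bin_width / field$dt)
    n_c <- (length(intensity) %/% agg) * agg
    intensity <- colMeans(matrix(intensity[seq_len(n_c)], nrow = agg))
  }
  mu <- mean(intensity)
  lam <- if (mu > 0) {
    spec$mean_count_rate * spec$bin_width * intensity / mu
  } else {
    rep.int(0, length(intensity))
  }
  counts <- rpois(length(lam), lam)
  if (spec$dark_rate > 0) {
    counts <- counts + rpois(length(lam), spec$dark_rate * spec$bin_width)
  }
  photon_count_series(counts, bin_width = spec$bin_width)
}

#' Simulate a complete synthetic photon stream
#'
#' Seeds the RNG from `spec$seed`, synthesizes the speckle intensity and
#' samples photon counts, so identical specs give identical streams.
#'
#' @param spec a [simulation_spec()].
#' @return A [photon_count_series()].
#' @examples
#' spec <- scenario_preset("solid_phantom", duration = 0.5)
#' simulate_photon_stream(spec)
#' @export
simulate_photon_stream <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  field <- synthesize_speckle_intensity(spec)
  sample_photon_counts(field, spec)
}

#' Built-in measurement scenarios
#'
#' Fully populated simulation specs emulating the bench and physiological
#' experiments a DCS system is validated on:
#' \describe{
#'   \item{`solid_phantom`}{static silicone phantom optics (mu_s' = 17.2,
#'     mu_a = 0.23 cm^-1) with a very low residual BFI; its slow decay is
#'     what the 120-delay schedule exists for.}
#'   \item{`liquid_phantom_series`}{four Intralipid-like phantoms
#'     (mu_s' = 20, mu_a = 0.14 cm^-1) of increasing viscosity, hence four
#'     strictly decreasing BFI values; returned as a list of four specs.}
#'   \item{`cuff_ischemia`}{10 s baseline, 25 s arterial occlusion with
#'     strongly suppressed flow, then a reactive-hyperemia overshoot
#'     relaxing back to baseline.}
#'   \item{`pulsatile`}{sinusoidal BFI modulation at a heart-rate
#'     frequency (default 1.45 Hz).}
#' }
#' All presets use a 1 cm source-detector separation, 785 nm, two detected
#' modes (beta = 0.5) and a 1e5 counts/s mean rate.
#'
#' @param name one of `"solid_phantom"`, `"liquid_phantom_series"`,
#'   `"cuff_ischemia"`, `"pulsatile"`.
#' @param duration stream duration, seconds (default per scenario).
#' @param mean_count_rate counts/s.
#' @param seed RNG seed.
#' @param pulse_hz heart-rate frequency for `"pulsatile"`, Hz.
#' @return A [simulation_spec()], or a named list of four for
#'   `"liquid_phantom_series"`.
#' @export
scenario_preset <- function(name, duration = NULL, mean_count_rate = 1e5,
                            seed = 1, pulse_hz = 1.45) {
  tissue <- optical_config(mu_a = 0.1, mu_s_prime = 10, rho = 1)
  switch(
    name,
    solid_phantom = simulation_spec(
      optics = optical_config(mu_a = 0.23, mu_s_prime = 17.2, rho = 1),
      flow_profile = flow_constant(1e-10),
      duration = if (is.null(duration)) 30 else duration,
      mean_count_rate = mean_count_rate, n_modes = 2, seed = seed
    ),
    liquid_phantom_series = {
      # viscosity steps: flow falls roughly exponentially with thickener
      # concentration, so four strictly decreasing BFI values
      alphas <- c(1.5e-10, 1.2e-10, 8e-11, 4e-11)
      liquid <- optical_config(mu_a = 0.14, mu_s_prime = 20, rho = 1)
      out <- lapply(seq_along(alphas), function(i) {
        simulation_spec(
          optics = liquid, flow_profile = flow_constant(alphas[i]),
          duration = if (is.null(duration)) 30 else duration,
          mean_count_rate = mean_count_rate, n_modes = 2, seed = seed + i
        )
      })
      names(out) <- c("mc_0", "mc_0.0625", "mc_0.5", "mc_1")
      out
    },
    cuff_ischemia = simulation_spec(
      optics = tissue,
      flow_profile = flow_piecewise(
        breaks = c(0, 10, 35, 40, 50),
        values = c(1.2e-8, 1.2e-8 * 0.06, 1.2e-8 * 2.0, 1.2e-8 * 1.4,
                   1.2e-8)
      ),
      duration = if (is.null(duration)) 60 else duration,
      mean_count_rate = mean_count_rate, n_modes = 2, seed = seed
    ),
    pulsatile = simulation_spec(
      optics = tissue,
      flow_profile = flow_sinusoid(1.2e-8, pulse_hz, frac_amplitude = 0.35),
      duration = if (is.null(duration)) 60 else duration,
      mean_count_rate = mean_count_rate, n_modes = 2, seed = seed
    ),
    stop("unknown scenario: '", name, "'")
  )
}

#' Expand binned counts into synthetic arrival timestamps
#'
#' Places each photon uniformly at random within its bin (sorted within
#' the stream), producing an event list compatible with [bin_events()].
#' Uses the current RNG state.
#'
#' @param series a [photon_count_series()].
#' @return Sorted arrival times in seconds.
#' @export
events_from_counts <- function(series) {
  stopifnot(inherits(series, "photon_count_series"))
  idx <- rep.int(seq_along(series$counts), series$counts)
  ts <- (idx - 1 + runif(length(idx))) * series$bin_width
  sort(ts)
}
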