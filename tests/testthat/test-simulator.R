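test_that("identical seed and spec give identical streams", {
  spec <- simulation_spec(tissue_optics(), flow_constant(1e-8),
                         duration = 0.2, mean_count_rate = 5e4, seed = 9)
  a <- simulate_photon_stream(spec)
  b <- simulate_photon_stream(spec)
  expect_identical(a$counts, b$counts)
})

test_that("the realized count rate tracks the requested rate", {
  spec <- simulation_spec(tissue_optics(), flow_constant(1e-8),
                         duration = 1, mean_count_rate = 1e5,
                         n_modes = 2, seed = 11)
  s <- simulate_photon_stream(spec)
  rate <- sum(s$counts) / (length(s$counts) * s$bin_width)
  expect_lt(abs(rate - 1e5) / 1e5, 0.01)
})

test_that("constant intensity reduces detection to pure Poisson counting", {
  set.seed(3)
  spec <- simulation_spec(tissue_optics(), flow_constant(1e-8),
                         duration = 1, mean_count_rate = 1e5, seed = 3)
  field <- list(intensity = rep(1, 1e6), dt = 1e-6)
  s <- sample_photon_counts(field, spec)
  expect_lt(abs(sum(s$counts) - 1e5), 3 * sqrt(1e5))
  expect_gt(sum(s$counts), 0)
  # variance consistent with Poisson (not speckle-broadened)
  expect_lt(abs(var(s$counts) / mean(s$counts) - 1), 0.05)

  dark <- list(intensity = rep(0, 1e5), dt = 1e-6)
  expect_true(all(sample_photon_counts(dark, spec)$counts == 0))
})

test_that("the intercept is controlled by the mode count (beta = 1/M)", {
  cfg <- correlator_preset(80)
  con <- tissue_constants()
  for (m in c(1L, 2L, 4L)) {
    spec <- simulation_spec(tissue_optics(), flow_constant(1e-8),
                           duration = 3, mean_count_rate = 2e5,
                           n_modes = m, seed = 100 + m)
    curve <- multitau_correlate(simulate_photon_stream(spec), cfg)
    fit <- nelder_mead_fit(curve, con)
    tol <- if (m == 1L) 0.05 else 0.03
    expect_lt(abs(fit$flow$beta - 1 / m), tol,
              label = sprintf("beta estimate for M = %d", m))
  }
})

test_that("ensemble-averaged correlations reproduce the model at every lag", {
  cfg <- correlator_preset(80)
  con <- tissue_constants()
  n_seeds <- 20
  g2 <- matrix(NA_real_, n_seeds, 80)
  for (i in seq_len(n_seeds)) {
    spec <- simulation_spec(tissue_optics(), flow_constant(1e-8),
                           duration = 0.5, mean_count_rate = 2e5,
                           n_modes = 2, seed = 1000 + i)
    g2[i, ] <- multitau_correlate(simulate_photon_stream(spec), cfg)$g2
  }
  taus <- delay_schedule(cfg)
  model <- g2_model(con, list(alpha_db = 1e-8, beta = 0.5), taus)$g2
  se <- apply(g2, 2, sd) / sqrt(n_seeds)
  expect_true(all(abs(colMeans(g2) - model) < 3 * se + 1e-4))
})

test_that("a too-coarse field sampling step is refused", {
  expect_error(
    synthesize_speckle_intensity(
      simulation_spec(tissue_optics(), flow_constant(1e-5),
                      duration = 0.01, field_dt = 1e-6, seed = 1)),
    "too coarse")
})

test_that("scenario presets encode the experimental protocols", {
  cuff <- scenario_preset("cuff_ischemia")
  expect_s3_class(cuff, "simulation_spec")
  prof <- cuff$flow_profile
  expect_equal(prof$type, "piecewise")
  # 10 s baseline, then 25 s occlusion at strongly suppressed flow
  expect_equal(prof$alpha_at(5), prof$alpha_at(0.5))
  expect_lt(prof$alpha_at(20), 0.3 * prof$alpha_at(5))
  expect_lt(prof$alpha_at(34.9), 0.3 * prof$alpha_at(5))
  # post-release overshoot above baseline
  expect_gt(prof$alpha_at(36), prof$alpha_at(5))

  liquid <- scenario_preset("liquid_phantom_series")
  expect_length(liquid, 4)
  alphas <- vapply(liquid, function(s) s$flow_profile$alpha_range[1],
                   numeric(1))
  expect_true(all(diff(alphas) < 0))

  puls <- scenario_preset("pulsatile", pulse_hz = 1.2)
  expect_equal(puls$flow_profile$timescale, 1 / 1.2)

  expect_error(scenario_preset("treadmill"), "unknown scenario")
})

test_that("binned counts expand to consistent event timestamps", {
  set.seed(8)
  s <- rand_poisson_series(5000, 1)
  ts <- events_from_counts(s)
  expect_length(ts, sum(s$counts))
  expect_false(is.unsorted(ts))
  rebinned <- bin_events(ts, s$bin_width, length(s$counts) * s$bin_width)
  expect_equal(rebinned$counts, s$counts)
})
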