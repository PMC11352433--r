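test_that("event binning uses half-open bins and conserves counts", {
  s <- bin_events(c(0.2e-6, 0.7e-6, 1.5e-6), 1e-6, 2e-6)
  expect_equal(s$counts, c(2, 1))
  expect_equal(bin_events(numeric(0), 1e-6, 3e-6)$counts, c(0, 0, 0))
  # an event exactly on the k-th edge lands in bin k (0-based)
  s <- bin_events(c(1e-6), 1e-6, 3e-6)
  expect_equal(s$counts, c(0, 1, 0))
  expect_error(bin_events(c(2e-6, 1e-6), 1e-6, 3e-6), "sorted")
  expect_error(bin_events(c(1e-6, 5e-6), 1e-6, 3e-6), "within")
})

test_that("delay schedules reproduce the two hardware presets", {
  t80 <- delay_schedule(correlator_preset(80))
  expect_length(t80, 80)
  expect_true(all(diff(t80) > 0))
  expect_equal(t80[16], 16e-6)
  expect_equal(t80[17], 18e-6)  # first multi-tau stage: 9 * 2 us
  expect_equal(max(t80), 16 * 2^8 * 1e-6)

  t120 <- delay_schedule(correlator_preset(120))
  expect_length(t120, 120)
  expect_equal(max(t120), 16 * 2^13 * 1e-6)

  t16 <- delay_schedule(correlator_config(n_stages = 0))
  expect_equal(t16, (1:16) * 1e-6)
})

test_that("constant input gives g2 = 1 exactly at every lag", {
  cfg <- correlator_preset(80)
  s <- photon_count_series(rep(7, 10000), 1e-6)
  expect_identical(multitau_correlate(s, cfg)$g2, rep(1, 80))
  expect_identical(brute_force_correlate(s, cfg)$g2, rep(1, 80))
})

test_that("hand-computed normalization on an alternating series", {
  # series {1,0,1,0,...} of 16 bins: lag 1 pairs all cross parity -> G = 0;
  # lag 2: G = 7, Md = Mdel = 7, Ms = 14 -> g2 = 7 * 14 / 49 = 2
  s <- photon_count_series(rep(c(1, 0), 8), 1e-6)
  cfg <- correlator_config(n_stages = 0, first_stage_delays = 2)
  for (curve in list(brute_force_correlate(s, cfg),
                     multitau_correlate(s, cfg))) {
    expect_equal(curve$g2[1], 0)
    expect_equal(curve$g2[2], 2)
  }
})

test_that("i.i.d. Poisson counts decorrelate to g2 = 1 within shot noise", {
  set.seed(101)
  s <- photon_count_series(rpois(1e6, 100), 1e-6)
  g2 <- multitau_correlate(s, correlator_preset(80))$g2
  expect_true(all(abs(g2 - 1) < 0.01))
})

test_that("multi-tau equals the direct-summation reference on random input", {
  set.seed(2024)
  cfg80 <- correlator_preset(80)
  for (i in 1:20) {
    n <- sample(7000:60000, 1)
    s <- if (i %% 2 == 0) rand_poisson_series(n, rate = runif(1, 0.05, 20))
         else rand_bursty_series(n)
    expect_curves_equal(multitau_correlate(s, cfg80),
                        brute_force_correlate(s, cfg80))
  }
  cfg120 <- correlator_preset(120)
  s <- rand_poisson_series(250000, rate = 0.4)
  expect_curves_equal(multitau_correlate(s, cfg120),
                      brute_force_correlate(s, cfg120))
})

test_that("integer rescaling of the counts leaves g2 unchanged", {
  set.seed(5)
  cfg <- correlator_preset(80)
  s <- rand_poisson_series(20000, 3)
  g2a <- multitau_correlate(s, cfg)$g2
  s2 <- photon_count_series(s$counts * 7L, s$bin_width)
  expect_equal(multitau_correlate(s2, cfg)$g2, g2a, tolerance = 1e-14)
})

test_that("the estimator is symmetric under time reversal", {
  set.seed(6)
  cfg <- correlator_preset(80)
  n <- 256 * 40  # multiple of the coarsest stage width: no truncation
  s <- rand_poisson_series(n, 2)
  fwd <- multitau_correlate(s, cfg)$g2
  rev <- multitau_correlate(photon_count_series(rev(s$counts), s$bin_width),
                            cfg)$g2
  expect_equal(rev, fwd, tolerance = 1e-14)
})

test_that("short series are rejected with the minimum length named", {
  s <- rand_poisson_series(1000, 2)
  expect_error(multitau_correlate(s, correlator_preset(80)), "6144")
  expect_error(brute_force_correlate(s, correlator_preset(80)), "6144")
})

test_that("an all-zero window propagates NaN rather than failing", {
  s <- photon_count_series(rep(0, 10000), 1e-6)
  g2 <- multitau_correlate(s, correlator_preset(80))$g2
  expect_true(all(is.nan(g2)))
})
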