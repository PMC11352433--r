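test_that("the MSE objective matches direct summation", {
  con <- tissue_constants()
  taus <- delay_schedule(correlator_preset(80))
  truth <- list(alpha_db = 1e-8, beta = 0.5)
  curve <- g2_model(con, truth, taus)

  expect_equal(correlation_mse(curve, con, truth), 0)

  # constant offset c at every lag -> mse = c^2
  off <- correlation_curve(taus, curve$g2 + 0.03)
  expect_equal(correlation_mse(off, con, truth), 0.03^2, tolerance = 1e-12)

  # independent direct summation at a mismatched candidate
  cand <- list(alpha_db = 2e-8, beta = 0.5)
  model <- 1 + cand$beta * g1_model(con, cand$alpha_db, taus)^2
  acc <- 0
  for (i in seq_along(taus)) acc <- acc + (curve$g2[i] - model[i])^2
  expect_equal(correlation_mse(curve, con, cand), acc / length(taus),
               tolerance = 1e-14)

  bad <- correlation_curve(taus, replace(curve$g2, 3, NaN))
  expect_error(correlation_mse(bad, con, truth), "non-finite")
})

test_that("simplex sorting orders by MSE with a deterministic tie-break", {
  s <- structure(list(beta = c(0.3, 0.4, 0.5), ladb = c(-8, -9, -7),
                      mse = c(3, 1, 2)), class = "dcs_simplex")
  out <- sort_simplex(s)
  expect_equal(out$mse, c(1, 2, 3))
  expect_equal(out$beta, c(0.4, 0.5, 0.3))

  # equal MSEs: smaller alpha_db (ladb) wins, stably
  s$mse <- c(0.5, 0, 0.5)
  out <- sort_simplex(s)
  expect_equal(out$mse, c(0, 0.5, 0.5))
  expect_equal(out$ladb, c(-9, -8, -7))
  expect_identical(sort_simplex(s), out)
})

test_that("candidate points follow the classical simplex geometry", {
  cfg <- fit_config(beta_bounds = c(-10, 10),
                    alpha_db_bounds = c(1e-30, 1e30))
  # sorted: best (2,0), good (0,2), worst (0,0); centroid (1,1)
  s <- structure(list(beta = c(2, 0, 0), ladb = c(0, 2, 0),
                      mse = c(1, 2, 3)), class = "dcs_simplex")
  p <- propose_points(s, cfg)
  expect_equal(p$reflected, c(2, 2))
  expect_equal(p$expanded, c(3, 3))
  expect_equal(p$contracted, c(0.5, 0.5))

  degenerate <- structure(list(beta = c(1, 2, 3), ladb = c(1, 2, 3),
                               mse = c(1, 2, 3)), class = "dcs_simplex")
  expect_error(propose_points(degenerate, cfg), "degenerate")
})

test_that("candidates are clipped to the configured bounds", {
  cfg <- fit_config()  # beta capped at 1.2
  s <- structure(list(beta = c(1.1, 1.0, 0.3), ladb = c(-8, -7.5, -8),
                      mse = c(1, 2, 3)), class = "dcs_simplex")
  p <- propose_points(s, cfg)
  expect_lte(p$reflected[1], 1.2)
  expect_lte(p$expanded[1], 1.2)
})

test_that("noiseless curves are recovered to high precision over the grid", {
  con <- tissue_constants()
  taus <- delay_schedule(correlator_preset(80))
  for (beta in c(0.3, 0.5, 1.0)) {
    for (a in c(1e-9, 5e-9, 1e-8, 5e-8)) {
      curve <- g2_model(con, list(alpha_db = a, beta = beta), taus)
      fit <- nelder_mead_fit(curve, con)
      expect_lt(abs(fit$flow$alpha_db - a) / a, 1e-3)
      expect_lt(abs(fit$flow$beta - beta) / beta, 1e-3)
      # progress is monotone: the fit can never end above the best
      # initial vertex
      init_best <- min(vapply(fit_config()$initial_simplex, function(v) {
        correlation_mse(curve, con, v)
      }, numeric(1)))
      expect_lte(fit$mse, init_best)
    }
  }
})

test_that("the fitted MSE beats a dense grid search on noisy curves", {
  set.seed(77)
  con <- tissue_constants()
  taus <- delay_schedule(correlator_preset(80))
  betas <- seq(0.2, 1.1, length.out = 120)
  ladbs <- seq(-10, -6.5, length.out = 120)
  g1sq <- sapply(ladbs, function(l) g1_model(con, 10^l, taus)^2)
  for (i in 1:6) {
    truth <- list(alpha_db = 10^runif(1, -9, -7.5), beta = runif(1, 0.4, 0.9))
    noisy <- g2_model(con, truth, taus)$g2 + rnorm(length(taus), 0, 0.01)
    curve <- correlation_curve(taus, noisy)
    fit <- nelder_mead_fit(curve, con)
    # grid objective, vectorized over (beta, ladb)
    grid_min <- min(sapply(seq_along(betas), function(bi) {
      colMeans((noisy - (1 + betas[bi] * g1sq))^2)
    }))
    expect_lte(fit$mse, grid_min + 1e-12)
  }
})

test_that("a flat plateau pins beta and leaves the flow unconstrained", {
  con <- tissue_constants()
  taus <- (1:16) * 1e-9  # far below any decay at physiological flow
  curve <- correlation_curve(taus, rep(1 + 0.62, 16))
  fit <- nelder_mead_fit(curve, con)
  expect_lt(abs(fit$flow$beta - 0.62), 0.01)
  # with no decay information the fit either exhausts its iterations or
  # converges onto an MSE plateau; it must not claim a meaningful flow
  expect_true(fit$termination_reason %in% c("max_iterations", "tolerance"))
})

test_that("max_iterations = 0 returns the best initial vertex unconverged", {
  con <- tissue_constants()
  taus <- delay_schedule(correlator_preset(80))
  curve <- g2_model(con, list(alpha_db = 1e-8, beta = 0.5), taus)
  cfg <- fit_config(max_iterations = 0)
  fit <- nelder_mead_fit(curve, con, cfg)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 0L)
  mses <- vapply(cfg$initial_simplex, function(v) {
    correlation_mse(curve, con, v)
  }, numeric(1))
  expect_equal(fit$mse, min(mses))
})

test_that("invalid curves produce a failed result, not an error", {
  con <- tissue_constants()
  curve <- correlation_curve(c(1e-6, 2e-6), c(NaN, NaN))
  fit <- nelder_mead_fit(curve, con)
  expect_null(fit$flow)
  expect_equal(fit$termination_reason, "invalid_input")
})

test_that("the fit agrees with an independent general-purpose optimizer", {
  set.seed(31)
  con <- tissue_constants()
  taus <- delay_schedule(correlator_preset(80))
  noisy <- g2_model(con, list(alpha_db = 8e-9, beta = 0.55), taus)$g2 +
    rnorm(80, 0, 0.005)
  curve <- correlation_curve(taus, noisy)
  fit <- nelder_mead_fit(curve, con)
  ref <- optim(c(0.5, -8), function(p) {
    correlation_mse(curve, con, list(beta = p[1], alpha_db = 10^p[2]))
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(fit$flow$beta, ref$par[1], tolerance = 1e-3)
  expect_equal(log10(fit$flow$alpha_db), ref$par[2], tolerance = 1e-3)
})

test_that("the validity gate separates healthy and pathological curves", {
  taus <- delay_schedule(correlator_preset(80))
  good <- correlation_curve(taus, seq(1.45, 1.003, length.out = 80))
  expect_true(validate_curve(good)$pass)

  low <- correlation_curve(taus, seq(0.8, 1.0, length.out = 80))
  v <- validate_curve(low)
  expect_false(v$pass)
  expect_match(v$reason, "intercept below range")

  undecayed <- correlation_curve(taus, seq(1.6, 1.5, length.out = 80))
  v <- validate_curve(undecayed)
  expect_false(v$pass)
  expect_match(v$reason, "tail not decayed")

  nanny <- correlation_curve(taus, rep(NaN, 80))
  expect_false(validate_curve(nanny)$pass)
})
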