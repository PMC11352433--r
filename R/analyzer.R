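# Internal constructor that skips flow_state()'s physical-range checks:
# fitted beta may legitimately exceed 1 (up to the fit bound) on noisy data.
new_flow_state <- function(alpha_db, beta) {
  structure(list(alpha_db = alpha_db, beta = beta), class = "flow_state")
}

#' Fit configuration for the Nelder-Mead analyzer
#'
#' The simplex is a triangle in (beta, log10 alpha_db) space; alpha_db is
#' handled in log10 internally because it spans decades. Coefficients are
#' the classical Nelder-Mead choices. Termination follows the relative
#' spread criterion: the fit stops when
#' `|MSE(worst) - MSE(best)| / max(MSE(best), eps) < convergence_threshold`
#' or after `max_iterations` iterations.
#'
#' @param initial_simplex list of three (beta, alpha_db) pairs, each a
#'   [flow_state()] or a list with those fields. The default spans the
#'   physiological / phantom range.
#' @param alpha_r reflection coefficient (> 0, default 1).
#' @param gamma expansion coefficient (> 1, default 2).
#' @param rho_c contraction coefficient (in (0, 1), default 0.5).
#' @param sigma shrink coefficient (in (0, 1), default 0.5).
#' @param convergence_threshold relative MSE spread for termination.
#' @param max_iterations iteration cap.
#' @param beta_bounds,alpha_db_bounds box constraints; candidates are
#'   clipped to these.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(initial_simplex = list(
                         list(beta = 0.40, alpha_db = 1e-9),
                         list(beta = 0.55, alpha_db = 1e-8),
                         list(beta = 0.45, alpha_db = 5e-8)),
                       alpha_r = 1, gamma = 2, rho_c = 0.5, sigma = 0.5,
                       convergence_threshold = 1e-4,
                       max_iterations = 100,
                       beta_bounds = c(1e-3, 1.2),
                       alpha_db_bounds = c(1e-12, 1e-5)) {
  stopifnot(length(initial_simplex) == 3L,
            alpha_r > 0, gamma > 1, rho_c > 0, rho_c < 1,
            sigma > 0, sigma < 1,
            convergence_threshold > 0, max_iterations >= 0,
            length(beta_bounds) == 2L, length(alpha_db_bounds) == 2L,
            all(alpha_db_bounds > 0), diff(beta_bounds) > 0,
            diff(alpha_db_bounds) > 0)
  structure(
    list(initial_simplex = initial_simplex,
         alpha_r = alpha_r, gamma = gamma, rho_c = rho_c, sigma = sigma,
         convergence_threshold = convergence_threshold,
         max_iterations = as.integer(max_iterations),
         beta_bounds = beta_bounds,
         ladb_bounds = log10(alpha_db_bounds)),
    class = "fit_config"
  )
}

#' Mean squared error between a measured and a model correlation
#'
#' Mean over all scheduled lags of the squared difference between the
#' measured g2 and [g2_model()] evaluated at the candidate flow state.
#' Every lag of the curve enters the objective.
#'
#' @param measured a [correlation_curve()].
#' @param constants a [derive_constants()] result.
#' @param flow candidate [flow_state()] (or list with `alpha_db`, `beta`).
#' @return The MSE (dimensionless, >= 0).
#' @export
correlation_mse <- function(measured, constants, flow) {
  stopifnot(inherits(measured, "correlation_curve"))
  if (any(!is.finite(measured$g2))) {
    stop("measured correlation contains non-finite values")
  }
  model <- g2_model(constants, flow, measured$taus)
  mean((measured$g2 - model$g2)^2)
}

# Simplex: three vertices in (beta, ladb = log10 alpha_db), with MSEs.
new_simplex <- function(beta, ladb, mse = rep(NA_real_, 3L)) {
  structure(list(beta = beta, ladb = ladb, mse = mse), class = "dcs_simplex")
}

simplex_area <- function(simplex) {
  x <- simplex$beta; y <- simplex$ladb
  abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
}

#' Sort a simplex into best / good / worst order
#'
#' Orders the three vertices by ascending MSE (best, good, worst). Ties are
#' broken deterministically in favor of the vertex with the smaller
#' alpha_db.
#'
#' @param simplex a simplex as built by [nelder_mead_fit()] internals: a
#'   list with numeric fields `beta`, `ladb` (log10 alpha_db) and `mse`,
#'   each of length 3.
#' @return The simplex with vertices reordered so
#'   `mse[1] <= mse[2] <= mse[3]`.
#' @export
sort_simplex <- function(simplex) {
  stopifnot(length(simplex$mse) == 3L, all(is.finite(simplex$mse)))
  ord <- order(simplex$mse, simplex$ladb)
  new_simplex(simplex$beta[ord], simplex$ladb[ord], simplex$mse[ord])
}

clip_point <- function(p, config) {
  c(min(max(p[1], config$beta_bounds[1]), config$beta_bounds[2]),
    min(max(p[2], config$ladb_bounds[1]), config$ladb_bounds[2]))
}

#' Candidate points of one Nelder-Mead step
#'
#' From a sorted simplex (best, good, worst), computes the centroid `c` of
#' the best and good vertices and the classical candidate points:
#' reflected `c + alpha_r (c - worst)`, expanded
#' `c + gamma (reflected - c)`, outside contraction
#' `c + rho_c (reflected - c)`, inside contraction
#' `c + rho_c (worst - c)`, and the shrink replacements
#' `best + sigma (v - best)` for the good and worst vertices. All
#' candidates are clipped to the configured bounds.
#'
#' @param simplex a sorted simplex (see [sort_simplex()]).
#' @param config a [fit_config()].
#' @return A list with entries `centroid`, `reflected`, `expanded`,
#'   `contracted_outside`, `contracted`, `shrunk_good`, `shrunk_worst`,
#'   each a `(beta, ladb)` pair.
#' @export
propose_points <- function(simplex, config) {
  if (simplex_area(simplex) <= 0) {
    stop("degenerate simplex: zero area in (beta, log10 alpha_db) space")
  }
  b <- c(simplex$beta[1], simplex$ladb[1])
  g <- c(simplex$beta[2], simplex$ladb[2])
  w <- c(simplex$beta[3], simplex$ladb[3])
  ctr <- (b + g) / 2
  refl <- ctr + config$alpha_r * (ctr - w)
  list(
    centroid = ctr,
    reflected = clip_point(refl, config),
    expanded = clip_point(ctr + config$gamma * (refl - ctr), config),
    contracted_outside = clip_point(ctr + config$rho_c * (refl - ctr), config),
    contracted = clip_point(ctr + config$rho_c * (w - ctr), config),
    shrunk_good = clip_point(b + config$sigma * (g - b), config),
    shrunk_worst = clip_point(b + config$sigma * (w - b), config)
  )
}

#' Validity gate for a measured correlation curve
#'
#' Mirrors the pre-fit sanity check of a hardware DCS processor: the first
#' point of the autocorrelation (the intercept, nominally 1 + beta) and the
#' last point (the decayed tail, nominally 1) must lie in their expected
#' ranges before the curve is handed to the analyzer.
#'
#' @param measured a [correlation_curve()].
#' @param gate list with `first_lo`, `first_hi` (bounds on the first g2
#'   value, defaults 1.05 and 2.0) and `last_tol` (maximum |last g2 - 1|,
#'   default 0.1).
#' @return A list with `pass` (logical) and `reason` (`"ok"` or a short
#'   diagnostic).
#' @export
validate_curve <- function(measured,
                           gate = list(first_lo = 1.05, first_hi = 2.0,
                                       last_tol = 0.1)) {
  stopifnot(inherits(measured, "correlation_curve"),
            length(measured$g2) >= 2L)
  g2 <- measured$g2
  if (any(!is.finite(g2))) {
    return(list(pass = FALSE, reason = "non-finite correlation values"))
  }
  first <- g2[1L]
  last <- g2[length(g2)]
  if (first <= gate$first_lo) {
    return(list(pass = FALSE, reason = "intercept below range"))
  }
  if (first >= gate$first_hi) {
    return(list(pass = FALSE, reason = "intercept above range"))
  }
  if (abs(last - 1) >= gate$last_tol) {
    return(list(pass = FALSE, reason = "tail not decayed"))
  }
  list(pass = TRUE, reason = "ok")
}

fit_result <- function(flow, mse, iterations, converged, termination_reason) {
  structure(
    list(flow = flow, mse = mse, iterations = iterations,
         converged = converged, termination_reason = termination_reason),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  if (is.null(x$flow)) {
    cat(sprintf("<fit_result> failed (%s)\n", x$termination_reason))
  } else {
    cat(sprintf(
      "<fit_result> alpha_db = %.4g cm^2/s, beta = %.4g, mse = %.3g, %d iterations (%s)\n",
      x$flow$alpha_db, x$flow$beta, x$mse, x$iterations,
      x$termination_reason))
  }
  invisible(x)
}

#' Fit (beta, alpha_db) to a measured correlation by Nelder-Mead
#'
#' Minimizes [correlation_mse()] over the coherence factor beta and the
#' blood flow index alpha_db with the Nelder-Mead simplex method, mirroring
#' a hardware analyzer's decomposition: MSE evaluation, vertex sorting,
#' candidate-point calculation ([propose_points()]), acceptance decision,
#' and termination check. The simplex lives in (beta, log10 alpha_db)
#' space; candidates are clipped to the configured box bounds.
#'
#' Acceptance follows the standard rules: a reflected point between the
#' best and good MSE replaces the worst vertex; one better than the best
#' triggers an expansion and the better of reflected/expanded is kept; one
#' worse than the good triggers an outside (or, if worse than the worst,
#' inside) contraction; a failed contraction shrinks the simplex toward
#' the best vertex.
#'
#' @param measured a [correlation_curve()]; curves with non-finite values
#'   yield a failed result with `termination_reason = "invalid_input"`.
#' @param constants a [derive_constants()] result.
#' @param config a [fit_config()].
#' @return A [flow_state()]-bearing `fit_result` with fields `flow`,
#'   `mse`, `iterations`, `converged`, `termination_reason` (one of
#'   `"tolerance"`, `"max_iterations"`, `"invalid_input"`).
#' @examples
#' con <- derive_constants(optical_config(0.1, 10, 1))
#' curve <- g2_model(con, flow_state(1e-8, 0.5), delay_schedule(correlator_preset(80)))
#' nelder_mead_fit(curve, con)
#' @export
nelder_mead_fit <- function(measured, constants, config = fit_config()) {
  stopifnot(inherits(measured, "correlation_curve"),
            inherits(constants, "model_constants"),
            inherits(config, "fit_config"))
  if (any(!is.finite(measured$g2))) {
    return(fit_result(NULL, NA_real_, 0L, FALSE, "invalid_input"))
  }

  eval_mse <- function(p) {
    correlation_mse(measured, constants,
                    list(beta = p[1], alpha_db = 10^p[2]))
  }

  init <- lapply(config$initial_simplex, function(v) {
    clip_point(c(v$beta, log10(v$alpha_db)), config)
  })
  simplex <- new_simplex(
    beta = vapply(init, `[`, numeric(1L), 1L),
    ladb = vapply(init, `[`, numeric(1L), 2L)
  )
  if (simplex_area(simplex) <= 0) {
    return(fit_result(NULL, NA_real_, 0L, FALSE, "invalid_input"))
  }
  simplex$mse <- vapply(seq_len(3L), function(i) {
    eval_mse(c(simplex$beta[i], simplex$ladb[i]))
  }, numeric(1L))

  replace_worst <- function(simplex, p, f) {
    simplex$beta[3] <- p[1]; simplex$ladb[3] <- p[2]; simplex$mse[3] <- f
    simplex
  }

  iterations <- 0L
  converged <- FALSE
  reason <- "max_iterations"
  eps <- 1e-30
  while (iterations < config$max_iterations) {
    simplex <- sort_simplex(simplex)
    spread <- abs(simplex$mse[3] - simplex$mse[1]) /
      max(simplex$mse[1], eps)
    if (spread < config$convergence_threshold) {
      converged <- TRUE
      reason <- "tolerance"
      break
    }
    iterations <- iterations + 1L
    cand <- tryCatch(propose_points(simplex, config), error = function(e) NULL)
    if (is.null(cand)) {
      # simplex collapsed to zero area (e.g. pinned on a bound): treat as
      # converged to the current best vertex
      converged <- TRUE
      reason <- "tolerance"
      break
    }
    f_r <- eval_mse(cand$reflected)
    if (f_r < simplex$mse[1]) {
      f_e <- eval_mse(cand$expanded)
      simplex <- if (f_e < f_r) {
        replace_worst(simplex, cand$expanded, f_e)
      } else {
        replace_worst(simplex, cand$reflected, f_r)
      }
    } else if (f_r < simplex$mse[2]) {
      simplex <- replace_worst(simplex, cand$reflected, f_r)
    } else if (f_r < simplex$mse[3]) {
      f_oc <- eval_mse(cand$contracted_outside)
      if (f_oc <= f_r) {
        simplex <- replace_worst(simplex, cand$contracted_outside, f_oc)
      } else {
        f_sg <- eval_mse(cand$shrunk_good)
        f_sw <- eval_mse(cand$shrunk_worst)
        simplex$beta[2:3] <- c(cand$shrunk_good[1], cand$shrunk_worst[1])
        simplex$ladb[2:3] <- c(cand$shrunk_good[2], cand$shrunk_worst[2])
        simplex$mse[2:3] <- c(f_sg, f_sw)
      }
    } else {
      f_ic <- eval_mse(cand$contracted)
      if (f_ic < simplex$mse[3]) {
        simplex <- replace_worst(simplex, cand$contracted, f_ic)
      } else {
        f_sg <- eval_mse(cand$shrunk_good)
        f_sw <- eval_mse(cand$shrunk_worst)
        simplex$beta[2:3] <- c(cand$shrunk_good[1], cand$shrunk_worst[1])
        simplex$ladb[2:3] <- c(cand$shrunk_good[2], cand$shrunk_worst[2])
        simplex$mse[2:3] <- c(f_sg, f_sw)
      }
    }
  }
  simplex <- sort_simplex(simplex)
  fit_result(
    flow = new_flow_state(alpha_db = 10^simplex$ladb[1],
                          beta = simplex$beta[1]),
    mse = simplex$mse[1],
    iterations = iterations,
    converged = converged,
    termination_reason = reason
  )
}
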