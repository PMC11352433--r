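#' Pipeline configuration: windowed counts-to-BFI processing
#'
#' @param optics an [optical_config()].
#' @param measurement_rate BFI output rate, Hz; each BFI is fitted from a
#'   non-overlapping window of `1/measurement_rate` seconds of counts
#'   (presets of interest: 1 Hz and 50 Hz).
#' @param correlator a [correlator_config()]; the window must contain at
#'   least the schedule's minimum support (so the 120-delay schedule is
#'   refused at 50 Hz, where its largest lag exceeds the window).
#' @param fit a [fit_config()].
#' @param gate validity-gate bounds, see [validate_curve()].
#' @param smoothing_window odd moving-average width in points applied to
#'   the BFI series (0 or 1 = off).
#' @param verbose emit a per-window log line.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(optics, measurement_rate = 1,
                            correlator = correlator_preset(80),
                            fit = fit_config(),
                            gate = list(first_lo = 1.05, first_hi = 2.0,
                                        last_tol = 0.1),
                            smoothing_window = 0,
                            verbose = FALSE) {
  stopifnot(inherits(optics, "optical_config"),
            measurement_rate > 0,
            inherits(correlator, "correlator_config"),
            inherits(fit, "fit_config"),
            smoothing_window >= 0)
  if (smoothing_window > 1 && smoothing_window %% 2 == 0) {
    stop("smoothing_window must be odd (centered moving average)")
  }
  window_s <- 1 / measurement_rate
  need_s <- min_series_length(correlator) * correlator$base_bin
  if (window_s < need_s) {
    stop(sprintf(
      "window of %g s (rate %g Hz) cannot hold the %d-delay schedule: it needs at least %g s of counts (largest lag %g s)",
      window_s, measurement_rate,
      correlator$first_stage_delays +
        correlator$n_stages * correlator$stage_delays,
      need_s, max(delay_schedule(correlator))))
  }
  structure(
    list(optics = optics, measurement_rate = measurement_rate,
         correlator = correlator, fit = fit, gate = gate,
         smoothing_window = as.integer(smoothing_window),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

new_bfi_time_series <- function(df, measurement_rate) {
  structure(df, class = c("bfi_time_series", "data.frame"),
            measurement_rate = measurement_rate)
}

#' @export
print.bfi_time_series <- function(x, ...) {
  ok <- sum(!is.na(x$alpha_db))
  cat(sprintf(
    "<bfi_time_series> %d windows at %g Hz, %d fitted (%d missing)\n",
    nrow(x), attr(x, "measurement_rate"), ok, nrow(x) - ok))
  if (ok > 0) {
    cat(sprintf("  alpha_db: mean %.4g cm^2/s, range %.4g..%.4g\n",
                mean(x$alpha_db, na.rm = TRUE),
                min(x$alpha_db, na.rm = TRUE),
                max(x$alpha_db, na.rm = TRUE)))
  }
  invisible(x)
}

#' Windowed counts-to-BFI processing
#'
#' Cuts the photon-count stream into non-overlapping windows of
#' `1/measurement_rate` seconds aligned to the stream start and, per
#' window, runs [multitau_correlate()], the [validate_curve()] gate and
#' [nelder_mead_fit()]. Windows whose curve fails the gate (or whose fit
#' input is invalid) yield missing BFI values with the reason recorded;
#' the stream is never aborted by a single bad window. A trailing partial
#' window is dropped.
#'
#' @param counts a [photon_count_series()] spanning at least one window.
#' @param config a [pipeline_config()].
#' @return A `bfi_time_series`: a data frame with one row per window
#'   (`t_s`, `alpha_db`, `beta`, `mse`, `iterations`, `converged`,
#'   `gate_status`) carrying the measurement rate as an attribute. If
#'   `config$smoothing_window > 1` the BFI column is smoothed with
#'   [moving_average()].
#' @examples
#' spec <- scenario_preset("pulsatile", duration = 2)
#' counts <- simulate_photon_stream(spec)
#' cfg <- pipeline_config(spec$optics, measurement_rate = 1)
#' run_pipeline(counts, cfg)
#' @export
run_pipeline <- function(counts, config) {
  stopifnot(inherits(counts, "photon_count_series"),
            inherits(config, "pipeline_config"))
  w_bins <- round(1 / (config$measurement_rate * counts$bin_width))
  if (w_bins < min_series_length(config$correlator)) {
    stop("window shorter than the correlator's minimum support")
  }
  n_windows <- length(counts$counts) %/% w_bins
  if (n_windows < 1L) stop("count stream shorter than one window")
  dropped <- length(counts$counts) - n_windows * w_bins
  if (config$verbose && dropped > 0) {
    message(sprintf("dropping trailing partial window (%d bins)", dropped))
  }
  constants <- derive_constants(config$optics)
  res <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    idx <- ((i - 1L) * w_bins + 1L):(i * w_bins)
    win <- photon_count_series(counts$counts[idx],
                               bin_width = counts$bin_width)
    curve <- multitau_correlate(win, config$correlator)
    gate <- validate_curve(curve, config$gate)
    if (gate$pass) {
      fit <- nelder_mead_fit(curve, constants, config$fit)
      row <- data.frame(
        t_s = (i - 1L) * w_bins * counts$bin_width,
        alpha_db = if (is.null(fit$flow)) NA_real_ else fit$flow$alpha_db,
        beta = if (is.null(fit$flow)) NA_real_ else fit$flow$beta,
        mse = fit$mse, iterations = fit$iterations,
        converged = fit$converged, gate_status = "ok"
      )
    } else {
      row <- data.frame(
        t_s = (i - 1L) * w_bins * counts$bin_width,
        alpha_db = NA_real_, beta = NA_real_, mse = NA_real_,
        iterations = 0L, converged = FALSE, gate_status = gate$reason
      )
    }
    if (config$verbose) {
      message(sprintf(
        "window %d/%d t=%.3fs gate=%s alpha_db=%.3g iters=%d",
        i, n_windows, row$t_s, row$gate_status, row$alpha_db,
        row$iterations))
    }
    res[[i]] <- row
  }
  out <- new_bfi_time_series(do.call(rbind, res), config$measurement_rate)
  if (config$smoothing_window > 1L) {
    out <- moving_average(out, config$smoothing_window)
  }
  out
}

moving_average_vec <- function(x, window_points) {
  n <- length(x)
  half <- (window_points - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    v <- x[lo:hi]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
}

#' Centered moving-average filter
#'
#' A centered box filter of odd width over the BFI values, as used to
#' suppress high-frequency noise in fast (50 Hz) BFI traces before
#' display or spectral reading. Edges use the truncated available window;
#' missing values are excluded from each local mean; length is preserved.
#'
#' @param series a `bfi_time_series` (smooths `alpha_db`) or a plain
#'   numeric vector.
#' @param window_points odd window width in points; 1 is the identity.
#' @return Same type as `series`.
#' @export
moving_average <- function(series, window_points) {
  stopifnot(window_points >= 1, window_points %% 2 == 1)
  if (is.numeric(series)) {
    return(moving_average_vec(series, as.integer(window_points)))
  }
  stopifnot(inherits(series, "bfi_time_series"))
  series$alpha_db <- moving_average_vec(series$alpha_db,
                                        as.integer(window_points))
  series
}

#' Amplitude spectrum of a BFI segment with dominant-peak report
#'
#' Discrete Fourier magnitude spectrum of the mean-removed BFI series over
#' a time segment, used to read the heart-rate line from pulsatile flow.
#' Missing values are linearly interpolated (flagged in the result).
#' Frequencies up to the Nyquist rate are returned together with the
#' location of the largest peak above 0.5 Hz (excluding DC and the
#' low-frequency drift band).
#'
#' @param series a `bfi_time_series` (uniformly sampled at its
#'   measurement rate).
#' @param t_range optional `c(from, to)` time window in seconds; default
#'   the whole series. Must span at least 4 s for usable resolution.
#' @return A list with `freq` (Hz), `magnitude` (mean-removed amplitude),
#'   `peak_freq`, `peak_magnitude` (both `NA` if the segment carries no
#'   signal above 0.5 Hz), and `interpolated`.
#' @export
bfi_spectrum <- function(series, t_range = NULL) {
  stopifnot(inherits(series, "bfi_time_series"))
  rate <- attr(series, "measurement_rate")
  x <- series$alpha_db
  t <- series$t_s
  if (!is.null(t_range)) {
    keep <- t >= t_range[1] & t < t_range[2]
    x <- x[keep]; t <- t[keep]
  }
  if (length(x) < 4 * rate) {
    stop("segment shorter than 4 s: insufficient frequency resolution")
  }
  interpolated <- anyNA(x)
  if (interpolated) {
    x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  }
  n <- length(x)
  mag <- Mod(fft(x - mean(x))) / n
  freq <- (seq_len(n) - 1L) * rate / n
  keep <- freq <= rate / 2
  freq <- freq[keep]; mag <- mag[keep]
  cand <- which(freq > 0.5)
  if (length(cand) == 0L || max(mag[cand]) <= 0) {
    peak_freq <- NA_real_; peak_mag <- NA_real_
  } else {
    i <- cand[which.max(mag[cand])]
    peak_freq <- freq[i]; peak_mag <- mag[i]
  }
  structure(
    list(freq = freq, magnitude = mag, peak_freq = peak_freq,
         peak_magnitude = peak_mag, interpolated = interpolated),
    class = "bfi_spectrum"
  )
}

#' @export
print.bfi_spectrum <- function(x, ...) {
  if (is.na(x$peak_freq)) {
    cat("<bfi_spectrum> no peak above 0.5 Hz\n")
  } else {
    cat(sprintf("<bfi_spectrum> dominant peak at %.3f Hz (amplitude %.3g)\n",
                x$peak_freq, x$peak_magnitude))
  }
  invisible(x)
}
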