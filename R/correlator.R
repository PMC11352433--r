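#' Photon counts in uniform time bins
#'
#' The correlator's input: nonnegative integer photon counts per fixed time
#' bin (the hardware counterpart bins APD pulses into 1 microsecond bins).
#'
#' @param counts integer-valued vector of photon counts, one per bin.
#' @param bin_width bin duration in seconds (default 1e-6).
#' @param t0 start time of the first bin, seconds.
#' @return An object of class `photon_count_series`.
#' @export
photon_count_series <- function(counts, bin_width = 1e-6, t0 = 0) {
  stopifnot(is.numeric(counts), length(counts) >= 1L,
            is.numeric(bin_width), length(bin_width) == 1L)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  structure(
    list(counts = as.numeric(counts), bin_width = bin_width, t0 = t0),
    class = "photon_count_series"
  )
}

#' @export
print.photon_count_series <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf(
    "<photon_count_series> %d bins x %g s (%.4g s), %d counts (%.4g counts/s)\n",
    n, x$bin_width, n * x$bin_width, sum(x$counts),
    sum(x$counts) / (n * x$bin_width)))
  invisible(x)
}

#' Bin photon arrival timestamps into uniform counts
#'
#' Counts events in half-open intervals `[k*bin_width, (k+1)*bin_width)`;
#' an event exactly on a bin edge belongs to the later bin.
#'
#' @param timestamps sorted arrival times in seconds, within `[0, duration)`.
#' @param bin_width bin duration, seconds.
#' @param duration total duration covered, seconds; the number of bins is
#'   `ceiling(duration / bin_width)`.
#' @return A [photon_count_series()].
#' @examples
#' bin_events(c(0.2e-6, 0.7e-6, 1.5e-6), 1e-6, 2e-6)$counts  # 2 1
#' @export
bin_events <- function(timestamps, bin_width, duration) {
  stopifnot(is.numeric(bin_width), bin_width > 0,
            is.numeric(duration), duration > 0)
  n_bins <- as.integer(ceiling(duration / bin_width - 1e-9))
  if (length(timestamps) == 0L) {
    return(photon_count_series(integer(n_bins), bin_width))
  }
  if (is.unsorted(timestamps)) stop("timestamps must be sorted")
  if (timestamps[1L] < 0 || timestamps[length(timestamps)] >= duration) {
    stop("timestamps must lie within [0, duration)")
  }
  idx <- floor(timestamps / bin_width) + 1
  idx <- pmin(idx, n_bins)  # guard float roundoff at the last edge
  photon_count_series(tabulate(idx, nbins = n_bins), bin_width)
}

#' Multi-tau correlator configuration
#'
#' Defines the quasi-logarithmic lag schedule: a linear first stage of
#' `first_stage_delays` lags at the base bin width, followed by `n_stages`
#' multi-tau stages of `stage_delays` lags each, the bin width multiplying
#' by `coarsening_factor` per stage so consecutive stages continue the
#' schedule contiguously. The two hardware presets are 80 delays
#' (16 + 8 stages x 8, physiological / liquid phantom) and 120 delays
#' (16 + 13 stages x 8, slow solid-phantom decays).
#'
#' @param n_stages number of multi-tau stages after the first stage.
#' @param base_bin base bin width in seconds (default 1e-6).
#' @param first_stage_delays lags in the linear first stage (default 16).
#' @param stage_delays lags per multi-tau stage (default 8).
#' @param coarsening_factor bin-width multiplier per stage (default 2).
#' @return An object of class `correlator_config`.
#' @examples
#' length(delay_schedule(correlator_preset(80)))   # 80
#' max(delay_schedule(correlator_preset(120)))     # 16 * 2^13 us
#' @export
correlator_config <- function(n_stages = 8, base_bin = 1e-6,
                              first_stage_delays = 16, stage_delays = 8,
                              coarsening_factor = 2) {
  stopifnot(first_stage_delays >= 1, stage_delays >= 1, n_stages >= 0,
            coarsening_factor >= 2, base_bin > 0)
  cfg <- structure(
    list(base_bin = base_bin,
         first_stage_delays = as.integer(first_stage_delays),
         stage_delays = as.integer(stage_delays),
         n_stages = as.integer(n_stages),
         coarsening_factor = as.integer(coarsening_factor)),
    class = "correlator_config"
  )
  schedule_table(cfg)  # validate contiguity
  cfg
}

#' @rdname correlator_config
#' @param n_delays total delay count, 80 or 120.
#' @export
correlator_preset <- function(n_delays = 80, base_bin = 1e-6) {
  n_delays <- as.integer(n_delays)
  if (!n_delays %in% c(80L, 120L)) {
    stop("available presets: 80 (physiological) or 120 (solid phantom)")
  }
  correlator_config(n_stages = (n_delays - 16L) %/% 8L, base_bin = base_bin)
}

#' @export
print.correlator_config <- function(x, ...) {
  sched <- delay_schedule(x)
  cat(sprintf(
    "<correlator_config> %d delays (%d + %d x %d), base bin %g s, max lag %g s\n",
    length(sched), x$first_stage_delays, x$n_stages, x$stage_delays,
    x$base_bin, max(sched)))
  invisible(x)
}

# Per-lag table: stage index, lag k in stage bins, lag in base bins.
schedule_table <- function(config) {
  m <- config$coarsening_factor
  stage <- integer(0); k <- integer(0)
  stage <- c(stage, rep.int(0L, config$first_stage_delays))
  k <- c(k, seq_len(config$first_stage_delays))
  last_k <- config$first_stage_delays  # max lag, in current-stage bins
  if (config$n_stages > 0) {
    for (s in seq_len(config$n_stages)) {
      if (last_k %% m != 0L) {
        stop("schedule not contiguous: previous stage maximum lag (",
             last_k, " bins) is not divisible by the coarsening factor")
      }
      start <- last_k %/% m + 1L
      ks <- seq.int(start, start + config$stage_delays - 1L)
      stage <- c(stage, rep.int(s, config$stage_delays))
      k <- c(k, ks)
      last_k <- ks[length(ks)]
    }
  }
  lag_base <- k * m^stage
  data.frame(stage = stage, k = k, lag_base_bins = lag_base)
}

#' Lag times of the multi-tau schedule
#'
#' @param config a [correlator_config()].
#' @return Strictly increasing lag times in seconds.
#' @export
delay_schedule <- function(config) {
  stopifnot(inherits(config, "correlator_config"))
  schedule_table(config)$lag_base_bins * config$base_bin
}

# Minimum series length (base bins) for a schedule: the coarsest stage must
# retain at least 8 samples beyond its largest lag.
min_series_length <- function(config) {
  tab <- schedule_table(config)
  s_max <- max(tab$stage)
  k_max <- max(tab$k[tab$stage == s_max])
  (k_max + 8L) * config$coarsening_factor^s_max
}

#' Measured or modeled correlation curve
#'
#' @param taus lag times, seconds, strictly increasing.
#' @param g2 normalized intensity autocorrelation values.
#' @param n_samples number of base bins that contributed (optional).
#' @param mean_rate mean count rate in counts/s (optional).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(taus, g2, n_samples = NA_real_,
                              mean_rate = NA_real_) {
  stopifnot(is.numeric(taus), is.numeric(g2), length(taus) == length(g2),
            length(taus) >= 1L)
  if (length(taus) > 1L && any(diff(taus) <= 0)) {
    stop("taus must be strictly increasing")
  }
  structure(
    list(taus = as.numeric(taus), g2 = as.numeric(g2),
         n_samples = n_samples, mean_rate = mean_rate),
    class = "correlation_curve"
  )
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "<correlation_curve> %d lags, tau %.3g..%.3g s, g2[1] = %.4g, g2[end] = %.4g\n",
    length(x$taus), min(x$taus), max(x$taus), x$g2[1L],
    x$g2[length(x$g2)]))
  invisible(x)
}

#' Multi-tau intensity autocorrelation of a photon-count series
#'
#' Estimates the normalized intensity autocorrelation g2 over the
#' quasi-logarithmic lag schedule of `config`. Each multi-tau stage works
#' on the series coarsened by successive pairwise summation; for a lag of
#' `k` stage bins, with `Ms` usable sample pairs,
#' \deqn{g_2(k) = \frac{M_s \sum_i n_i n_{i+k}}
#'       {\left(\sum_i n_i\right)\left(\sum_i n_{i+k}\right)}}
#' (symmetric normalization: direct and delayed monitors over the same
#' index range, no wraparound or zero padding). A constant input therefore
#' gives g2 = 1 exactly at every lag, and scaling all counts leaves g2
#' unchanged.
#'
#' @param series a [photon_count_series()] whose bin width equals the
#'   schedule's base bin.
#' @param config a [correlator_config()].
#' @return A [correlation_curve()]; lags for which a monitor sum is zero
#'   (e.g. an all-zero window) yield `NaN`.
#' @seealso [brute_force_correlate()] for the exact reference estimator.
#' @export
multitau_correlate <- function(series, config) {
  stopifnot(inherits(series, "photon_count_series"),
            inherits(config, "correlator_config"))
  if (abs(series$bin_width - config$base_bin) >
      1e-12 * max(series$bin_width, config$base_bin)) {
    stop("series bin_width (", series$bin_width,
         " s) does not match the schedule base bin (", config$base_bin, " s)")
  }
  n <- length(series$counts)
  need <- min_series_length(config)
  if (n < need) {
    stop("series too short for this schedule: ", n,
         " base bins given, at least ", need, " required")
  }
  tab <- schedule_table(config)
  res <- multitau_core(series$counts, tab$stage, tab$k,
                       config$coarsening_factor)
  g2 <- ifelse(res[, "Md"] > 0 & res[, "Mdel"] > 0,
               res[, "G"] * res[, "Ms"] / (res[, "Md"] * res[, "Mdel"]),
               NaN)
  correlation_curve(
    taus = tab$lag_base_bins * config$base_bin,
    g2 = g2,
    n_samples = n,
    mean_rate = sum(series$counts) / (n * series$bin_width)
  )
}

#' Exact reference autocorrelator (direct summation)
#'
#' Computes the same normalized autocorrelation as [multitau_correlate()]
#' by explicitly coarsening the whole series to each lag's stage
#' resolution and summing the lag products directly. It is an O(N x L)
#' reference estimator kept deliberately independent of the streaming
#' multi-tau implementation so the two can be cross-validated.
#'
#' @inheritParams multitau_correlate
#' @return A [correlation_curve()].
#' @export
brute_force_correlate <- function(series, config) {
  stopifnot(inherits(series, "photon_count_series"),
            inherits(config, "correlator_config"))
  n <- length(series$counts)
  need <- min_series_length(config)
  if (n < need) {
    stop("series too short for this schedule: ", n,
         " base bins given, at least ", need, " required")
  }
  tab <- schedule_table(config)
  m <- config$coarsening_factor
  g2 <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    w <- m^tab$stage[i]
    n_c <- (n %/% w) * w
    x <- if (w == 1L) series$counts else {
      colSums(matrix(series$counts[seq_len(n_c)], nrow = w))
    }
    k <- tab$k[i]
    ms <- length(x) - k
    lead <- x[seq_len(ms)]
    lagd <- x[seq_len(ms) + k]
    G <- sum(lead * lagd)
    md <- sum(lead)
    mdel <- sum(lagd)
    g2[i] <- if (md > 0 && mdel > 0) G * ms / (md * mdel) else NaN
  }
  correlation_curve(
    taus = tab$lag_base_bins * config$base_bin,
    g2 = g2,
    n_samples = n,
    mean_rate = sum(series$counts) / (n * series$bin_width)
  )
}
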