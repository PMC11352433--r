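# Plain-text (and raw binary event) file formats for every pipeline
# intermediate, with line-numbered diagnostics on malformed input. All
# read/write pairs round-trip exactly.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Event-file input and output
#'
#' Two interchangeable formats selected by extension: plain text with one
#' arrival time in seconds per line, or (extension `.bin`) raw
#' little-endian unsigned 64-bit integer timestamps in nanoseconds.
#'
#' @param timestamps sorted arrival times, seconds.
#' @param path file path; a `.bin` suffix selects the binary format.
#' @return `read_events()` returns sorted arrival times in seconds.
#' @export
write_events <- function(timestamps, path) {
  if (grepl("\\.bin$", path)) {
    ns <- round(timestamps * 1e9)
    lo <- ns %% 4294967296
    hi <- ns %/% 4294967296
    to_int32 <- function(v) as.integer(v - 4294967296 * (v >= 2147483648))
    words <- integer(2L * length(ns))
    words[seq_along(ns) * 2L - 1L] <- to_int32(lo)
    words[seq_along(ns) * 2L] <- to_int32(hi)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(words, con, size = 4L, endian = "little")
  } else {
    writeLines(formatC(timestamps, format = "g", digits = 15), path)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (grepl("\\.bin$", path)) {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    words <- readBin(con, "integer", n = sz / 4, size = 4L,
                     endian = "little")
    if (length(words) %% 2L != 0L) {
      stop("malformed binary event file (odd word count): ", path)
    }
    u <- words + 4294967296 * (words < 0)
    lo <- u[seq_len(length(u) / 2) * 2 - 1]
    hi <- u[seq_len(length(u) / 2) * 2]
    ts <- (hi * 4294967296 + lo) * 1e-9
  } else {
    lines <- read_lines_checked(path)
    lines <- lines[nzchar(trimws(lines))]
    ts <- suppressWarnings(as.numeric(lines))
    if (anyNA(ts)) {
      stop("malformed event file ", path, ": non-numeric value at line ",
           which(is.na(ts))[1L])
    }
  }
  if (is.unsorted(ts)) stop("event file not sorted: ", path)
  ts
}

#' Count-file input and output
#'
#' CSV with a `bin_width_s` metadata header line followed by one count
#' per line.
#'
#' @param series a [photon_count_series()].
#' @param path file path.
#' @return `read_counts()` returns a [photon_count_series()].
#' @export
write_counts <- function(series, path) {
  stopifnot(inherits(series, "photon_count_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("bin_width_s,%.17g", series$bin_width), con)
  writeLines(formatC(series$counts, format = "d"), con)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "bin_width_s,")) {
    stop("malformed count file ", path,
         ": line 1 must be 'bin_width_s,<seconds>'")
  }
  bw <- as.numeric(sub("^bin_width_s,", "", lines[1L]))
  if (is.na(bw) || bw <= 0) {
    stop("malformed count file ", path, ": bad bin width at line 1")
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  counts <- suppressWarnings(as.numeric(body))
  if (anyNA(counts)) {
    stop("malformed count file ", path, ": non-numeric count at line ",
         which(is.na(counts))[1L] + 1L)
  }
  photon_count_series(counts, bin_width = bw)
}

#' Correlation-file input and output
#'
#' CSV with columns `tau_s,g2`, one row per scheduled lag.
#'
#' @param curve a [correlation_curve()].
#' @param path file path.
#' @return `read_correlation()` returns a [correlation_curve()].
#' @export
write_correlation <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(tau_s = curve$taus, g2 = curve$g2)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- read.csv(path)
  if (!all(c("tau_s", "g2") %in% names(df))) {
    stop("malformed correlation file ", path,
         ": expected columns tau_s,g2 at line 1")
  }
  if (nrow(df) > 1L && any(diff(df$tau_s) <= 0)) {
    bad <- which(diff(df$tau_s) <= 0)[1L]
    stop("malformed correlation file ", path,
         ": taus not strictly increasing at line ", bad + 2L)
  }
  correlation_curve(df$tau_s, df$g2)
}

#' BFI time-series input and output
#'
#' CSV with a `measurement_rate_hz` metadata line, then columns
#' `t_s,alpha_db,beta,mse,iterations,converged,gate_status`. Missing BFIs
#' (gate or fit failures) are written as empty fields, never interpolated.
#'
#' @param series a `bfi_time_series` (see [run_pipeline()]).
#' @param path file path.
#' @return `read_bfi()` returns a `bfi_time_series`.
#' @export
write_bfi <- function(series, path) {
  stopifnot(inherits(series, "bfi_time_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("measurement_rate_hz,%.17g",
                     attr(series, "measurement_rate")), con)
  write.csv(as.data.frame(series), con, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' @rdname write_bfi
#' @export
read_bfi <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "measurement_rate_hz,")) {
    stop("malformed BFI file ", path,
         ": line 1 must be 'measurement_rate_hz,<Hz>'")
  }
  rate <- as.numeric(sub("^measurement_rate_hz,", "", lines[1L]))
  df <- read.csv(text = lines[-1L], na.strings = "")
  need <- c("t_s", "alpha_db", "beta", "mse", "iterations", "converged",
            "gate_status")
  if (!all(need %in% names(df))) {
    stop("malformed BFI file ", path, ": missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$converged <- as.logical(df$converged)
  new_bfi_time_series(df, rate)
}

#' Fit-report input and output
#'
#' One CSV row per fitted window: start time, fitted parameters,
#' objective, iteration count, convergence flag and validity-gate status.
#' The same columns as the BFI series; provided under the fit-report name
#' for single-curve workflows.
#'
#' @param result a `fit_result` (from [nelder_mead_fit()]).
#' @param path file path.
#' @param t_s window start time recorded in the report, seconds.
#' @param gate_status validity-gate status string.
#' @export
write_fit_report <- function(result, path, t_s = 0, gate_status = "ok") {
  stopifnot(inherits(result, "fit_result"))
  df <- data.frame(
    t_s = t_s,
    alpha_db = if (is.null(result$flow)) NA_real_ else result$flow$alpha_db,
    beta = if (is.null(result$flow)) NA_real_ else result$flow$beta,
    mse = result$mse, iterations = result$iterations,
    converged = result$converged,
    gate_status = if (result$termination_reason == "invalid_input") {
      "invalid_input"
    } else {
      gate_status
    }
  )
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write a pipeline configuration to the flat key-value format
#'
#' Inverse of [load_config()] for the keys it covers.
#'
#' @param config a [pipeline_config()].
#' @param path destination path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  opt <- config$optics
  cor <- config$correlator
  keys <- list(
    mu_a = opt$mu_a, mu_s_prime = opt$mu_s_prime, rho_cm = opt$rho,
    wavelength_nm = opt$wavelength * 1e7, n_medium = opt$n_medium,
    n_outside = opt$n_outside,
    preset = cor$first_stage_delays + cor$n_stages * cor$stage_delays,
    base_bin_s = cor$base_bin,
    measurement_rate_hz = config$measurement_rate,
    smoothing_window = config$smoothing_window,
    convergence_threshold = config$fit$convergence_threshold,
    max_iterations = config$fit$max_iterations,
    gate_first_lo = config$gate$first_lo,
    gate_first_hi = config$gate$first_hi,
    gate_last_tol = config$gate$last_tol,
    beta_init = vapply(config$fit$initial_simplex, `[[`, numeric(1L),
                       "beta"),
    alpha_db_init = vapply(config$fit$initial_simplex, `[[`, numeric(1L),
                           "alpha_db")
  )
  if (!is.null(opt$reff_override)) keys$reff <- opt$reff_override
  yaml::write_yaml(keys, path)
  invisible(path)
}

#' Load a pipeline configuration from a flat key-value file
#'
#' Reads a flat YAML file (`key: value` per line) covering the optical,
#' correlator, fit and pipeline settings, and assembles a
#' [pipeline_config()]. Required keys: `mu_a`, `mu_s_prime`, `rho_cm`.
#' Optional keys (with their defaults): `wavelength_nm` (785), `n_medium`
#' (1.4), `n_outside` (1), `reff` (computed), `preset` (80),
#' `base_bin_s` (1e-6), `measurement_rate_hz` (1), `smoothing_window`
#' (0), `convergence_threshold` (1e-4), `max_iterations` (100),
#' `gate_first_lo` (1.05), `gate_first_hi` (2.0), `gate_last_tol` (0.1),
#' `beta_init` / `alpha_db_init` (three-element initial simplex).
#'
#' @param path config file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("mu_a", "mu_s_prime", "rho_cm")) {
    if (is.null(cfg[[key]])) {
      stop("config ", path, " is missing required key '", key, "'")
    }
  }
  get <- function(key, default) {
    if (is.null(cfg[[key]])) default else cfg[[key]]
  }
  optics <- optical_config(
    mu_a = cfg$mu_a, mu_s_prime = cfg$mu_s_prime, rho = cfg$rho_cm,
    wavelength_nm = get("wavelength_nm", 785),
    n_medium = get("n_medium", 1.4),
    n_outside = get("n_outside", 1.0),
    reff_override = cfg$reff
  )
  fit <- fit_config(
    initial_simplex = if (!is.null(cfg$beta_init)) {
      stopifnot(length(cfg$beta_init) == 3L,
                length(cfg$alpha_db_init) == 3L)
      lapply(1:3, function(i) {
        list(beta = cfg$beta_init[i], alpha_db = cfg$alpha_db_init[i])
      })
    } else {
      formals(fit_config)$initial_simplex |> eval()
    },
    convergence_threshold = get("convergence_threshold", 1e-4),
    max_iterations = get("max_iterations", 100)
  )
  pipeline_config(
    optics = optics,
    measurement_rate = get("measurement_rate_hz", 1),
    correlator = correlator_preset(get("preset", 80),
                                   base_bin = get("base_bin_s", 1e-6)),
    fit = fit,
    gate = list(first_lo = get("gate_first_lo", 1.05),
                first_hi = get("gate_first_hi", 2.0),
                last_tol = get("gate_last_tol", 0.1)),
    smoothing_window = get("smoothing_window", 0)
  )
}
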