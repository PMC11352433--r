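#' Optical and probe-geometry configuration
#'
#' Bundles the tissue optical properties and probe geometry that
#' parameterize the semi-infinite correlation-diffusion model. Lengths are
#' stored in cm; the wavelength is accepted in nm at the interface and
#' stored in cm.
#'
#' @param mu_a absorption coefficient, cm^-1.
#' @param mu_s_prime reduced scattering coefficient, cm^-1.
#' @param rho source-detector separation, cm.
#' @param wavelength_nm laser wavelength in vacuum, nm (default 785, the
#'   usual CW-DCS line).
#' @param n_medium tissue refractive index (default 1.4, a standard soft
#'   tissue value).
#' @param n_outside refractive index of the external medium (default 1.0).
#' @param reff_override optional fixed effective Fresnel reflection
#'   coefficient in `[0, 1)`. When `NULL` (default) the coefficient is
#'   computed from the relative refractive index with the standard
#'   diffuse-optics polynomial approximation (see [effective_reflection()]).
#'
#' @return An object of class `optical_config`.
#' @seealso [derive_constants()], [g2_model()]
#' @examples
#' opt <- optical_config(mu_a = 0.23, mu_s_prime = 17.2, rho = 1)
#' derive_constants(opt)
#' @export
optical_config <- function(mu_a, mu_s_prime, rho,
                           wavelength_nm = 785,
                           n_medium = 1.4,
                           n_outside = 1.0,
                           reff_override = NULL) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.numeric(rho), length(rho) == 1L,
            is.numeric(wavelength_nm), length(wavelength_nm) == 1L)
  if (!is.finite(mu_a) || mu_a <= 0) stop("mu_a must be positive (cm^-1)")
  if (!is.finite(mu_s_prime) || mu_s_prime <= 0) {
    stop("mu_s_prime must be positive (cm^-1)")
  }
  if (!is.finite(rho) || rho <= 0) stop("rho must be positive (cm)")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0) {
    stop("wavelength_nm must be positive")
  }
  if (!is.finite(n_medium) || n_medium < 1) stop("n_medium must be >= 1")
  if (!is.finite(n_outside) || n_outside <= 0) stop("n_outside must be > 0")
  if (!is.null(reff_override)) {
    if (!is.numeric(reff_override) || length(reff_override) != 1L ||
        !is.finite(reff_override) ||
        reff_override < 0 || reff_override >= 1) {
      stop("reff_override must lie in [0, 1)")
    }
  }
  structure(
    list(
      mu_a = mu_a,
      mu_s_prime = mu_s_prime,
      rho = rho,
      wavelength = wavelength_nm * 1e-7,  # nm -> cm
      n_medium = n_medium,
      n_outside = n_outside,
      reff_override = reff_override
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  mu_a        : %g cm^-1\n", x$mu_a))
  cat(sprintf("  mu_s'       : %g cm^-1\n", x$mu_s_prime))
  cat(sprintf("  rho         : %g cm\n", x$rho))
  cat(sprintf("  wavelength  : %g nm\n", x$wavelength * 1e7))
  cat(sprintf("  n_medium    : %g   n_outside : %g\n", x$n_medium, x$n_outside))
  cat(sprintf("  Reff        : %s\n",
              if (is.null(x$reff_override)) {
                sprintf("%.4f (from index mismatch)",
                        effective_reflection(x$n_medium / x$n_outside))
              } else {
                sprintf("%.4f (fixed)", x$reff_override)
              }))
  invisible(x)
}

#' Effective Fresnel reflection coefficient
#'
#' Polynomial approximation of the effective (angle-integrated) Fresnel
#' reflection coefficient at a refractive-index mismatch, as used for the
#' extrapolated-zero boundary of the diffusion equation:
#' \deqn{R_{eff} \approx -1.440\,n^{-2} + 0.710\,n^{-1} + 0.668 + 0.0636\,n}
#' with \eqn{n = n_{medium}/n_{outside}}.
#'
#' @param n_rel relative refractive index (inside / outside), >= 1 for the
#'   usual tissue-air case.
#' @return The effective reflection coefficient (dimensionless, < 1).
#' @export
effective_reflection <- function(n_rel) {
  stopifnot(is.numeric(n_rel), all(is.finite(n_rel)), all(n_rel > 0))
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

#' Derive the fixed constants of the semi-infinite model
#'
#' Precomputes the quantities that the semi-infinite solution of the
#' correlation diffusion equation needs, from the optical properties and
#' probe geometry:
#' \deqn{A = 3\mu_s'\mu_a, \quad \kappa_0 = 2\pi n/\lambda, \quad
#'       B = 6\mu_s'^2\kappa_0^2,}
#' \deqn{z_0 = 1/\mu_s', \quad r_1 = \sqrt{z_0^2 + \rho^2}, \quad
#'       z_b = \frac{2}{3\mu_s'}\frac{1+R_{eff}}{1-R_{eff}}, \quad
#'       r_b = \sqrt{(2 z_b + z_0)^2 + \rho^2},}
#' \deqn{H = e^{-r_1\sqrt{A}}/r_1 - e^{-r_b\sqrt{A}}/r_b.}
#' The wave number uses the in-medium wavelength (\eqn{\kappa_0 = 2\pi
#' n_{medium}/\lambda_{vac}}).
#'
#' @param optics an [optical_config()].
#' @return An object of class `model_constants` with fields `A` (cm^-2),
#'   `B` (cm^-4 s / (cm^2)), `r1`, `rb`, `zb` (cm), `H` (cm^-1), `k0`
#'   (cm^-1) and `reff`.
#' @examples
#' derive_constants(optical_config(mu_a = 0.23, mu_s_prime = 17.2, rho = 1))
#' @export
derive_constants <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  reff <- if (is.null(optics$reff_override)) {
    effective_reflection(optics$n_medium / optics$n_outside)
  } else {
    optics$reff_override
  }
  if (reff >= 1) stop("effective reflection coefficient must be < 1")
  mu_s <- optics$mu_s_prime
  A <- 3 * mu_s * optics$mu_a
  k0 <- 2 * pi * optics$n_medium / optics$wavelength
  B <- 6 * mu_s^2 * k0^2
  z0 <- 1 / mu_s
  r1 <- sqrt(z0^2 + optics$rho^2)
  zb <- (2 / (3 * mu_s)) * (1 + reff) / (1 - reff)
  rb <- sqrt((2 * zb + z0)^2 + optics$rho^2)
  H <- exp(-r1 * sqrt(A)) / r1 - exp(-rb * sqrt(A)) / rb
  out <- structure(
    list(A = A, B = B, r1 = r1, rb = rb, zb = zb, H = H, k0 = k0,
         reff = reff),
    class = "model_constants"
  )
  stopifnot(all(vapply(out, is.finite, logical(1L))), H > 0, rb > r1)
  out
}

#' @export
print.model_constants <- function(x, ...) {
  cat("<model_constants>\n")
  cat(sprintf("  A  = %.6g cm^-2    B  = %.6g cm^-4\n", x$A, x$B))
  cat(sprintf("  r1 = %.6g cm       rb = %.6g cm\n", x$r1, x$rb))
  cat(sprintf("  zb = %.6g cm       H  = %.6g cm^-1\n", x$zb, x$H))
  cat(sprintf("  k0 = %.6g cm^-1    Reff = %.4f\n", x$k0, x$reff))
  invisible(x)
}

#' Flow state: blood flow index and coherence factor
#'
#' The two free parameters of the DCS fit: `alpha_db`, the blood flow index
#' \eqn{\alpha D_B} in cm^2/s, and `beta`, the coherence factor (the
#' intercept \eqn{g_2(0) - 1}).
#'
#' @param alpha_db blood flow index, cm^2/s, >= 0.
#' @param beta coherence factor in (0, 1].
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(alpha_db, beta) {
  stopifnot(is.numeric(alpha_db), length(alpha_db) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (!is.finite(alpha_db) || alpha_db < 0) stop("alpha_db must be >= 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1) {
    stop("beta must lie in (0, 1]")
  }
  structure(list(alpha_db = alpha_db, beta = beta), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> alpha_db = %.4g cm^2/s, beta = %.4g\n",
              x$alpha_db, x$beta))
  invisible(x)
}
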