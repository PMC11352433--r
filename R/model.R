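#' Normalized field autocorrelation of the semi-infinite model
#'
#' Evaluates \eqn{g_1(\tau)}, the normalized electric-field autocorrelation
#' predicted by the semi-infinite solution of the correlation diffusion
#' equation:
#' \deqn{g_1(\tau) = \frac{1}{H}\left[\frac{e^{-r_1 K(\tau)}}{r_1}
#'       - \frac{e^{-r_b K(\tau)}}{r_b}\right], \qquad
#'       K(\tau) = \sqrt{A + B\,\alpha D_B\,\tau}.}
#' \eqn{g_1(0) = 1} exactly, and \eqn{g_1} decays monotonically in both
#' \eqn{\tau} and \eqn{\alpha D_B}. Values that round below zero through
#' floating cancellation at very large \eqn{\tau} are clipped to 0.
#'
#' @param constants a [derive_constants()] result.
#' @param alpha_db blood flow index, cm^2/s.
#' @param taus lag times in seconds, nonnegative and strictly increasing.
#' @return Numeric vector of \eqn{g_1} values, one per lag.
#' @export
g1_model <- function(constants, alpha_db, taus) {
  stopifnot(inherits(constants, "model_constants"),
            is.numeric(taus), length(taus) >= 1L, all(is.finite(taus)))
  if (any(taus < 0)) stop("taus must be nonnegative")
  if (length(taus) > 1L && any(diff(taus) <= 0)) {
    stop("taus must be strictly increasing")
  }
  if (!is.finite(alpha_db) || alpha_db < 0) stop("alpha_db must be >= 0")
  K <- sqrt(constants$A + constants$B * alpha_db * taus)
  g1 <- (exp(-constants$r1 * K) / constants$r1 -
           exp(-constants$rb * K) / constants$rb) / constants$H
  pmax(g1, 0)
}

#' Normalized intensity autocorrelation of the semi-infinite model
#'
#' The Siegert relation applied to [g1_model()]:
#' \deqn{g_2(\tau) = 1 + \beta\, g_1(\tau)^2,}
#' so \eqn{g_2(0) = 1 + \beta} and \eqn{g_2 \to 1} as the field decorrelates.
#'
#' @inheritParams g1_model
#' @param flow a [flow_state()] (or a list with `alpha_db` and `beta`).
#' @return A [correlation_curve()] with the model lags and g2 values.
#' @examples
#' con <- derive_constants(optical_config(0.1, 10, 1))
#' g2_model(con, flow_state(1e-8, 0.5), c(1e-6, 1e-5, 1e-4, 1e-3))
#' @export
g2_model <- function(constants, flow, taus) {
  stopifnot(!is.null(flow$alpha_db), !is.null(flow$beta))
  g1 <- g1_model(constants, flow$alpha_db, taus)
  correlation_curve(taus = taus, g2 = 1 + flow$beta * g1^2)
}
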