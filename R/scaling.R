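# The linear scaling law D(theta) = D_B [1 + (D_C/D_B - 1) theta]:
# prediction, density-weighted generalization, inversion and fitting.

#' Scaling law between confinement and diffusivity
#'
#' Holds the two anchors of the linear law -- the bulk self-diffusion
#' coefficient D_B and the totally confined one D_C -- and optionally
#' the bulk/confined water densities used by the density-weighted
#' variant.
#'
#' @param D_B bulk diffusivity (m^2/s); default 2.60e-9 at 300 K
#' @param D_C fully confined diffusivity (m^2/s), in [0, D_B]
#' @param rho_B,rho_C optional bulk and confined water densities
#'   (kg/m^3)
#' @return list of class `scaling_law`
#' @export
#' @examples
#' law <- scaling_law(D_C = 0.39e-9)
#' predict_D(0.5, law)
scaling_law <- function(D_B = 2.60e-9, D_C = 0, rho_B = NULL, rho_C = NULL) {
  if (D_B <= 0) stop("D_B must be positive")
  if (D_C < 0 || D_C > D_B) stop("D_C must lie in [0, D_B]")
  structure(list(D_B = D_B, D_C = D_C, rho_B = rho_B, rho_C = rho_C),
            class = "scaling_law")
}

#' Predict the diffusivity at a given confinement level
#'
#' D(theta) = D_B [1 + (D_C/D_B - 1) theta]; theta = 0 returns the
#' bulk value, theta = 1 the fully confined one, and with D_C = 0 the
#' law reduces to D_B (1 - theta).
#'
#' @param theta scaling parameter(s) in [0, 1]
#' @param law `scaling_law`
#' @return diffusivity (m^2/s)
#' @export
predict_D <- function(theta, law = scaling_law()) {
  if (any(theta < -1e-12 | theta > 1 + 1e-12))
    stop("theta must lie in [0, 1]")
  theta <- pmin(1, pmax(0, theta))
  law$D_B * (1 + (law$D_C / law$D_B - 1) * theta)
}

#' Density-weighted diffusivity prediction
#'
#' Mixing-rule variant: the confined and bulk molecule counts are
#' weighted by their densities, w = rho_C theta / (rho_C theta +
#' rho_B (1 - theta)), and D = D_B [1 + (D_C/D_B - 1) w]. Coincides
#' with [predict_D()] when rho_C = rho_B.
#'
#' @param theta scaling parameter(s) in [0, 1]
#' @param law `scaling_law` with densities set
#' @return diffusivity (m^2/s)
#' @export
predict_D_density <- function(theta, law) {
  if (is.null(law$rho_B) || is.null(law$rho_C) ||
      law$rho_B <= 0 || law$rho_C <= 0)
    stop("law must carry positive rho_B and rho_C")
  if (any(theta < -1e-12 | theta > 1 + 1e-12))
    stop("theta must lie in [0, 1]")
  theta <- pmin(1, pmax(0, theta))
  w <- law$rho_C * theta / (law$rho_C * theta + law$rho_B * (1 - theta))
  w[theta == 1] <- 1   # guard 0/0 when both densities weight nothing
  law$D_B * (1 + (law$D_C / law$D_B - 1) * w)
}

#' Fit the scaling law to (theta, D) observations
#'
#' Least squares for the line D = D_B + (D_C - D_B) theta, optionally
#' weighted by inverse variance from the D error bars. D_C is
#' recovered from the fitted slope and clamped at 0 when the
#' unconstrained value is negative (re-fitting the intercept with the
#' slope pinned at -D_B); `constrain_DC_zero` forces that one-
#' parameter fit.
#'
#' @param theta,D observed scaling parameters and diffusivities
#' @param sigma_D optional uncertainties on D (same units)
#' @param constrain_DC_zero fit D_B only, with D_C fixed at 0
#' @return list with `law` (`scaling_law`), `r_squared`, and the raw
#'   `fit` object
#' @export
fit_law <- function(theta, D, sigma_D = NULL, constrain_DC_zero = FALSE) {
  if (length(theta) < 2 || length(unique(theta)) < 2)
    stop("need at least 2 distinct theta values")
  if (length(theta) != length(D)) stop("theta and D lengths differ")
  w <- if (is.null(sigma_D)) NULL else 1 / sigma_D^2
  dat <- data.frame(theta = theta, D = D)
  if (constrain_DC_zero) {
    # D = D_B (1 - theta): regression through the origin on (1 - theta)
    fit <- stats::lm(D ~ 0 + I(1 - theta), data = dat, weights = w)
    D_B <- unname(stats::coef(fit)[1])
    D_C <- 0
  } else {
    fit <- stats::lm(D ~ theta, data = dat, weights = w)
    D_B <- unname(stats::coef(fit)[1])
    D_C <- unname(D_B + stats::coef(fit)[2])
    if (D_C < 0) {
      fit <- stats::lm(D ~ 0 + I(1 - theta), data = dat, weights = w)
      D_B <- unname(stats::coef(fit)[1])
      D_C <- 0
    }
  }
  pred <- D_B + (D_C - D_B) * theta
  ss_res <- sum((D - pred)^2)
  ss_tot <- sum((D - mean(D))^2)
  list(law = scaling_law(D_B = D_B, D_C = D_C),
       r_squared = 1 - ss_res / ss_tot,
       fit = fit)
}

#' Invert the scaling law
#'
#' theta = (D_B - D) / (D_B - D_C); exact algebraic inverse of
#' [predict_D()].
#'
#' @param D diffusivity (m^2/s), within [D_C, D_B]
#' @param law `scaling_law` with D_C < D_B
#' @return theta in [0, 1]
#' @export
invert_theta <- function(D, law = scaling_law()) {
  if (law$D_C >= law$D_B) stop("inversion needs D_C < D_B")
  if (any(D < law$D_C - 1e-15 | D > law$D_B + 1e-15))
    stop("D must lie within [D_C, D_B]")
  (law$D_B - D) / (law$D_B - law$D_C)
}

#' Read (theta, D, sigma_D) points from a text file
#'
#' Three whitespace-delimited columns; the third (uncertainty) is
#' optional.
#'
#' @param path file path
#' @return data.frame with columns theta, D and optionally sigma_D
#' @export
read_points <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("theta", "D") %in% names(tab)))
    stop("points file needs columns 'theta' and 'D'")
  tab
}
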