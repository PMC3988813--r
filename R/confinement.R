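# From delta and geometry to the scaling parameter theta.
#
# theta is the fraction of the accessible water volume lying within
# the confinement length delta of solid surfaces. The volume of
# influence is S_tot * delta to first order, with exact shell formulas
# for curved surfaces; overlapping volumes of influence are corrected
# by the classical continuum-percolation result 1 - exp(-theta).

#' Specify one confining surface
#'
#' @param S_tot total solvent-accessible area of the surface (nm^2)
#' @param delta characteristic confinement length (nm)
#' @param shape one of "plane", "sphere", "cylinder_inner",
#'   "cylinder_outer"
#' @param R radius of curvature (nm); required for curved shapes
#' @param L cylinder length (nm); required for cylinders
#' @param count number of identical copies of this surface
#' @return list of class `surface_spec`
#' @export
surface_spec <- function(S_tot, delta, shape = c("plane", "sphere",
                                                 "cylinder_inner",
                                                 "cylinder_outer"),
                         R = NULL, L = NULL, count = 1) {
  shape <- match.arg(shape)
  if (S_tot <= 0) stop("S_tot must be positive")
  if (delta < 0) stop("delta must be >= 0")
  if (count < 1) stop("count must be >= 1")
  if (shape != "plane" && (is.null(R) || R <= 0))
    stop("curved shapes need a positive radius R")
  if (shape %in% c("cylinder_inner", "cylinder_outer") &&
      (is.null(L) || L <= 0))
    stop("cylinders need a positive length L")
  structure(list(S_tot = S_tot, delta = delta, shape = shape,
                 R = R, L = L, count = count),
            class = "surface_spec")
}

#' Total volume of influence of a set of surfaces
#'
#' Sums, over all surfaces, the volume of the water shell of thickness
#' delta adjacent to each: S * delta for planes, exact spherical and
#' cylindrical shell formulas for curved walls (delta capped at the
#' pore radius for inner cylinder surfaces, where the shell saturates
#' to the whole pore).
#'
#' @param specs a `surface_spec` or list of them
#' @return volume of influence (nm^3)
#' @export
#' @examples
#' volume_of_influence(surface_spec(10, 0.3))  # 3 nm^3
volume_of_influence <- function(specs) {
  if (inherits(specs, "surface_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("specs must be non-empty")
  sum(vapply(specs, function(sp) {
    v <- switch(sp$shape,
      plane = sp$S_tot * sp$delta,
      sphere = 4 * pi / 3 * ((sp$R + sp$delta)^3 - sp$R^3),
      cylinder_inner = {
        d <- min(sp$delta, sp$R)
        pi * sp$L * (sp$R^2 - (sp$R - d)^2)
      },
      cylinder_outer = pi * sp$L * ((sp$R + sp$delta)^2 - sp$R^2))
    v * sp$count
  }, numeric(1)))
}

#' Volume accessible to water from a molecule count
#'
#' V_w = N_sol / rho_n, with rho_n the water number density. The
#' companion `particle_volume` returns the solid volume as the box
#' complement V_p = V_box - V_w.
#'
#' @param n_sol number of water molecules in the box
#' @param rho_n water number density (nm^-3); about 33.4 at ambient
#'   conditions
#' @return water volume (nm^3)
#' @export
water_volume <- function(n_sol, rho_n) {
  if (rho_n <= 0) stop("rho_n must be positive")
  if (n_sol < 0) stop("n_sol must be >= 0")
  n_sol / rho_n
}

#' @rdname water_volume
#' @param V_box computational box volume (nm^3)
#' @param V_w water volume (nm^3)
#' @export
particle_volume <- function(V_box, V_w) {
  if (V_w > V_box) stop("water volume exceeds the box volume")
  V_box - V_w
}

#' Apparent scaling parameter
#'
#' Ratio V_in / V_w between the volume of influence and the volume
#' accessible to water; 0 is the bulk limit, 1 total confinement. Not
#' clamped -- overlapping volumes of influence can push the apparent
#' value above 1 (see [cpt_correct()]).
#'
#' @param V_in volume of influence (nm^3)
#' @param V_w water volume (nm^3), > 0
#' @return apparent theta (>= 0)
#' @export
theta_apparent <- function(V_in, V_w) {
  if (V_w <= 0) stop("V_w must be positive")
  if (V_in < 0) stop("V_in must be >= 0")
  V_in / V_w
}

#' Continuum-percolation overlap correction
#'
#' For randomly placed overlapping volumes the effective covered
#' fraction is 1 - exp(-theta_apparent). The correction applies only
#' when volumes of influence can overlap (several particles in the
#' box); otherwise the apparent value is kept, clamped to [0, 1].
#'
#' @param theta_app apparent theta (>= 0)
#' @param overlap logical: can the volumes of influence overlap?
#' @return effective theta in [0, 1]
#' @export
cpt_correct <- function(theta_app, overlap) {
  if (any(theta_app < 0)) stop("theta_app must be >= 0")
  if (overlap) 1 - exp(-theta_app) else pmin(theta_app, 1)
}

#' Full theta pipeline for a scene of surfaces
#'
#' Combines the volume of influence of all surfaces with the water
#' volume, applies the percolation correction (automatically enabled
#' when more than one surface copy is present), and clamps to [0, 1].
#' An uncertainty on rho_n propagates to a theta error bar.
#'
#' @param specs list of `surface_spec`
#' @param V_w water volume (nm^3); alternatively give `n_sol` and
#'   `rho_n`
#' @param n_sol,rho_n molecule count and number density (nm^-3)
#' @param rho_n_sd optional standard deviation of rho_n
#' @param overlap force the percolation correction on/off; default
#'   NULL auto-enables it when the total surface count exceeds 1
#' @return list of class `theta_result`: `V_in`, `V_w`,
#'   `theta_apparent`, `theta`, `theta_sd`
#' @export
compute_theta <- function(specs, V_w = NULL, n_sol = NULL, rho_n = NULL,
                          rho_n_sd = 0, overlap = NULL) {
  if (inherits(specs, "surface_spec")) specs <- list(specs)
  if (is.null(V_w)) {
    if (is.null(n_sol) || is.null(rho_n))
      stop("give either V_w or both n_sol and rho_n")
    V_w <- water_volume(n_sol, rho_n)
  }
  V_in <- if (length(specs) > 0) volume_of_influence(specs) else 0
  if (is.null(overlap))
    overlap <- sum(vapply(specs, `[[`, numeric(1), "count")) > 1
  th_app <- theta_apparent(V_in, V_w)
  th <- min(1, max(0, cpt_correct(th_app, overlap)))
  th_sd <- 0
  if (rho_n_sd > 0 && !is.null(rho_n)) {
    # V_w = n/rho so dtheta/drho = theta_app / rho; push through the
    # correction by finite difference
    dapp <- th_app * rho_n_sd / rho_n
    th_sd <- abs(cpt_correct(th_app + dapp, overlap) -
                 cpt_correct(max(0, th_app - dapp), overlap)) / 2
  }
  structure(list(V_in = V_in, V_w = V_w, theta_apparent = th_app,
                 theta = th, theta_sd = th_sd),
            class = "theta_result")
}

#' @export
print.theta_result <- function(x, ...) {
  cat(sprintf("theta_result: V_in = %.4g nm^3, V_w = %.4g nm^3, ",
              x$V_in, x$V_w))
  cat(sprintf("theta_apparent = %.4g, theta = %.4g", x$theta_apparent,
              x$theta))
  if (x$theta_sd > 0) cat(sprintf(" +/- %.2g", x$theta_sd))
  cat("\n")
  invisible(x)
}
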