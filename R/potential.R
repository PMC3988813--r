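# Effective wall potential along SAS normals and the characteristic
# confinement length delta.
#
# A water molecule approaching a solid wall feels (i) a 12-6
# Lennard-Jones potential summed over the nearest wall atoms and (ii)
# the thermally averaged interaction between its dipole and the
# electric field of the partial surface charges (a Langevin
# orientation average). The depth and width of the resulting well,
# measured against the thermal level alpha * k_B * T, define a
# per-atom confinement length delta_i; the SAS-weighted surface
# average gives the structure's characteristic length delta.

#' Configuration for the delta pipeline
#'
#' Collects every numerical choice of the confinement-length
#' computation so a run can be reproduced from its resolved
#' configuration alone.
#'
#' @param cutoff neighbour cutoff radius (nm); also the outer end of
#'   the profile grid
#' @param grid_n number of uniform grid points along the normal
#' @param n_min inner end of the profile grid (nm)
#' @param alpha thermal-level fraction in U_eff + alpha k_B T = 0;
#'   1/4 is exact for planar walls (escape along half of one degree of
#'   freedom)
#' @param probe_radius SAS probe radius (nm)
#' @param n_points SAS test points per atom
#' @param temperature temperature (K)
#' @param eps_r relative-permittivity model, a function of distance
#'   (nm); see [eps_r_sigmoidal()]
#' @param precombined if TRUE the table's LJ parameters already
#'   incorporate the combination rule with water oxygen; if FALSE
#'   (default) Lorentz-Berthelot combination with the water model's
#'   oxygen parameters is applied
#' @param charges if FALSE partial charges are ignored (pure LJ wall)
#' @param surface_threshold minimum S_loc (nm^2) for an atom to enter
#'   the surface average
#' @return list of class `delta_config`
#' @export
delta_config <- function(cutoff = 1.0, grid_n = 2000, n_min = 0.05,
                         alpha = 0.25, probe_radius = 0.14, n_points = 960,
                         temperature = 300, eps_r = eps_r_sigmoidal(),
                         precombined = FALSE, charges = TRUE,
                         surface_threshold = 0) {
  stopifnot(cutoff > n_min, n_min > 0, grid_n >= 10, alpha > 0,
            temperature > 0)
  structure(list(cutoff = cutoff, grid_n = grid_n, n_min = n_min,
                 alpha = alpha, probe_radius = probe_radius,
                 n_points = n_points, temperature = temperature,
                 eps_r = eps_r, precombined = precombined,
                 charges = charges, surface_threshold = surface_threshold),
            class = "delta_config")
}

#' Relative permittivity models
#'
#' `eps_r_constant` returns a constant-permittivity model;
#' `eps_r_sigmoidal` a distance-dependent one rising smoothly from 1
#' at contact to the bulk value far from the surface, reflecting the
#' reduced dielectric screening of interfacial water.
#'
#' @param value constant relative permittivity (>= 1)
#' @param eps_bulk far-field permittivity (default 78, bulk water)
#' @param midpoint distance (nm) at which half the rise is reached
#' @param width sigmoid width (nm)
#' @return function mapping distance (nm) to relative permittivity
#' @export
eps_r_constant <- function(value = 1) {
  if (value < 1) stop("relative permittivity must be >= 1")
  function(r) rep_len(value, length(r))
}

#' @rdname eps_r_constant
#' @export
eps_r_sigmoidal <- function(eps_bulk = 78, midpoint = 0.35, width = 0.07) {
  function(r) 1 + (eps_bulk - 1) / (1 + exp(-(r - midpoint) / width))
}

# neighbour set of atom i within the cutoff, including i itself;
# returns positions relative to atom i (minimum image when periodic)
neighbour_set <- function(i, s, cutoff) {
  pos <- atom_positions(s)
  d <- sweep(pos, 2, pos[match(i, s$atoms$id), ])
  if (!is.null(s$box)) d <- mic(d, s$box)
  keep <- rowSums(d^2) <= cutoff^2
  list(rel = d[keep, , drop = FALSE],
       epsilon = s$atoms$epsilon[keep],
       sigma = s$atoms$sigma[keep],
       charge = s$atoms$charge[keep])
}

combine_lj <- function(nb, water, precombined) {
  if (precombined) return(nb)
  nb$sigma <- (nb$sigma + water$lj_sigma_O) / 2
  nb$epsilon <- sqrt(nb$epsilon * water$lj_epsilon_O)
  nb
}

# distances (nm) from each grid point along the normal to each
# neighbour; rows = grid points, cols = neighbours; floored at 1e-4 nm
grid_neighbour_dist <- function(grid, normal, rel) {
  px <- outer(grid, rep(1, nrow(rel))) * normal[1] - rep(rel[, 1], each = length(grid))
  py <- outer(grid, rep(1, nrow(rel))) * normal[2] - rep(rel[, 2], each = length(grid))
  pz <- outer(grid, rep(1, nrow(rel))) * normal[3] - rep(rel[, 3], each = length(grid))
  r <- sqrt(px^2 + py^2 + pz^2)
  if (any(r < 1e-4)) {
    message("grid point within 1e-4 nm of an atom centre; distance floored")
    r[r < 1e-4] <- 1e-4
  }
  r
}

#' Lennard-Jones wall potential along an atom's normal
#'
#' Sums the 12-6 potential of all neighbours within the cutoff
#' (including atom i itself) at each point of a grid along the
#' outward normal: U_vdw(n) = sum_k 4 eps_k [(sigma_k/r_k)^12 -
#' (sigma_k/r_k)^6], with parameters Lorentz-Berthelot-combined
#' against the water oxygen unless the table stores pre-combined
#' values.
#'
#' @param i atom id
#' @param s `param_structure`
#' @param water `water_model`
#' @param normal unit 3-vector (outward)
#' @param grid distances along the normal (nm)
#' @param config `delta_config`
#' @return vector of energies (kJ/mol), one per grid point
#' @export
lj_profile <- function(i, s, water, normal, grid, config = delta_config()) {
  nb <- combine_lj(neighbour_set(i, s, config$cutoff), water,
                   config$precombined)
  r <- grid_neighbour_dist(grid, normal, nb$rel)
  sr6 <- sweep(1 / r, 2, nb$sigma, `*`)^6
  rowSums(sweep(sr6^2 - sr6, 2, 4 * nb$epsilon, `*`))
}

# vectorised field magnitude over grid points (V/m)
field_on_grid <- function(grid, normal, rel, charge, eps_r) {
  nz <- which(charge != 0)
  if (length(nz) == 0) return(numeric(length(grid)))
  rel <- rel[nz, , drop = FALSE]
  charge <- charge[nz]
  Ex <- Ey <- Ez <- numeric(length(grid))
  for (k in seq_along(charge)) {
    dx <- grid * normal[1] - rel[k, 1]
    dy <- grid * normal[2] - rel[k, 2]
    dz <- grid * normal[3] - rel[k, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    r[r < 1e-4] <- 1e-4
    pref <- charge[k] * .e_charge /
      (4 * pi * .eps0 * eps_r(r) * (r * 1e-9)^2) / r
    Ex <- Ex + pref * dx
    Ey <- Ey + pref * dy
    Ez <- Ez + pref * dz
  }
  sqrt(Ex^2 + Ey^2 + Ez^2)
}

#' Electric field strength of wall partial charges at a point
#'
#' Vector sum of the Coulomb fields q_k / (4 pi eps0 eps_r r^2) over a
#' set of charged neighbours, with a distance-dependent relative
#' permittivity; the magnitude (V/m) is returned.
#'
#' @param point 3-vector (nm)
#' @param neighbours data.frame or list with fields `x`, `y`, `z` (nm)
#'   and `charge` (e)
#' @param eps_r_model function distance (nm) -> relative permittivity
#' @return field magnitude (V/m)
#' @export
coulomb_field <- function(point, neighbours, eps_r_model = eps_r_constant(1)) {
  rel <- cbind(neighbours$x - point[1], neighbours$y - point[2],
               neighbours$z - point[3])
  # reuse the grid machinery with a single grid point at the origin;
  # only the magnitude is returned, so the sign convention of rel is
  # immaterial
  field_on_grid(0, c(0, 0, 1), rel, neighbours$charge, eps_r_model)
}

#' Langevin function
#'
#' Gamma(x) = coth(x) - 1/x, the mean cosine of a dipole's angle to a
#' field of reduced strength x at thermal equilibrium. A series
#' expansion x/3 - x^3/45 is used below 1e-3 for numerical stability.
#'
#' @param x nonnegative reduced field strength(s)
#' @return value(s) in [0, 1)
#' @export
langevin <- function(x) {
  if (any(x < 0)) stop("langevin is defined here for x >= 0")
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Thermally averaged dipole-field energy
#'
#' Boltzmann average of -mu . E over dipole orientations:
#' U_c = -E mu Gamma(mu E / (k_B T)), converted to kJ/mol.
#'
#' @param E field strength(s) (V/m)
#' @param water `water_model` (supplies the dipole moment)
#' @param T temperature (K)
#' @return energy (kJ/mol), zero or negative
#' @export
dipole_energy <- function(E, water, T) {
  if (T <= 0) stop("temperature must be positive")
  mu <- water$dipole_moment
  beta <- mu * E / (.k_B * T)
  -E * mu * langevin(beta) * .N_A / 1e3
}

new_potential_profile <- function(n_grid, U_vdw, U_c, fun = NULL) {
  U_eff <- U_vdw + U_c
  mins <- min(U_eff)
  structure(list(n_grid = n_grid, U_vdw = U_vdw, U_c = U_c, U_eff = U_eff,
                 well_depth = if (mins < 0) -mins else 0,
                 well_position = n_grid[which.min(U_eff)]),
            fun = fun, class = "potential_profile")
}

#' Construct a potential profile from sampled energies
#'
#' Builds a `potential_profile` from externally supplied energies
#' (for example an analytic well used to validate the root finder).
#'
#' @param n_grid ordered distances (nm)
#' @param U_eff effective potential (kJ/mol) at the grid
#' @param U_vdw,U_c optional split into van der Waals and Coulomb
#'   parts (default: all vdw)
#' @param fun optional exact evaluator n -> U_eff used for root
#'   refinement instead of spline interpolation
#' @return `potential_profile`
#' @export
potential_profile <- function(n_grid, U_eff, U_vdw = U_eff,
                              U_c = U_eff - U_vdw, fun = NULL) {
  stopifnot(length(n_grid) == length(U_eff), !is.unsorted(n_grid))
  new_potential_profile(n_grid, U_vdw, U_c, fun)
}

#' Effective wall potential profile for a surface atom
#'
#' Evaluates U_eff = U_vdw + U_c on a uniform grid along the atom's
#' outward SAS normal. The Coulomb part is the Langevin-averaged
#' dipole energy in the field of the charged neighbours and vanishes
#' when charges are zero or disabled.
#'
#' @param i atom id (must have S_loc > 0)
#' @param s `param_structure`
#' @param sas `sas_result` computed on `s`
#' @param water `water_model`
#' @param config `delta_config`
#' @return `potential_profile`
#' @export
effective_profile <- function(i, s, sas, water = water_model(),
                              config = delta_config()) {
  key <- as.character(i)
  if (is.na(sas$S_loc[key]) || sas$S_loc[key] <= 0 ||
      anyNA(sas$normal[key, ]))
    stop("atom ", i, " has no accessible surface / normal; ",
         "select atoms with surface_atoms()")
  normal <- sas$normal[key, ]
  grid <- seq(config$n_min, config$cutoff, length.out = config$grid_n)
  nb <- neighbour_set(i, s, config$cutoff)
  nbc <- combine_lj(nb, water, config$precombined)
  eval_profile <- function(n) {
    r <- grid_neighbour_dist(n, normal, nbc$rel)
    sr6 <- sweep(1 / r, 2, nbc$sigma, `*`)^6
    U_vdw <- rowSums(sweep(sr6^2 - sr6, 2, 4 * nbc$epsilon, `*`))
    U_c <- if (config$charges && any(nb$charge != 0)) {
      E <- field_on_grid(n, normal, nb$rel, nb$charge, config$eps_r)
      dipole_energy(E, water, config$temperature)
    } else numeric(length(n))
    list(U_vdw = U_vdw, U_c = U_c)
  }
  parts <- eval_profile(grid)
  new_potential_profile(grid, parts$U_vdw, parts$U_c,
                        fun = function(n) {
                          p <- eval_profile(n)
                          p$U_vdw + p$U_c
                        })
}

#' Local confinement length from a potential profile
#'
#' delta_i = n_2 - n_1, where n_1 and n_2 are the innermost and
#' outermost zeros of U_eff(n) + alpha k_B T = 0 that bracket the
#' global minimum of the well; water inside [n_1, n_2] lacks the
#' thermal energy to escape the well. When the thermal line does not
#' intersect the profile (well depth below alpha k_B T) delta_i = 0.
#' Roots are refined to 1e-6 nm by bisection on the exact evaluator
#' when available, else on a cubic spline through the grid.
#'
#' @param p `potential_profile`
#' @param T temperature (K)
#' @param alpha thermal-level fraction (default 1/4)
#' @return delta_i (nm)
#' @export
local_delta <- function(p, T = 300, alpha = 0.25) {
  if (any(!is.finite(p$U_eff))) stop("profile contains non-finite values")
  if (T <= 0 || alpha <= 0) stop("T and alpha must be positive")
  level <- -alpha * kBT_kJmol(T)
  if (-p$well_depth > level) return(0)
  f <- attr(p, "fun")
  if (is.null(f)) f <- stats::splinefun(p$n_grid, p$U_eff)
  h <- function(n) f(n) - level
  hv <- p$U_eff - level
  imin <- which.min(p$U_eff)
  sgn <- sign(hv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  lower <- cross[cross < imin]
  upper <- cross[cross >= imin]
  refine <- function(k) stats::uniroot(h, lower = p$n_grid[k],
                                       upper = p$n_grid[k + 1],
                                       tol = 1e-9)$root
  n1 <- if (length(lower) > 0) refine(min(lower)) else p$n_grid[1]
  n2 <- if (length(upper) > 0) refine(max(upper)) else p$n_grid[length(p$n_grid)]
  max(0, n2 - n1)
}

#' SAS-weighted mean confinement length of a structure
#'
#' Computes delta_i for every atom with accessible surface and
#' averages with S_loc weights: delta = sum_i delta_i S_loc,i / S_tot.
#' Buried atoms carry zero weight. Also returns the SAS-weighted mean
#' well depth epsilon (used as the energy of confinement by the
#' supercooled-water route) and the maximum well depth.
#'
#' @param s `param_structure`
#' @param sas `sas_result` on `s` (computed if missing)
#' @param water `water_model`
#' @param config `delta_config`
#' @return object of class `confinement_result` with fields `delta_i`
#'   (named by atom id), `delta_mean` (nm), `epsilon_mean`,
#'   `epsilon_max` (kJ/mol), `alpha`, `well_depth_i`
#' @export
mean_delta <- function(s, sas = NULL, water = water_model(),
                       config = delta_config()) {
  if (is.null(sas))
    sas <- compute_sas(s, probe_radius = config$probe_radius,
                       n_points = config$n_points)
  if (sas$S_tot <= 0) stop("structure has no accessible surface")
  ids <- surface_atoms(sas, config$surface_threshold)
  delta_i <- well_i <- stats::setNames(numeric(length(ids)), ids)
  for (i in ids) {
    p <- effective_profile(i, s, sas, water, config)
    key <- as.character(i)
    delta_i[key] <- local_delta(p, config$temperature, config$alpha)
    well_i[key] <- p$well_depth
  }
  w <- sas$S_loc[as.character(ids)]
  structure(list(delta_i = delta_i,
                 delta_mean = sum(delta_i * w) / sas$S_tot,
                 epsilon_mean = sum(well_i * w) / sas$S_tot,
                 epsilon_max = if (length(well_i)) max(well_i) else 0,
                 alpha = config$alpha,
                 well_depth_i = well_i),
            class = "confinement_result")
}

#' @export
print.confinement_result <- function(x, ...) {
  cat("confinement_result: delta =", signif(x$delta_mean, 4), "nm;",
      "epsilon_mean =", signif(x$epsilon_mean, 4), "kJ/mol;",
      "alpha =", x$alpha, "\n")
  invisible(x)
}

#' Export a potential profile as two-column text
#'
#' @param p `potential_profile`
#' @param path output file
#' @return path, invisibly
#' @export
write_profile <- function(p, path) {
  utils::write.table(data.frame(n = p$n_grid, U_eff = p$U_eff), path,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
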