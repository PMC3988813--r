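# End-to-end pipelines behind the command-line front end.
#
# Each cmd_* function composes the module operations, resolves every
# default into the returned `config` element (so identical resolved
# configs reproduce identical outputs), and optionally writes its
# report to text files.

resolve_config <- function(config) {
  cfg <- unclass(config)
  cfg$eps_r <- NULL   # functions are not serialisable; record the family
  cfg$eps_r_model <- if (identical(config$eps_r(1e3), 1))
    "constant" else "sigmoidal"
  cfg
}

#' Characteristic-length pipeline
#'
#' SAS + potential chain on a structure: computes per-atom delta_i and
#' the SAS-weighted mean delta and well depth.
#'
#' @param s `param_structure`, or path to a structure text table
#' @param water `water_model`
#' @param config `delta_config`
#' @param output optional file prefix; writes `<output>_delta.txt`
#'   (per-atom table) and `<output>_report.txt`
#' @return list: `delta`, `epsilon_mean`, `epsilon_max`, `per_atom`
#'   (data.frame id, S_loc, delta, well_depth), `config`
#' @export
cmd_delta <- function(s, water = water_model(), config = delta_config(),
                      output = NULL) {
  if (is.character(s)) s <- read_structure_table(s)
  sas <- compute_sas(s, probe_radius = config$probe_radius,
                     n_points = config$n_points)
  res <- mean_delta(s, sas, water, config)
  ids <- as.integer(names(res$delta_i))
  per_atom <- data.frame(id = ids,
                         S_loc = unname(sas$S_loc[names(res$delta_i)]),
                         delta = unname(res$delta_i),
                         well_depth = unname(res$well_depth_i))
  report <- list(delta = res$delta_mean, epsilon_mean = res$epsilon_mean,
                 epsilon_max = res$epsilon_max, per_atom = per_atom,
                 config = resolve_config(config))
  if (!is.null(output)) {
    utils::write.table(per_atom, paste0(output, "_delta.txt"),
                       quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("delta_nm %.8g", report$delta),
                 sprintf("epsilon_mean_kJmol %.8g", report$epsilon_mean),
                 sprintf("epsilon_max_kJmol %.8g", report$epsilon_max)),
               paste0(output, "_report.txt"))
  }
  report
}

parse_surface_specs <- function(lst) {
  lapply(lst, function(e)
    surface_spec(S_tot = e$S_tot, delta = e$delta,
                 shape = if (is.null(e$shape)) "plane" else e$shape,
                 R = e$R, L = e$L,
                 count = if (is.null(e$count)) 1 else e$count))
}

#' Confinement-to-diffusivity prediction pipeline
#'
#' Reads a scene description (a YAML file or equivalent list with
#' `surfaces`, `water`, and optional `law` blocks), computes V_in,
#' V_w and theta, and predicts D.
#'
#' @param scene path to a YAML scene file or a list
#' @return list: `V_in`, `V_w`, `theta_apparent`, `theta`,
#'   `theta_sd`, `D`, `law`
#' @export
cmd_predict <- function(scene) {
  if (is.character(scene)) scene <- yaml::read_yaml(scene)
  specs <- if (length(scene$surfaces) > 0)
    parse_surface_specs(scene$surfaces) else list()
  w <- scene$water
  th <- if (length(specs) == 0) {
    V_w <- if (!is.null(w$V_w)) w$V_w else water_volume(w$n_sol, w$rho_n)
    structure(list(V_in = 0, V_w = V_w, theta_apparent = 0, theta = 0,
                   theta_sd = 0), class = "theta_result")
  } else {
    compute_theta(specs, V_w = w$V_w, n_sol = w$n_sol, rho_n = w$rho_n,
                  rho_n_sd = if (is.null(w$rho_n_sd)) 0 else w$rho_n_sd,
                  overlap = scene$overlap)
  }
  law <- if (is.null(scene$law)) scaling_law()
         else scaling_law(D_B = if (is.null(scene$law$D_B)) 2.60e-9
                                else scene$law$D_B,
                          D_C = if (is.null(scene$law$D_C)) 0
                                else scene$law$D_C)
  list(V_in = th$V_in, V_w = th$V_w, theta_apparent = th$theta_apparent,
       theta = th$theta, theta_sd = th$theta_sd,
       D = predict_D(th$theta, law), law = law)
}

#' Scaling-law fitting pipeline
#'
#' @param points path to a points file (columns theta, D, optional
#'   sigma_D) or a data.frame
#' @param weighted use inverse-variance weights when sigma_D present
#' @param constrain_DC_zero force D_C = 0
#' @return the [fit_law()] result
#' @export
cmd_fit <- function(points, weighted = TRUE, constrain_DC_zero = FALSE) {
  if (is.character(points)) points <- read_points(points)
  sigma <- if (weighted && "sigma_D" %in% names(points)) points$sigma_D
           else NULL
  fit_law(points$theta, points$D, sigma_D = sigma,
          constrain_DC_zero = constrain_DC_zero)
}

#' Confined-diffusivity-ratio pipeline
#'
#' @param cp_path two-column text table (T, cp)
#' @param g_path two-column text table (T, ratio)
#' @param epsilon well depth (kJ/mol)
#' @param T0 reference temperature (K)
#' @return list: `ratio` (= D_C/D_B), `T_star` (mapped subcooled
#'   temperature, K)
#' @export
cmd_dc_ratio <- function(cp_path, g_path, epsilon, T0 = 300) {
  cp <- read_thermo_table(cp_path)
  g <- read_thermo_table(g_path)
  names(cp) <- c("T", "cp")
  names(g) <- c("T", "ratio")
  tables <- thermo_tables(cp, g, T0 = T0)
  f <- enthalpy_function(tables)
  finv <- invert_enthalpy(f, tables)
  dh <- -epsilon * 1e3 / .M_water
  T_star <- if (dh >= f(tables$cp_samples$T[1])) finv(dh) else NA_real_
  list(ratio = dc_ratio(epsilon, tables), T_star = T_star)
}

#' MSD/Einstein pipeline
#'
#' @param t `trajectory` or path to a trajectory text file
#' @param max_lag_fraction,fit_window,dimensionality passed through to
#'   [msd()] and [estimate_D()]
#' @return `diffusion_estimate`
#' @export
cmd_msd <- function(t, max_lag_fraction = 0.5, fit_window = NULL,
                    dimensionality = 3) {
  if (is.character(t)) t <- read_trajectory(t)
  if (t$wrapped) t <- unwrap(t)
  estimate_D(msd(t, max_lag_fraction), fit_window = fit_window,
             dimensionality = dimensionality)
}

#' Relaxivity-enhancement pipeline
#'
#' Full chain from a label image to the enhancement map: pixel
#' density, pore-scale smoothing with mass conservation,
#' representative-pore theta, calibrated theta map, local volume
#' fractions and the outer-sphere enhancement. The representative
#' pore is assigned the density-weighted mean pore occupancy; the
#' bulk reference volume fraction defaults to the same SPIOs spread
#' over the whole construct volume.
#'
#' @param scene `edx_scene`, or path to a YAML file whose fields match
#'   [edx_scene()] with `image` given as a text-matrix path
#' @param law `scaling_law`
#' @param bandwidth smoothing bandwidth (pixels); NULL = pore scale
#' @param v_bulk bulk reference volume fraction; NULL = automatic
#' @param output optional file prefix; writes theta/D/En maps as text
#'   matrices
#' @return list: `rho_spio`, `theta_bar`, `n_p_spio`, `map`
#'   (`enhancement_map`), `v_bulk`
#' @export
cmd_relaxmap <- function(scene, law = scaling_law(), bandwidth = NULL,
                         v_bulk = NULL, output = NULL) {
  if (is.character(scene)) {
    y <- yaml::read_yaml(scene)
    img <- read_raster(y$image)
    y$image <- NULL
    scene <- do.call(edx_scene, c(list(image = img), y))
  }
  rho_point <- local_density(scene, bandwidth)
  rho_spio <- pore_scale_density(scene, rho_point)
  occ <- rho_spio > 0
  rho_bar <- sum(rho_spio[occ]^2) / sum(rho_spio[occ])
  n_p <- rho_bar * scene$A_p
  theta_bar <- representative_theta(scene, n_p)
  th <- theta_map(scene, rho_spio, theta_bar)
  v <- spio_volume_fraction(scene, rho_spio)
  if (is.null(v_bulk)) {
    V_spio <- 4 * pi / 3 * scene$spio_radius^3
    v_bulk <- scene$N_SPIO * V_spio / (scene$A_SiMP * scene$h)
  }
  map <- enhancement_map(th, v, law, v_bulk, weights = rho_spio)
  if (!is.null(output)) {
    write_raster(map$theta_map, paste0(output, "_theta.txt"))
    write_raster(map$D_map, paste0(output, "_D.txt"))
    write_raster(map$En_map, paste0(output, "_En.txt"))
  }
  list(rho_spio = rho_spio, theta_bar = theta_bar, n_p_spio = n_p,
       map = map, v_bulk = v_bulk)
}
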