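# From a label image of SPIO clusters inside a mesoporous construct
# to maps of theta, D and transverse-relaxivity enhancement.
#
# The chain: pixel-scale SPIO density from the raw image ->
# pore-scale density by kernel smoothing + mass conservation ->
# representative-pore theta via the shell/percolation machinery ->
# theta and D maps -> outer-sphere enhancement En = (v/D)/(v_B/D_B)
# and its SPIO-weighted average.

#' Describe an EDX-like scene of SPIO-loaded mesoporous particles
#'
#' @param image nonnegative 2-D matrix (label intensity per pixel)
#' @param A_pix pixel area (nm^2)
#' @param A_SiMP area of the mesoporous particle (nm^2)
#' @param A_p area of a representative pore (nm^2)
#' @param pore_diameter representative pore diameter (nm)
#' @param h construct height (nm)
#' @param N_SPIO total number of SPIOs in the particle
#' @param spio_radius SPIO core radius (nm)
#' @param c_fill fraction of the pore effectively occupied, in (0, 1]
#' @param delta confinement length at the SPIO surface (nm)
#' @return list of class `edx_scene`
#' @export
edx_scene <- function(image, A_pix, A_SiMP, A_p, pore_diameter, h,
                      N_SPIO, spio_radius, c_fill = 1, delta = 0.5) {
  image <- as.matrix(image)
  if (any(image < 0)) stop("image intensities must be nonnegative")
  if (!(A_pix <= A_p && A_p <= A_SiMP))
    stop("areas must satisfy A_pix <= A_p <= A_SiMP")
  if (c_fill <= 0 || c_fill > 1) stop("c_fill must lie in (0, 1]")
  stopifnot(h > 0, N_SPIO >= 0, spio_radius > 0, delta >= 0,
            pore_diameter > 0)
  structure(list(image = image, A_pix = A_pix, A_SiMP = A_SiMP,
                 A_p = A_p, pore_diameter = pore_diameter, h = h,
                 N_SPIO = N_SPIO, spio_radius = spio_radius,
                 c_fill = c_fill, delta = delta),
            class = "edx_scene")
}

#' Generate a synthetic EDX-like scene
#'
#' Sparse raster with Gaussian-blob clusters at random positions;
#' deterministic for a fixed seed. Emulates the iron label image of a
#' SPIO-loaded mesoporous silicon particle. Geometry defaults follow
#' a 1000-nm discoidal construct with 40-nm pores loaded with 5-nm
#' SPIOs.
#'
#' @param shape image dimensions (pixels), default c(64, 64)
#' @param n_clusters number of clusters
#' @param cluster_size cluster standard deviation (pixels)
#' @param seed RNG seed
#' @param intensity total intensity per cluster
#' @param pixel_nm pixel edge length (nm)
#' @param N_SPIO,spio_radius,c_fill,delta,h,pore_diameter passed to
#'   [edx_scene()]
#' @return `edx_scene`
#' @export
generate_synthetic_edx <- function(shape = c(64, 64), n_clusters = 25,
                                   cluster_size = 2.5, seed = 1,
                                   intensity = 100, pixel_nm = 15.625,
                                   N_SPIO = 20000, spio_radius = 2.5,
                                   c_fill = 0.2, delta = 0.5, h = 400,
                                   pore_diameter = 40) {
  set.seed(seed)
  img <- matrix(0, shape[1], shape[2])
  if (n_clusters > 0) {
    cx <- stats::runif(n_clusters, 1, shape[1])
    cy <- stats::runif(n_clusters, 1, shape[2])
    ix <- matrix(seq_len(shape[1]), shape[1], shape[2])
    iy <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (k in seq_len(n_clusters)) {
      blob <- exp(-((ix - cx[k])^2 + (iy - cy[k])^2) / (2 * cluster_size^2))
      blob[blob < 1e-3 * max(blob)] <- 0  # true zeros outside the cluster
      img <- img + intensity * blob / sum(blob)
    }
  }
  A_pix <- pixel_nm^2
  edx_scene(img, A_pix = A_pix,
            A_SiMP = A_pix * prod(shape),
            A_p = pi * (pore_diameter / 2)^2,
            pore_diameter = pore_diameter, h = h, N_SPIO = N_SPIO,
            spio_radius = spio_radius, c_fill = c_fill, delta = delta)
}

#' Pixel-scale SPIO surface density
#'
#' rho_areal(X, Y) = N_SPIO f(X, Y) / (sum(f) A_pix): the raw image
#' normalized so that summing rho * A_pix over pixels returns N_SPIO.
#'
#' @param scene `edx_scene`
#' @return matrix (SPIO per nm^2)
#' @export
pixel_density <- function(scene) {
  tot <- sum(scene$image)
  if (tot <= 0) stop("image has zero total intensity")
  scene$N_SPIO * scene$image / (tot * scene$A_pix)
}

# separable Gaussian blur, zero-padded edges
gaussian_blur <- function(m, sigma) {
  half <- max(1, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- stats::convolve(c(numeric(half), v, numeric(half)), rev(k),
                           type = "filter")
    out[seq_len(n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' Pore-scale local density of labelled pixels
#'
#' Gaussian-kernel-smoothed density of the non-zero pixels, normalized
#' to unit integral (sum times pixel area equals 1). The default
#' bandwidth is one pore diameter in pixels, replacing the
#' non-representative pixel scale with the pore scale.
#'
#' @param scene `edx_scene`
#' @param bandwidth kernel standard deviation in pixels; default
#'   pore_diameter / pixel edge
#' @return matrix (nm^-2) integrating to 1
#' @export
local_density <- function(scene, bandwidth = NULL) {
  if (is.null(bandwidth))
    bandwidth <- scene$pore_diameter / sqrt(scene$A_pix)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ind <- (scene$image > 0) * 1
  sm <- gaussian_blur(ind, bandwidth)
  sm[sm < 0] <- 0
  tot <- sum(sm) * scene$A_pix
  if (tot <= 0) stop("no labelled pixels in the image")
  sm / tot
}

#' Pore-scale SPIO density by mass conservation
#'
#' rho_SPIO = C rho_point with the constant C fixed so the density
#' integrates back to the total SPIO count:
#' sum(rho_SPIO) * A_pix = N_SPIO.
#'
#' @param scene `edx_scene`
#' @param rho_point smoothed density from [local_density()]
#' @return matrix (SPIO per nm^2)
#' @export
pore_scale_density <- function(scene, rho_point) {
  tot <- sum(rho_point) * scene$A_pix
  if (tot <= 0) stop("rho_point has zero integral")
  scene$N_SPIO * rho_point / tot
}

#' Representative-pore scaling parameter
#'
#' For a pore holding `n_p_spio` SPIOs: the volume of influence is the
#' sum of spherical shells of thickness delta around each SPIO, the
#' water volume is the filled pore volume minus the SPIO cores, and
#' theta is the percolation-corrected ratio (SPIO shells overlap
#' within a pore).
#'
#' @param scene `edx_scene`
#' @param n_p_spio SPIOs in the representative pore (>= 0)
#' @return theta in [0, 1]
#' @export
representative_theta <- function(scene, n_p_spio) {
  if (n_p_spio < 0) stop("n_p_spio must be >= 0")
  if (n_p_spio == 0) return(0)
  r <- scene$spio_radius
  V_core <- 4 * pi / 3 * r^3
  V_in <- n_p_spio * 4 * pi / 3 * ((r + scene$delta)^3 - r^3)
  V_w <- scene$c_fill * scene$A_p * scene$h - n_p_spio * V_core
  if (V_w <= 0) stop("overfilled pore: SPIO cores exceed the water volume")
  min(1, max(0, cpt_correct(V_in / V_w, overlap = TRUE)))
}

#' Scaling-parameter map calibrated to the representative pore
#'
#' theta(X, Y) = C' rho_SPIO(X, Y), with C' fixed so the
#' rho_SPIO-weighted mean of theta over occupied pixels equals the
#' representative-pore value. Values are clamped to [0, 1]; the
#' clamped mass fraction is attached as attribute "clamped_fraction".
#'
#' @param scene `edx_scene`
#' @param rho_spio pore-scale density from [pore_scale_density()]
#' @param theta_bar representative-pore theta in [0, 1]
#' @param occupied_threshold rho_spio level below which a pixel does
#'   not count as occupied (default 0)
#' @return matrix with values in [0, 1]
#' @export
theta_map <- function(scene, rho_spio, theta_bar, occupied_threshold = 0) {
  if (theta_bar < 0 || theta_bar > 1) stop("theta_bar must lie in [0, 1]")
  occ <- rho_spio > occupied_threshold
  if (!any(occ) || sum(rho_spio[occ]) <= 0)
    stop("rho_spio has no occupied pixels")
  w <- rho_spio[occ]
  Cp <- theta_bar * sum(w) / sum(w^2)
  th <- Cp * rho_spio
  clamped <- sum(rho_spio[th > 1]) / sum(rho_spio)
  th <- pmin(pmax(th, 0), 1)   # argument order preserves the matrix shape
  attr(th, "clamped_fraction") <- clamped
  th
}

#' Transverse relaxivity from relaxation times
#'
#' r_2 = (1/T_2 - 1/T_{0,w}) / M_Fe with times in ms (converted to s)
#' and iron concentration in mM.
#'
#' @param T2 transverse relaxation time with contrast agent (ms)
#' @param T0w transverse relaxation time of bulk water (ms),
#'   default 2800
#' @param M_Fe iron concentration (mM)
#' @return relaxivity (mM^-1 s^-1)
#' @export
relaxivity <- function(T2, T0w = 2800, M_Fe = 1) {
  if (any(c(T2, T0w, M_Fe) <= 0)) stop("T2, T0w and M_Fe must be positive")
  (1e3 / T2 - 1e3 / T0w) / M_Fe
}

#' Measured relaxivity enhancement ratio
#'
#' At equal iron concentration the enhancement of a confined agent
#' over the free one is the ratio of their relaxivities.
#'
#' @param r2_confined,r2_bulk transverse relaxivities (mM^-1 s^-1)
#' @return enhancement ratio
#' @export
enhancement_ratio <- function(r2_confined, r2_bulk) {
  if (r2_bulk <= 0) stop("bulk relaxivity must be positive")
  r2_confined / r2_bulk
}

#' Local SPIO volume fraction map
#'
#' v(X, Y) = rho_SPIO * V_SPIO / (h c_fill): SPIO volume per pixel
#' column over the water-accessible slab volume of that column.
#'
#' @param scene `edx_scene`
#' @param rho_spio pore-scale density (nm^-2)
#' @return dimensionless matrix
#' @export
spio_volume_fraction <- function(scene, rho_spio) {
  V_spio <- 4 * pi / 3 * scene$spio_radius^3
  rho_spio * V_spio / (scene$h * scene$c_fill)
}

#' Outer-sphere relaxivity enhancement map and average
#'
#' D(X, Y) = predict_D(theta(X, Y)); En(X, Y) =
#' (v(X, Y)/D(X, Y)) / (v_B/D_B). Pixels where D = 0 (full confinement
#' with D_C = 0) are flagged NA and excluded from the average with a
#' warning. The scalar average En_avg weights En by the normalized
#' SPIO distribution f_SPIO.
#'
#' @param theta_map matrix in [0, 1]
#' @param vol_fraction_map matrix of local SPIO volume fractions
#' @param law `scaling_law`
#' @param v_bulk reference volume fraction of the freely dispersed
#'   agent
#' @param weights weighting field for the average (normalized
#'   internally); defaults to `vol_fraction_map`, which is
#'   proportional to rho_SPIO
#' @return list of class `enhancement_map`: `theta_map`, `D_map`,
#'   `En_map`, `En_avg`, `n_flagged`
#' @export
enhancement_map <- function(theta_map, vol_fraction_map,
                            law = scaling_law(), v_bulk,
                            weights = vol_fraction_map) {
  if (!all(dim(theta_map) == dim(vol_fraction_map)))
    stop("maps must share a shape")
  if (v_bulk <= 0) stop("v_bulk must be positive")
  D <- matrix(predict_D(as.vector(theta_map), law), nrow(theta_map))
  En <- (vol_fraction_map / D) / (v_bulk / law$D_B)
  bad <- D <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) fully confined with D = 0; ",
            "excluded from the average")
    En[bad] <- NA_real_
  }
  ok <- !is.na(En)
  w <- weights
  w[!ok] <- 0
  if (sum(w) <= 0) stop("no valid pixels to average")
  f_spio <- w / sum(w)
  structure(list(theta_map = theta_map, D_map = D, En_map = En,
                 En_avg = sum(En[ok] * f_spio[ok]),
                 n_flagged = sum(bad)),
            class = "enhancement_map")
}

#' @export
print.enhancement_map <- function(x, ...) {
  cat(sprintf("enhancement_map: %d x %d pixels, En_avg = %.4g, max En = %.4g\n",
              nrow(x$En_map), ncol(x$En_map), x$En_avg,
              max(x$En_map, na.rm = TRUE)))
  invisible(x)
}

#' Raster matrix I/O
#'
#' `read_raster` reads a grayscale PNG/TIFF (via the png/tiff
#' packages, if installed) or a plain whitespace-delimited text
#' matrix; `write_raster` writes the text form.
#'
#' @param path file path
#' @param m matrix
#' @return matrix / path invisibly
#' @export
read_raster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG needs the 'png' package")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF needs the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_raster
#' @export
write_raster <- function(m, path) {
  utils::write.table(m, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
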