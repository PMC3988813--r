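# Fully confined diffusivity from supercooled-water thermodynamics.
#
# Water trapped within the confinement layer behaves like supercooled
# bulk water: the energy lost to the wall well (-epsilon) maps, via
# the specific-heat integral f(T) = int_{T0}^{T} c_p dT, to an
# effective subcooled temperature T* = f^{-1}(-epsilon), and the
# measured diffusivity ratio of supercooled water g(T) evaluated at T*
# gives D_C / D_B.

#' Thermodynamic input tables for the confined-diffusivity chain
#'
#' @param cp_samples data.frame with columns `T` (K, strictly
#'   increasing) and `cp` (J/(kg K), positive): specific heat of
#'   confined/supercooled water
#' @param g_samples data.frame with columns `T` (K, strictly
#'   increasing) and `ratio` (in [0, 1]): measured D(T)/D_B of
#'   strongly confined water
#' @param T0 reference bulk temperature (K), inside both T ranges;
#'   default 300
#' @return list of class `thermo_tables`
#' @export
thermo_tables <- function(cp_samples, g_samples, T0 = 300) {
  stopifnot(all(c("T", "cp") %in% names(cp_samples)),
            all(c("T", "ratio") %in% names(g_samples)))
  if (is.unsorted(cp_samples$T, strictly = TRUE) ||
      is.unsorted(g_samples$T, strictly = TRUE))
    stop("temperature grids must be strictly increasing")
  if (any(cp_samples$cp <= 0)) stop("c_p must be positive")
  if (any(g_samples$ratio < 0 | g_samples$ratio > 1))
    stop("diffusivity ratio must lie in [0, 1]")
  if (T0 < cp_samples$T[1] || T0 > cp_samples$T[nrow(cp_samples)] ||
      T0 < g_samples$T[1] || T0 > g_samples$T[nrow(g_samples)])
    stop("T0 must lie within both temperature ranges")
  structure(list(cp_samples = cp_samples, g_samples = g_samples, T0 = T0),
            class = "thermo_tables")
}

#' Read a two-column table (T, value) from a text file
#'
#' @param path file with two whitespace-separated columns and a header
#' @return data.frame
#' @export
read_thermo_table <- function(path) {
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Enthalpy-difference function f(T) = int_{T0}^{T} c_p dT
#'
#' Trapezoidal integration of the sampled specific heat with linear
#' interpolation between samples (exact for piecewise-linear c_p);
#' anchored at f(T0) = 0 and strictly increasing. The returned
#' function errors outside the table range (no extrapolation).
#'
#' @param tables `thermo_tables`
#' @return function T (K) -> delta h (J/kg)
#' @export
enthalpy_function <- function(tables) {
  Tg <- tables$cp_samples$T
  cp <- tables$cp_samples$cp
  Fnode <- c(0, cumsum(diff(Tg) * (cp[-1] + cp[-length(cp)]) / 2))
  eval_raw <- function(x) {
    j <- findInterval(x, Tg, rightmost.closed = TRUE)
    cpx <- stats::approx(Tg, cp, xout = x)$y
    Fnode[j] + (x - Tg[j]) * (cp[j] + cpx) / 2
  }
  F0 <- eval_raw(tables$T0)
  function(T) {
    if (any(T < Tg[1] - 1e-12 | T > Tg[length(Tg)] + 1e-12))
      stop("temperature outside the c_p table range; no extrapolation")
    T <- pmin(Tg[length(Tg)], pmax(Tg[1], T))
    eval_raw(T) - F0
  }
}

#' Inverse of the enthalpy-difference function
#'
#' Monotone inversion of f by bisection to 1e-9 K; f^{-1}(0) = T0 and
#' f^{-1}(f(T)) = T to well below 1e-6 K on the table grid.
#'
#' @param f function returned by [enthalpy_function()]
#' @param tables the same `thermo_tables`
#' @return function delta h (J/kg) -> T (K)
#' @export
invert_enthalpy <- function(f, tables) {
  Tg <- tables$cp_samples$T
  lo <- Tg[1]; hi <- Tg[length(Tg)]
  f_lo <- f(lo); f_hi <- f(hi)
  function(dh) {
    vapply(dh, function(v) {
      if (v < f_lo - 1e-9 || v > f_hi + 1e-9)
        stop("delta h outside the range of f; no extrapolation")
      v <- min(f_hi, max(f_lo, v))
      stats::uniroot(function(T) f(T) - v, lower = lo, upper = hi,
                     tol = 1e-9)$root
    }, numeric(1))
  }
}

#' Fully confined diffusivity ratio D_C / D_B from the well depth
#'
#' Converts the well depth epsilon (kJ/mol per water molecule) to
#' J/kg via the molar mass of water, maps the confinement energy
#' -epsilon to a subcooled temperature through f^{-1}, and evaluates
#' the supercooled diffusivity ratio g there:
#' D_C/D_B = g(f^{-1}(-epsilon)), clamped to [0, 1]. Wells deeper than
#' the table range correspond to essentially frozen interfacial water
#' and return 0 with a warning.
#'
#' @param epsilon well depth (kJ/mol), >= 0
#' @param tables `thermo_tables`
#' @return ratio in [0, 1]
#' @export
#' @examples
#' cp <- data.frame(T = seq(150, 320, 5), cp = 4186)
#' g <- data.frame(T = seq(150, 320, 5),
#'                 ratio = pmin(1, exp((seq(150, 320, 5) - 300) / 40)))
#' tab <- thermo_tables(cp, g)
#' dc_ratio(0, tab)     # g at 300 K
#' dc_ratio(2.0, tab)
dc_ratio <- function(epsilon, tables) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  f <- enthalpy_function(tables)
  finv <- invert_enthalpy(f, tables)
  dh <- -epsilon * 1e3 / .M_water   # kJ/mol -> J/kg
  f_min <- f(tables$cp_samples$T[1])
  vapply(dh, function(v) {
    if (v < f_min) {
      warning("well depth beyond the thermodynamic table range; D_C ~ 0")
      return(0)
    }
    Tstar <- finv(v)
    g <- stats::approx(tables$g_samples$T, tables$g_samples$ratio,
                       xout = Tstar, rule = 1)$y
    if (is.na(g)) {
      warning("mapped temperature outside the g table range; D_C ~ 0")
      return(0)
    }
    min(1, max(0, g))
  }, numeric(1))
}

#' Synthetic thermodynamic tables for testing and demonstration
#'
#' A stand-in (synthetic) emulation of the experimental inputs: a
#' specific-heat curve with a supercooled-water-like peak near 225 K
#' on a 2400 J/(kg K) baseline, and a Vogel-Fulcher-Tammann
#' diffusivity ratio g(T) = exp(-B/(T - T_VFT) + B/(T0 - T_VFT)),
#' equal to 1 at T0 and vanishing towards the glassy regime.
#'
#' @param T_min,T_max,n temperature grid (K)
#' @param T0 reference temperature (K)
#' @param B,T_VFT VFT parameters (K)
#' @return `thermo_tables`
#' @export
synthetic_thermo_tables <- function(T_min = 180, T_max = 320, n = 300,
                                    T0 = 300, B = 900, T_VFT = 175) {
  Tg <- seq(T_min, T_max, length.out = n)
  cp <- 2400 + 2000 * exp(-((Tg - 225) / 25)^2)
  ratio <- pmin(1, exp(-B / (Tg - T_VFT) + B / (T0 - T_VFT)))
  thermo_tables(data.frame(T = Tg, cp = cp),
                data.frame(T = Tg, ratio = ratio), T0 = T0)
}
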