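# Physical constants (SI) and internal unit conventions.
#
# Internal units throughout the package: lengths in nm, energies in
# kJ/mol, charges in elementary charge units e, temperatures in K.
# Diffusivities cross the API in m^2/s; trajectory times in ps.
# All unit conversions happen at I/O boundaries.

.k_B      <- 1.380649e-23      # Boltzmann constant, J/K
.N_A      <- 6.02214076e23     # Avogadro number, 1/mol
.e_charge <- 1.602176634e-19   # elementary charge, C
.eps0     <- 8.8541878128e-12  # vacuum permittivity, F/m
.R_gas    <- .k_B * .N_A / 1e3 # gas constant, kJ/(mol K)
.M_water  <- 0.01801528        # molar mass of water, kg/mol

#' Thermal energy in internal units
#'
#' @param T temperature (K)
#' @return k_B T expressed in kJ/mol
#' @keywords internal
kBT_kJmol <- function(T) .R_gas * T

#' SPC/E-like water model parameters
#'
#' Bundles the water-side parameters entering the effective wall
#' potential and the scaling law: the molecular dipole moment used in
#' the Langevin orientation average, the oxygen Lennard-Jones
#' parameters used in Lorentz-Berthelot combination with wall atoms,
#' and reference bulk properties at 300 K.
#'
#' @param dipole_moment molecular dipole moment (C m); SPC/E value 7.50e-30
#' @param lj_sigma_O oxygen LJ sigma (nm)
#' @param lj_epsilon_O oxygen LJ epsilon (kJ/mol)
#' @param bulk_density bulk liquid density (kg/m^3)
#' @param bulk_diffusivity bulk self-diffusion coefficient (m^2/s) at 300 K
#' @param molecule_mass mass of one water molecule (kg)
#' @return object of class `water_model`
#' @export
#' @examples
#' w <- water_model()
#' w$dipole_moment
water_model <- function(dipole_moment = 7.50e-30,
                        lj_sigma_O = 0.3166,
                        lj_epsilon_O = 0.6502,
                        bulk_density = 998,
                        bulk_diffusivity = 2.60e-9,
                        molecule_mass = .M_water / .N_A) {
  vals <- c(dipole_moment, lj_sigma_O, lj_epsilon_O, bulk_density,
            bulk_diffusivity, molecule_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all water model parameters must be positive and finite")
  structure(list(dipole_moment = dipole_moment,
                 lj_sigma_O = lj_sigma_O,
                 lj_epsilon_O = lj_epsilon_O,
                 bulk_density = bulk_density,
                 bulk_diffusivity = bulk_diffusivity,
                 molecule_mass = molecule_mass),
            class = "water_model")
}

#' Relative percentage change between two values
#'
#' Convenience helper for comparing diffusivities and other scalars:
#' returns 100 * (new - old) / old, so a drop from 2.20 to 0.44
#' gives -80.
#'
#' @param old reference value (nonzero)
#' @param new new value
#' @return signed percentage change
#' @export
percent_change <- function(old, new) {
  if (any(old == 0)) stop("reference value must be nonzero")
  100 * (new - old) / old
}
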