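# Physical constants (SI) used only where absolute units enter: the thermal
# de Broglie wavelength and pressure-volume conversions. Everything else in
# the package is expressed in reduced units (energies in k_B T, beta = 1,
# lengths in Angstrom), which matches how results are reported and removes a
# class of unit errors.
.const <- list(
  h  = 6.62607015e-34,    # J s
  kB = 1.380649e-23,      # J / K
  u  = 1.66053906660e-27  # kg
)

#' Thermal de Broglie wavelength
#'
#' \eqn{\Lambda = h / \sqrt{2 \pi m k_B T}}, the length scale that sets the
#' absolute normalization of ideal free-energy terms. It cancels between the
#' solid and solution sides of a phase equilibrium when both use the same
#' molecular mass and temperature.
#'
#' @param mass molecular (or atomic) mass in unified atomic mass units (u).
#' @param temperature absolute temperature in K.
#' @return wavelength in Angstrom.
#' @examples
#' de_broglie_wavelength(39.948, 298.15)  # argon, ~0.16 Angstrom
#' @export
de_broglie_wavelength <- function(mass, temperature) {
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  m_kg <- mass * .const$u
  lambda_m <- .const$h / sqrt(2 * pi * m_kg * .const$kB * temperature)
  lambda_m * 1e10
}

#' Convert a pressure-volume product to k_B T units
#'
#' Evaluates \eqn{P \Delta V / (k_B T)}. Used to check that the Gibbs/Helmholtz
#' distinction is negligible for solids (\eqn{\Delta G \approx \Delta A}):
#' typical lattice-relaxation volumes give values of order 1e-3 k_B T, far
#' below the statistical error of the simulated legs.
#'
#' @param pressure pressure in kPa.
#' @param delta_volume volume difference in nm^3.
#' @param temperature absolute temperature in K.
#' @return energy in k_B T (dimensionless).
#' @examples
#' pdv_correction(101.325, 0.14, 298.15)  # ~3.4e-3 k_B T
#' @export
pdv_correction <- function(pressure, delta_volume, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  # kPa * nm^3 = 1e3 Pa * 1e-27 m^3 = 1e-24 J
  (pressure * delta_volume * 1e-24) / (.const$kB * temperature)
}
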