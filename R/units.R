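#' Physical constants and unit conventions
#'
#' Conventions used throughout the package: momentum transfer q in inverse
#' angstroms on the neutron side and inverse metres for light scattering,
#' Fourier times in nanoseconds, energies in micro-electronvolts, kinetic
#' (sample-age) times in hours, short-time diffusion coefficients in
#' angstrom^2 per nanosecond and long-time (DLS) diffusion coefficients in
#' m^2 per second.
#'
#' @format A list with elements `hbar_uev_ns` (0.6582119569 ueV ns) and
#'   `kB` (Boltzmann constant, J/K).
#' @export
unit_constants <- list(
  hbar_uev_ns = 0.6582119569,
  kB = 1.380649e-23
)

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB * T / (6 pi eta Rh)` for a sphere of hydrodynamic radius `Rh` in
#' a solvent of viscosity `eta` at temperature `T`.
#' [hydrodynamic_radius()] is the exact inverse.
#'
#' @param temperature_K temperature in kelvin (> 0).
#' @param eta_Pas solvent viscosity in Pa s (> 0).
#' @param Rh_m hydrodynamic radius in metres (> 0).
#' @return diffusion coefficient in m^2/s.
#' @export
#' @examples
#' stokes_einstein(295, 1.1e-3, 3.5e-9)
stokes_einstein <- function(temperature_K, eta_Pas, Rh_m) {
  stopifnot(all(temperature_K > 0), all(eta_Pas > 0), all(Rh_m > 0))
  unit_constants$kB * temperature_K / (6 * pi * eta_Pas * Rh_m)
}

#' @rdname stokes_einstein
#' @param D_m2s diffusion coefficient in m^2/s (> 0).
#' @export
hydrodynamic_radius <- function(temperature_K, eta_Pas, D_m2s) {
  stopifnot(all(temperature_K > 0), all(eta_Pas > 0), all(D_m2s > 0))
  unit_constants$kB * temperature_K / (6 * pi * eta_Pas * D_m2s)
}

#' Momentum transfer from neutron scattering angle
#'
#' `q = (4 pi / lambda) sin(2theta / 2)` with the wavelength in angstroms,
#' giving q in inverse angstroms.
#'
#' @param two_theta_deg full scattering angle in degrees, in `[0, 180)`.
#' @param lambda_A neutron wavelength in angstroms (> 0).
#' @return q in 1/angstrom.
#' @export
#' @examples
#' q_from_angle_neutron(7.3, 8)   # ~0.100 1/A
q_from_angle_neutron <- function(two_theta_deg, lambda_A) {
  if (any(two_theta_deg < 0) || any(two_theta_deg >= 180)) {
    stop("two_theta_deg must lie in [0, 180)")
  }
  stopifnot(all(lambda_A > 0))
  (4 * pi / lambda_A) * sin(two_theta_deg * pi / 360)
}

#' Momentum transfer from light scattering angle
#'
#' `q = (4 pi n / lambda) sin(theta / 2)` with the vacuum wavelength in
#' metres and the solvent refractive index `n`, giving q in 1/m.
#'
#' @param theta_deg scattering angle in degrees, in `(0, 180)`.
#' @param lambda_m laser vacuum wavelength in metres.
#' @param n solvent refractive index (>= 1); default 1.333 for D2O at 633 nm.
#' @return q in 1/m.
#' @export
q_from_angle_light <- function(theta_deg, lambda_m = 633e-9, n = 1.333) {
  if (any(theta_deg <= 0) || any(theta_deg >= 180)) {
    stop("theta_deg must lie in (0, 180)")
  }
  stopifnot(all(lambda_m > 0), all(n >= 1))
  (4 * pi * n / lambda_m) * sin(theta_deg * pi / 360)
}

#' Lattice spacing from Bragg-peak position
#'
#' `d = 2 pi / q`, converted from angstroms to nanometres.
#'
#' @param q_A_inv momentum transfer in 1/angstrom (> 0).
#' @return d-spacing in nanometres.
#' @export
#' @examples
#' d_spacing_nm(0.15)   # ~4.19 nm
d_spacing_nm <- function(q_A_inv) {
  stopifnot(all(q_A_inv > 0))
  (2 * pi / q_A_inv) / 10
}
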