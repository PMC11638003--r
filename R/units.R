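# Physical constants (CODATA 2018, exact SI values)
.const <- list(
  N_A = 6.02214076e23,    # mol^-1
  h   = 6.62607015e-34,   # J s
  c   = 2.99792458e8,     # m s^-1
  k_B = 1.380649e-23,     # J K^-1
  R   = 8.314462618       # J mol^-1 K^-1
)

#' Convert photon flux density to irradiance
#'
#' Converts a photon flux density in microeinstein per second and square
#' meter (1 uE = 1 umol photons) into an irradiance in mW cm^-2 at the
#' given wavelength. At 660 nm, 1 uE s^-1 m^-2 corresponds to about
#' 0.018 mW cm^-2, the regime in which optogenetic reporter assays are
#' typically run.
#'
#' @param flux_uE photon flux density, uE s^-1 m^-2 (non-negative).
#' @param wavelength_nm wavelength in nm (positive).
#' @return irradiance in mW cm^-2.
#' @seealso [irradiance_to_photon_flux()] for the inverse.
#' @export
#' @examples
#' photon_flux_to_irradiance(1, 660)   # ~0.0181
photon_flux_to_irradiance <- function(flux_uE, wavelength_nm) {
  stopifnot(is.numeric(flux_uE), is.numeric(wavelength_nm))
  if (any(flux_uE < 0)) stop("photon flux must be non-negative")
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  e_photon <- .const$h * .const$c / (wavelength_nm * 1e-9)  # J
  w_m2 <- flux_uE * 1e-6 * .const$N_A * e_photon            # W m^-2
  w_m2 * 0.1                                                # mW cm^-2
}

#' Convert irradiance to photon flux density
#'
#' Inverse of [photon_flux_to_irradiance()].
#'
#' @param irradiance_mW_cm2 irradiance in mW cm^-2 (non-negative).
#' @param wavelength_nm wavelength in nm (positive).
#' @return photon flux density in uE s^-1 m^-2.
#' @export
irradiance_to_photon_flux <- function(irradiance_mW_cm2, wavelength_nm) {
  stopifnot(is.numeric(irradiance_mW_cm2))
  if (any(irradiance_mW_cm2 < 0)) stop("irradiance must be non-negative")
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  e_photon <- .const$h * .const$c / (wavelength_nm * 1e-9)
  (irradiance_mW_cm2 / 0.1) / (1e-6 * .const$N_A * e_photon)
}

#' Temperature conversions
#'
#' @param T_C temperature in degree Celsius.
#' @return temperature in kelvin.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @param T_K temperature in kelvin.
#' @return temperature in degree Celsius.
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15
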