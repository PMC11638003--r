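# Published parameter presets for the receptor/PIF pairs at 15 C, their
# Arrhenius activation energies, and the photoconversion calibrations.
# Rates: k_aFR in M^-1 s^-1 (already corrected for the photostationary Pfr
# fraction), k_dFR and k_dR in s^-1; E_A in J mol^-1.
.presets <- list(
  P6A = list(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 2.5, K_d_nM = 183,
             E_A_assoc = 1.2e4, E_A_dissoc = 7.1e4,
             pfr_fraction = 0.73, k_q_consecutive = 1.94),
  PIF6 = list(k_aFR = 5.2e5, k_dFR = 0.07, k_dR = 0.26, K_d_nM = 133,
              E_A_assoc = 1.1e4, E_A_dissoc = 7.2e4,
              pfr_fraction = 0.73, k_q_consecutive = 1.94),
  P3A = list(k_aFR = 3.1e5, k_dFR = 0.10, k_dR = 1.9, K_d_nM = 322,
             E_A_assoc = 2.5e4, E_A_dissoc = 4.7e4,
             pfr_fraction = 0.73, k_q_consecutive = 1.94),
  PIF3 = list(k_aFR = 4.3e5, k_dFR = 0.13, k_dR = 1.6, K_d_nM = 308,
              E_A_assoc = 3.1e4, E_A_dissoc = 5.3e4,
              pfr_fraction = 0.73, k_q_consecutive = 1.94),
  # extended receptor (residues 1-982, dimerization-competent) with P6A
  PhyB982_P6A = list(k_aFR = 9.0e4, k_dFR = 0.095, k_dR = 2.2, K_d_nM = 1050,
                     E_A_assoc = 2.3e4, E_A_dissoc = 7.5e4,
                     pfr_fraction = 0.55, k_q_consecutive = 2.75)
)

# Photoconversion calibrations at 15 C: single-exponential equilibration
# rates under 658-nm light (absorbance at 715 nm and Pr fluorescence
# readouts), the shutter-based total rate, and the far-red photoreversion.
.photoconversion <- list(
  absorbance = data.frame(intensity_mW_cm2 = c(1, 10, 30, 69),
                          rate_s = c(0.19, 1.3, 2.5, 5.2)),
  fluorescence = data.frame(intensity_mW_cm2 = c(1, 10, 30, 69),
                            rate_s = c(0.25, 1.6, 4.2, 6.2)),
  shutter_total_rate = list(rate_s = 10, intensity_mW_cm2 = 69),
  farred = list(rate_s = 2.4, intensity_mW_cm2 = 42)
)

#' Published parameter presets
#'
#' Named parameter sets for the interaction of the phytochrome B
#' photosensory core module with the PIF3/PIF6 variants (P6A, PIF6, P3A,
#' PIF3) at 15 C and for the extended, dimerization-competent receptor
#' fragment with P6A (`"PhyB982_P6A"`). Each preset carries the corrected
#' Pfr-state association rate, the Pfr- and Pr-state dissociation rates,
#' the derived dissociation constant, the Arrhenius activation energies of
#' association and dissociation, the photostationary Pfr fraction under
#' 658-nm light, and the photoreversion rate held fixed in consecutive-model
#' fits.
#'
#' @param name preset name; see [pif_preset_names()].
#' @return a list of preset parameters; `as_rate_constants = TRUE` returns
#'   the kinetic part as a [rate_constants()] object.
#' @param as_rate_constants return a [rate_constants()] object instead of
#'   the raw list.
#' @export
#' @examples
#' pif_preset("P6A")$k_aFR
#' pif_preset("PIF6", as_rate_constants = TRUE)
pif_preset <- function(name, as_rate_constants = FALSE) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  p <- .presets[[name]]
  if (as_rate_constants)
    return(rate_constants(k_aFR = p$k_aFR, k_dFR = p$k_dFR, k_dR = p$k_dR))
  p
}

#' @rdname pif_preset
#' @export
pif_preset_names <- function() names(.presets)

#' @rdname pif_preset
#' @param which calibration table: `"absorbance"`, `"fluorescence"`,
#'   `"shutter_total_rate"`, or `"farred"`.
#' @export
photoconversion_calibration <- function(which = c("absorbance", "fluorescence",
                                                  "shutter_total_rate", "farred")) {
  .photoconversion[[match.arg(which)]]
}
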