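# Diffusion-side computations: solvent viscosity, Stokes-Einstein,
# Smoluchowski encounter rates, and FCS correlogram modelling.

#' Viscosity of pure water
#'
#' Vogel-type empirical correlation
#' `eta(T) = 1e-3 * exp(-3.7188 + 578.919 / (T - 137.546))` Pa s,
#' accurate to better than 1% between 15 and 40 C (1.002e-3 Pa s at
#' 293.15 K). Used to convert diffusion coefficients measured at different
#' temperatures onto a common viscosity scale, assuming the buffer viscosity
#' equals that of water.
#'
#' @param T_K temperature in kelvin, within (273, 373).
#' @return dynamic viscosity in Pa s.
#' @export
water_viscosity <- function(T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 273) || any(T_K >= 373))
    stop("temperature must lie in (273, 373) K")
  1e-3 * exp(-3.7188 + 578.919 / (T_K - 137.546))
}

#' Stokes-Einstein relation
#'
#' `D = k_B T / (6 pi eta R_h)` for a spherical particle; supply either the
#' hydrodynamic radius (to get the diffusion coefficient) or the diffusion
#' coefficient (to get the radius).
#'
#' @param T_K temperature, K (> 0).
#' @param eta dynamic viscosity, Pa s (> 0); defaults to
#'   [water_viscosity()] at `T_K`.
#' @param R_h hydrodynamic radius, m.
#' @param D diffusion coefficient, m^2 s^-1.
#' @return the missing quantity (`D` in m^2 s^-1 or `R_h` in m).
#' @export
#' @examples
#' stokes_einstein(celsius_to_kelvin(15), R_h = 2.3e-9) * 1e12  # ~80 um^2/s
stokes_einstein <- function(T_K, eta = water_viscosity(T_K),
                            R_h = NULL, D = NULL) {
  stopifnot(T_K > 0, eta > 0)
  if (is.null(R_h) == is.null(D))
    stop("supply exactly one of R_h or D")
  if (!is.null(R_h)) {
    if (any(R_h <= 0)) stop("R_h must be positive")
    .const$k_B * T_K / (6 * pi * eta * R_h)
  } else {
    if (any(D <= 0)) stop("D must be positive")
    .const$k_B * T_K / (6 * pi * eta * D)
  }
}

#' Smoluchowski diffusional encounter rate
#'
#' Encounter rate of two diffusing spheres,
#' `4 pi N_A (R_h1 + R_h2) (D1 + D2)`. Both unit conventions are always
#' reported: `as_printed` is the bare SI product (m^3 mol^-1 s^-1, the
#' magnitude conventionally quoted alongside experimental M^-1 s^-1
#' association rate constants in this field) and `si_molar` multiplies by
#' 1000 to give L mol^-1 s^-1.
#'
#' @param R_h1,R_h2 hydrodynamic radii of the two particles, m.
#' @param D1,D2 diffusion coefficients of the two particles, m^2 s^-1.
#' @return named numeric vector with `as_printed` and `si_molar`.
#' @export
#' @examples
#' encounter_rate(2.3e-9, 2.5e-9, 80e-12, 86e-12)  # ~6e6 as printed
encounter_rate <- function(R_h1, R_h2, D1, D2) {
  vals <- c(R_h1, R_h2, D1, D2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("radii and diffusion coefficients must be non-negative")
  base <- 4 * pi * .const$N_A * (R_h1 + R_h2) * (D1 + D2)
  c(as_printed = base, si_molar = base * 1000)
}

#' After-pulsing correction of an FCS correlogram
#'
#' Detector after-pulsing inflates the short-lag autocorrelation. Given a
#' reference correlogram recorded with uncorrelated light (`G_ap`, mean
#' count rate `i_ap`), the measured curve (`G`, mean count rate `i`) is
#' corrected point-wise as `G(tau) - (i_ap / i) * (G_ap(tau) - 1)`. If the
#' lag grids differ, the reference is interpolated log-linearly in lag.
#'
#' @param raw_curve data frame with columns `lag_s` (strictly increasing)
#'   and `G`; attribute or column `mean_count_rate` (Hz).
#' @param ap_curve reference data frame with columns `lag_s`, `G` and its
#'   `mean_count_rate`.
#' @param mean_count_rate,ap_count_rate mean count rates of measurement and
#'   reference (Hz); read from the `mean_count_rate` attribute of each
#'   curve when omitted.
#' @return the corrected curve (`lag_s`, `G`), class `fcs_curve`.
#' @export
correct_afterpulsing <- function(raw_curve, ap_curve,
                                 mean_count_rate = attr(raw_curve, "mean_count_rate"),
                                 ap_count_rate = attr(ap_curve, "mean_count_rate")) {
  for (cv in list(raw_curve, ap_curve))
    if (!all(c("lag_s", "G") %in% names(cv)))
      stop("curves need columns lag_s and G")
  if (is.null(ap_curve)) stop("after-pulsing reference curve is required")
  if (is.null(mean_count_rate) || is.null(ap_count_rate))
    stop("mean count rates of both curves are required")
  if (is.unsorted(raw_curve$lag_s, strictly = TRUE))
    stop("lag grid must be strictly increasing")
  gap <- if (identical(raw_curve$lag_s, ap_curve$lag_s)) ap_curve$G
  else stats::approx(log(ap_curve$lag_s), ap_curve$G,
                     xout = log(raw_curve$lag_s), rule = 2)$y
  out <- data.frame(lag_s = raw_curve$lag_s,
                    G = raw_curve$G - (ap_count_rate / mean_count_rate) * (gap - 1))
  attr(out, "mean_count_rate") <- mean_count_rate
  class(out) <- c("fcs_curve", "data.frame")
  out
}

fcs_model <- function(lag, G0, tau_D, gamma) {
  G0 / ((1 + lag / tau_D) * sqrt(1 + lag / (gamma^2 * tau_D)))
}

#' Fit the 3-D diffusion model to an FCS correlogram
#'
#' Fits `G(tau) = G0 * (1 + tau/tau_D)^-1 * (1 + tau/(gamma^2 tau_D))^-1/2`
#' (zero long-lag baseline) and reports the diffusion coefficient through
#' the standard confocal relation `D = omega_r^2 / (4 tau_D)`. The axial
#' ratio `gamma` and lateral focal radius `omega_r` are calibration
#' constants of the detection volume; the defaults are the 510-nm channel
#' calibration (`gamma = 9`, `omega_r = 250 nm`; the 640-nm channel uses
#' `gamma = 6`, `omega_r = 304 nm`). Setting `fit_gamma = TRUE` frees the
#' axial ratio, mirroring the calibration procedure itself.
#'
#' @param curve data frame with columns `lag_s` and `G`; a curve on the
#'   1-baseline convention can be passed with `baseline_one = TRUE` (1 is
#'   subtracted before fitting).
#' @param gamma axial ratio of the detection volume (fixed unless
#'   `fit_gamma`).
#' @param omega_r lateral focal radius, m.
#' @param fit_gamma free the axial ratio (default FALSE).
#' @param baseline_one input decays to 1 instead of 0 (default FALSE).
#' @return an `fcs_fit` object with estimates `G0`, `tau_D` (s), `gamma`,
#'   and `D` (m^2 s^-1); a non-decaying curve is flagged `"non_decaying"`.
#' @export
fit_fcs <- function(curve, gamma = 9, omega_r = 250e-9,
                    fit_gamma = FALSE, baseline_one = FALSE) {
  if (!all(c("lag_s", "G") %in% names(curve)))
    stop("curve needs columns lag_s and G")
  stopifnot(gamma > 0, omega_r > 0)
  lag <- curve$lag_s
  G <- curve$G - if (baseline_one) 1 else 0
  if (is.unsorted(lag, strictly = TRUE)) stop("lag grid must be strictly increasing")
  n <- length(G)
  head_m <- mean(G[seq_len(max(3L, n %/% 10))])
  tail_m <- mean(G[(n - max(3L, n %/% 10) + 1L):n])
  flags <- character(0)
  if (!(head_m > tail_m + 1e-12 * max(abs(G), 1))) {
    # nothing for the diffusion model to latch onto; report without fitting
    return(new_fit("fcs_fit",
                   estimates = c(G0 = NA_real_, tau_D = NA_real_,
                                 gamma = gamma, D = NA_real_),
                   se = c(G0 = NA_real_, tau_D = NA_real_, gamma = NA_real_,
                          D = NA_real_),
                   rss = NA_real_, fitted = rep(NA_real_, n),
                   flags = "non_decaying", extra = list(omega_r = omega_r)))
  }
  G0s <- max(head_m, 1e-12)
  # lag at half-amplitude as tau_D start
  tds <- lag[which.min(abs(G - G0s / 2))]
  if (tds <= 0) tds <- stats::median(lag)
  df <- data.frame(lag = lag, G = G)
  fit <- if (fit_gamma) {
    minpack.lm::nlsLM(G ~ fcs_model(lag, G0, exp(ltd), exp(lg)), data = df,
                      start = list(G0 = G0s, ltd = log(tds), lg = log(gamma)),
                      control = minpack.lm::nls.lm.control(maxiter = 400))
  } else {
    minpack.lm::nlsLM(G ~ fcs_model(lag, G0, exp(ltd), gamma), data = df,
                      start = list(G0 = G0s, ltd = log(tds)),
                      control = minpack.lm::nls.lm.control(maxiter = 400))
  }
  est <- stats::coef(fit); se <- fit_se(fit)
  tau_D <- exp(est[["ltd"]])
  gam <- if (fit_gamma) exp(est[["lg"]]) else gamma
  D <- omega_r^2 / (4 * tau_D)
  new_fit("fcs_fit",
          estimates = c(G0 = est[["G0"]], tau_D = tau_D, gamma = gam, D = D),
          se = c(G0 = unname(se[["G0"]]), tau_D = tau_D * unname(se[["ltd"]]),
                 gamma = if (fit_gamma) gam * unname(se[["lg"]]) else NA_real_,
                 D = D * unname(se[["ltd"]])),
          rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit),
          flags = flags, extra = list(omega_r = omega_r))
}
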