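# Steady-state receptor distribution at a fixed free-PIF concentration p.
# With p held constant the receptor balance is linear; three rate equations
# plus mass conservation give a 4x4 system in (R, FR, RP, FRP).
receptor_system <- function(k, p, R0) {
  rbind(c(-(k$k1 + k$k3 * p), k$k2, k$k4, 0),
        c(k$k1, -(k$k2 + k$k5 * p), 0, k$k6),
        c(k$k3 * p, 0, -(k$k1 + k$k4), k$k2),
        c(1, 1, 1, 1))
}

receptor_given_p <- function(k, p, R0) {
  A <- receptor_system(k, p, R0)
  x <- solve(A, c(0, 0, 0, R0))
  names(x) <- c("R", "FR", "RP", "FRP")
  x
}

# PIF balance residual f(p) = p + RP(p) + FRP(p) - P0; its root in [0, P0]
# is the photostationary free-PIF concentration.
pif_residual <- function(k, p, R0, P0) {
  x <- receptor_given_p(k, p, R0)
  p + x[["RP"]] + x[["FRP"]] - P0
}

# Cubic coefficients of q(p) = f(p) * det(A(p)), obtained by exact
# polynomial interpolation at four nodes. det(A) is quadratic in p and the
# species numerators are at most quadratic, so q is at most cubic; the
# interpolation therefore reconstructs the steady-state polynomial without
# transcribing its printed coefficient form.
steady_state_polynomial <- function(k, R0, P0) {
  s <- max(P0, R0, 1e-9)
  nodes <- s * c(0.15, 0.45, 0.8, 1.2)
  q <- vapply(nodes, function(p) {
    A <- receptor_system(k, p, R0)
    d <- det(A)
    x <- solve(A, c(0, 0, 0, R0))
    (p + x[3L] + x[4L] - P0) * d
  }, numeric(1))
  V <- outer(nodes, 0:3, `^`)
  coefs <- solve(V, q)          # q(p) = c0 + c1 p + c2 p^2 + c3 p^3
  names(coefs) <- paste0("c", 0:3)
  coefs
}

#' Photostationary state of the reaction network
#'
#' Closed-form steady state of the coupled photoconversion/binding network
#' under constant illumination. The free-PIF concentration is the real root
#' in `[0, P0]` of a cubic polynomial derived from the steady-state
#' conditions of the rate equations together with the receptor and PIF mass
#' balances; the remaining species follow from the linear receptor balance
#' at that root. The polynomial is constructed from the rate equations
#' themselves (see Details), roots are taken with `polyroot`, and a
#' bisection fallback on `[0, P0]` guards degenerate coefficient sets
#' (e.g. the quadratic limit at `k_aR = 0`).
#'
#' @details The rate constants enter through their photostationary aliases
#' k1 = k_p, k2 = k_q + k_rec, k3 = k_aR, k4 = k_dR, k5 = k_aFR,
#' k6 = k_dFR. A valid photostationary state requires light or thermal
#' reversion, i.e. `k1 + k2 > 0`.
#'
#' @param rc a [rate_constants()] object.
#' @param composition a [system_composition()]; only the totals are used.
#' @param intensity light intensity, mW cm^-2.
#' @param channel illumination channel, `"red658"` (default) or
#'   `"farred733"`.
#' @return named numeric vector with elements `R_M`, `FR_M`, `RP_M`,
#'   `FRP_M`, `P_M` (concentrations in M).
#' @export
#' @examples
#' rc <- rate_constants(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 2.5)
#' comp <- system_composition(1e-6, 2e-8)
#' solve_photostationary(rc, comp, 1)
solve_photostationary <- function(rc, composition, intensity,
                                  channel = c("red658", "farred733")) {
  channel <- match.arg(channel)
  stopifnot(inherits(rc, "rate_constants"),
            inherits(composition, "system_composition"))
  kpq <- intensity_to_rates(
    data.frame(channel = channel, intensity = intensity), rc)
  k <- list(k1 = kpq$k_p, k2 = kpq$k_q + rc$k_rec,
            k3 = rc$k_aR, k4 = rc$k_dR, k5 = rc$k_aFR, k6 = rc$k_dFR)
  if (k$k1 + k$k2 <= 0)
    stop("no unique photostationary state: need light or dark reversion (k_p + k_q + k_rec > 0)")
  R0 <- composition$R0_total
  P0 <- composition$P0_total
  phi <- k$k1 / (k$k1 + k$k2)

  if (P0 <= 0 || R0 <= 0) {
    st <- c(R_M = (1 - phi) * R0, FR_M = phi * R0, RP_M = 0, FRP_M = 0, P_M = P0)
    return(st)
  }

  p_root <- tryCatch({
    coefs <- steady_state_polynomial(k, R0, P0)
    roots <- polyroot(coefs)
    s <- max(P0, R0)
    real <- Re(roots)[abs(Im(roots)) < 1e-7 * (abs(roots) + s)]
    cand <- real[real >= -1e-9 * P0 & real <= P0 * (1 + 1e-9)]
    if (length(cand) == 0L) stop("no admissible real root")
    cand <- pmin(pmax(cand, 0), P0)
    resid <- vapply(cand, function(p) abs(pif_residual(k, p, R0, P0)), numeric(1))
    cand[which.min(resid)]
  }, error = function(e) NA_real_)

  f <- function(p) pif_residual(k, p, R0, P0)
  if (is.na(p_root) || abs(f(p_root)) > 1e-9 * P0) {
    # bisection fallback: f(0) = -P0 < 0 and f(P0) >= 0
    p_root <- tryCatch(
      stats::uniroot(f, c(0, P0), tol = .Machine$double.eps^0.75 * max(P0, 1e-12))$root,
      error = function(e)
        stop("photostationary solve failed: no root of the PIF balance in [0, P0] ",
             "(internal consistency error)"))
  }

  x <- receptor_given_p(k, p_root, R0)
  st <- c(R_M = max(x[["R"]], 0), FR_M = max(x[["FR"]], 0),
          RP_M = max(x[["RP"]], 0), FRP_M = max(x[["FRP"]], 0),
          P_M = max(p_root, 0))
  st
}

#' Dose-response of PIF complexation versus light intensity
#'
#' Computes the photostationary bound fraction of the PIF pool over a grid
#' of light intensities and summarizes the characteristic features of the
#' curve: the low-intensity plateau, the location and height of the peak,
#' and the attenuation onset, operationalized as the lowest intensity above
#' the peak at which the bound fraction has fallen a given fraction
#' (default 10%) below the peak value (interpolated on a logarithmic
#' intensity axis).
#'
#' @param rc a [rate_constants()] object.
#' @param composition a [system_composition()].
#' @param intensities positive, strictly increasing intensity grid
#'   (>= 3 points), mW cm^-2.
#' @param channel illumination channel.
#' @param attenuation_drop relative drop below the peak defining the
#'   attenuation onset (default 0.1).
#' @return a data frame of class `dose_response` with columns
#'   `intensity_mW_cm2` and `bound_fraction`; attributes `plateau_low`,
#'   `peak_intensity`, `peak_bound_fraction`, `attenuation_onset` (NA when
#'   the curve never drops below the threshold).
#' @export
dose_response <- function(rc, composition, intensities,
                          channel = "red658", attenuation_drop = 0.1) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 3L || any(intensities <= 0) ||
      is.unsorted(intensities, strictly = TRUE))
    stop("intensities must be a strictly increasing positive grid with >= 3 points")
  bf <- vapply(intensities, function(I) {
    st <- tryCatch(solve_photostationary(rc, composition, I, channel),
                   error = function(e)
                     stop(sprintf("dose_response failed at %g mW cm^-2: %s",
                                  I, conditionMessage(e))))
    (st[["RP_M"]] + st[["FRP_M"]]) / composition$P0_total
  }, numeric(1))

  ipk <- which.max(bf)
  thr <- bf[ipk] * (1 - attenuation_drop)
  onset <- NA_real_
  if (ipk < length(bf)) {
    below <- which(bf < thr & seq_along(bf) > ipk)
    if (length(below) > 0L) {
      j <- below[1L]
      # interpolate crossing on log-intensity
      x1 <- log(intensities[j - 1L]); x2 <- log(intensities[j])
      y1 <- bf[j - 1L]; y2 <- bf[j]
      onset <- exp(x1 + (thr - y1) * (x2 - x1) / (y2 - y1))
    }
  }
  out <- data.frame(intensity_mW_cm2 = intensities, bound_fraction = bf)
  attr(out, "plateau_low") <- bf[1L]
  attr(out, "peak_intensity") <- intensities[ipk]
  attr(out, "peak_bound_fraction") <- bf[ipk]
  attr(out, "attenuation_onset") <- onset
  attr(out, "channel") <- channel
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Families of dose-response curves over a scanned parameter
#'
#' Recomputes the dose-response curve while scaling one model dimension by
#' a set of multipliers, reproducing the classic simulation panels:
#' receptor abundance, Pr-state dissociation rate, Pfr-state binding
#' kinetics (association and dissociation jointly, preserving the
#' dissociation constant), Pfr-state affinity (`k_dFR` alone), thermal dark
#' reversion, and light quality (the k_p/k_q ratio at fixed total
#' photoconversion coefficient; use `Inf` for pure forward driving).
#'
#' @param rc a [rate_constants()] object (reference parameter set).
#' @param composition a [system_composition()] (reference totals).
#' @param dimension one of `"R0_total"`, `"k_dR"`, `"k_aFR_k_dFR"`,
#'   `"k_dFR"`, `"k_rec"`, `"kp_kq_ratio"`.
#' @param multipliers numeric multipliers applied to the scanned dimension;
#'   for `"kp_kq_ratio"` they are the absolute k_p/k_q ratios instead
#'   (`Inf` means k_q = 0).
#' @param intensities intensity grid passed to [dose_response()].
#' @param ... further arguments passed to [dose_response()].
#' @return named list of `dose_response` objects, one per multiplier.
#' @export
scan_panel <- function(rc, composition, dimension, multipliers,
                       intensities, ...) {
  dims <- c("R0_total", "k_dR", "k_aFR_k_dFR", "k_dFR", "k_rec", "kp_kq_ratio")
  if (!dimension %in% dims)
    stop("unknown scan dimension '", dimension, "'; must be one of: ",
         paste(dims, collapse = ", "))
  out <- lapply(multipliers, function(m) {
    rci <- rc; compi <- composition
    switch(dimension,
      R0_total = { compi$R0_total <- composition$R0_total * m },
      k_dR = { rci$k_dR <- rc$k_dR * m },
      k_dFR = { rci$k_dFR <- rc$k_dFR * m },
      k_aFR_k_dFR = { rci$k_aFR <- rc$k_aFR * m; rci$k_dFR <- rc$k_dFR * m },
      k_rec = { rci$k_rec <- rc$k_rec * m },
      kp_kq_ratio = {
        tot <- rc$k_p_coeff + rc$k_q_coeff
        frac <- if (is.infinite(m)) 1 else m / (1 + m)
        rci$k_p_coeff <- tot * frac
        rci$k_q_coeff <- tot * (1 - frac)
      })
    dose_response(rci, compi, intensities, ...)
  })
  names(out) <- as.character(multipliers)
  out
}
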