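#' Microscopic rate constants of the phytochrome-PIF reaction network
#'
#' Bundles the rate constants of the five-species reaction network in which
#' the photoreceptor interconverts between its dark-adapted Pr and
#' light-activated Pfr state (light-driven in both directions) while
#' reversibly binding a PIF partner in either state. Photoconversion rates
#' scale linearly with light intensity, so they are stored as per-intensity
#' coefficients; binding and dissociation rates are intensity-independent.
#'
#' The default red-light calibration pins the total Pr/Pfr equilibration
#' rate k_p + k_q at 10 s^-1 for 69 mW cm^-2 of 658-nm light (shutter-based
#' fluorescence measurement) with the k_p:k_q split fixed at 0.73:0.27, the
#' photostationary Pfr:Pr ratio of the receptor under red light. An
#' alternative absorbance-based calibration (5.2 s^-1 at 69 mW cm^-2) can be
#' selected through [red_calibration()]; the two differ because of the
#' different illumination geometries of the instruments.
#'
#' @param k_aFR bimolecular association rate in the Pfr state, M^-1 s^-1.
#' @param k_dFR unimolecular dissociation rate in the Pfr state, s^-1.
#' @param k_dR unimolecular dissociation rate in the Pr state, s^-1.
#' @param k_aR bimolecular association rate in the Pr state, M^-1 s^-1;
#'   defaults to 0 because the Pr state binds PIFs only weakly.
#' @param k_rec thermal Pfr->Pr dark-reversion rate, s^-1. Defaults to 0:
#'   for the isolated photosensory core module the dark-reversion time
#'   constant exceeds 200 h at 15 C, negligible on experiment timescales,
#'   but it is a first-class parameter because it carries the temperature
#'   dependence of the photostationary state.
#' @param k_p_coeff per-intensity Pr->Pfr photoconversion coefficient,
#'   s^-1 per mW cm^-2 (658-nm channel).
#' @param k_q_coeff per-intensity Pfr->Pr photoreversion coefficient,
#'   s^-1 per mW cm^-2 (658-nm channel).
#' @param k_q733_coeff per-intensity Pfr->Pr photoreversion coefficient for
#'   the 733-nm channel, s^-1 per mW cm^-2. Default reproduces the measured
#'   2.4 s^-1 at the maximal far-red intensity of 42 mW cm^-2.
#' @return an object of class `rate_constants`.
#' @export
#' @examples
#' rc <- rate_constants(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 2.5)
#' intensity_to_rates(light_segment(0, 20, "red658", 69), rc)
rate_constants <- function(k_aFR, k_dFR, k_dR,
                           k_aR = 0, k_rec = 0,
                           k_p_coeff = 10 * 0.73 / 69,
                           k_q_coeff = 10 * 0.27 / 69,
                           k_q733_coeff = 2.4 / 42) {
  vals <- c(k_aFR = k_aFR, k_dFR = k_dFR, k_dR = k_dR, k_aR = k_aR,
            k_rec = k_rec, k_p_coeff = k_p_coeff, k_q_coeff = k_q_coeff,
            k_q733_coeff = k_q733_coeff)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and non-negative")
  structure(as.list(vals), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Phytochrome-PIF rate constants\n")
  cat(sprintf("  k_aFR  %.4g M^-1 s^-1   k_dFR %.4g s^-1\n", x$k_aFR, x$k_dFR))
  cat(sprintf("  k_aR   %.4g M^-1 s^-1   k_dR  %.4g s^-1\n", x$k_aR, x$k_dR))
  cat(sprintf("  k_p_coeff %.4g, k_q_coeff %.4g, k_q733_coeff %.4g s^-1 per mW cm^-2\n",
              x$k_p_coeff, x$k_q_coeff, x$k_q733_coeff))
  cat(sprintf("  k_rec  %.4g s^-1\n", x$k_rec))
  invisible(x)
}

#' Red-light photoconversion calibration
#'
#' Converts a measured total Pr/Pfr equilibration rate (k_p + k_q) at a
#' reference 658-nm intensity into the per-intensity coefficients, splitting
#' by the photostationary Pfr fraction.
#'
#' @param total_rate total equilibration rate k_p + k_q, s^-1, at
#'   `at_intensity`. The shutter-based measurement gives 10 s^-1 at
#'   69 mW cm^-2 (the default); the absorbance-based one gives 5.2 s^-1.
#' @param at_intensity reference intensity, mW cm^-2.
#' @param pfr_fraction photostationary Pfr fraction under the red channel
#'   (default 0.73).
#' @return named list with `k_p_coeff` and `k_q_coeff`.
#' @export
red_calibration <- function(total_rate = 10, at_intensity = 69,
                            pfr_fraction = 0.73) {
  stopifnot(total_rate > 0, at_intensity > 0,
            pfr_fraction > 0, pfr_fraction < 1)
  list(k_p_coeff = total_rate * pfr_fraction / at_intensity,
       k_q_coeff = total_rate * (1 - pfr_fraction) / at_intensity)
}

#' Illumination protocols
#'
#' A protocol is an ordered set of non-overlapping piecewise-constant light
#' segments; times outside any segment are dark. `light_segment()` builds a
#' single segment, `illumination_protocol()` assembles and validates a
#' protocol.
#'
#' @param t_start segment start time, s.
#' @param duration segment duration, s (> 0).
#' @param channel one of `"red658"`, `"farred733"`, `"dark"`.
#' @param intensity light intensity, mW cm^-2 (>= 0; must be 0 for dark).
#' @return `light_segment()`: a one-row data frame; `illumination_protocol()`:
#'   a data frame of class `illumination_protocol` with columns `t_start`,
#'   `duration`, `channel`, `intensity`.
#' @export
#' @examples
#' # 0.5-s saturating red pulse followed by darkness
#' illumination_protocol(light_segment(0, 0.5, "red658", 69))
light_segment <- function(t_start, duration, channel, intensity) {
  channel <- match.arg(channel, c("red658", "farred733", "dark"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(intensity) || intensity < 0) stop("intensity must be >= 0")
  if (channel == "dark" && intensity != 0) stop("dark segments have intensity 0")
  data.frame(t_start = t_start, duration = duration,
             channel = channel, intensity = intensity,
             stringsAsFactors = FALSE)
}

#' @rdname light_segment
#' @param ... one or more segments created with [light_segment()], or a
#'   single data frame of segments.
#' @export
illumination_protocol <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.data.frame(segs[[1L]]) &&
      !inherits(segs[[1L]], "illumination_protocol") &&
      nrow(segs[[1L]]) > 1L) {
    segs <- segs[[1L]]
  } else {
    segs <- do.call(rbind, segs)
  }
  need <- c("t_start", "duration", "channel", "intensity")
  if (!all(need %in% names(segs))) stop("segments need columns ", paste(need, collapse = ", "))
  segs <- segs[order(segs$t_start), , drop = FALSE]
  if (any(segs$duration <= 0)) stop("segment durations must be > 0")
  if (any(segs$intensity < 0)) stop("segment intensities must be >= 0")
  ends <- segs$t_start + segs$duration
  if (nrow(segs) > 1L && any(segs$t_start[-1L] < ends[-nrow(segs)] - 1e-12))
    stop("illumination segments must not overlap")
  rownames(segs) <- NULL
  class(segs) <- c("illumination_protocol", "data.frame")
  segs
}

#' Convert a light segment into photoconversion rates
#'
#' Maps the channel and intensity of one protocol segment to the
#' photoconversion rate constants, assuming linear scaling of both k_p and
#' k_q with intensity. Under 658-nm light the realized k_p/k_q ratio is
#' therefore intensity-independent; 733-nm light drives only the Pfr->Pr
#' direction; darkness drives neither. Thermal dark reversion (`k_rec`) is
#' not included here -- it adds to the Pfr->Pr flux independently of light
#' and is applied by the integrator and the steady-state solver.
#'
#' @param segment a one-row segment (see [light_segment()]).
#' @param rc a [rate_constants()] object.
#' @return named list with photoconversion rates `k_p` and `k_q` in s^-1.
#' @export
intensity_to_rates <- function(segment, rc) {
  stopifnot(inherits(rc, "rate_constants"))
  intensity <- segment$intensity
  if (!is.finite(intensity) || intensity < 0) stop("intensity must be >= 0")
  switch(as.character(segment$channel),
    red658    = list(k_p = rc$k_p_coeff * intensity, k_q = rc$k_q_coeff * intensity),
    farred733 = list(k_p = 0, k_q = rc$k_q733_coeff * intensity),
    dark      = list(k_p = 0, k_q = 0),
    stop("unknown channel: ", segment$channel))
}

#' Photostationary Pfr fraction of the free receptor
#'
#' Under constant light the free receptor settles into a steady Pr:Pfr
#' distribution set by the balance of forward photoconversion (k_p) against
#' photoreversion (k_q) and thermal dark reversion (k_rec):
#' Pfr fraction = k_p / (k_p + k_q + k_rec). With k_rec = 0 the fraction is
#' independent of intensity because k_p and k_q scale together.
#'
#' @param k_p Pr->Pfr photoconversion rate, s^-1.
#' @param k_q Pfr->Pr photoreversion rate, s^-1.
#' @param k_rec thermal Pfr->Pr reversion rate, s^-1.
#' @return the Pfr fraction in `[0, 1]`.
#' @export
#' @examples
#' photostationary_pfr_fraction(7.3, 2.7)  # 0.73
photostationary_pfr_fraction <- function(k_p, k_q, k_rec = 0) {
  if (any(c(k_p, k_q, k_rec) < 0)) stop("rates must be non-negative")
  tot <- k_p + k_q + k_rec
  if (tot <= 0) stop("photostationary state undefined: all rates are zero")
  k_p / tot
}

#' System composition
#'
#' Total concentrations and initial state of the receptor/PIF mixture.
#' The initial receptor pool is split between Pr and Pfr by `pfr_fraction0`
#' and a fraction `bound_fraction0` of the PIF pool starts in complex
#' (distributed over the Pr- and Pfr-state complexes by the same Pfr
#' fraction).
#'
#' @param R0_total total phytochrome concentration, M.
#' @param P0_total total PIF concentration, M.
#' @param pfr_fraction0 initial Pfr fraction of the receptor, in `[0, 1]`.
#' @param bound_fraction0 initial bound fraction of the PIF pool, in `[0, 1]`.
#' @return an object of class `system_composition`.
#' @export
system_composition <- function(R0_total, P0_total,
                               pfr_fraction0 = 0, bound_fraction0 = 0) {
  stopifnot(R0_total >= 0, P0_total >= 0,
            pfr_fraction0 >= 0, pfr_fraction0 <= 1,
            bound_fraction0 >= 0, bound_fraction0 <= 1)
  if (bound_fraction0 > 0 && P0_total * bound_fraction0 > R0_total)
    stop("initial bound PIF exceeds total receptor")
  structure(list(R0_total = R0_total, P0_total = P0_total,
                 pfr_fraction0 = pfr_fraction0,
                 bound_fraction0 = bound_fraction0),
            class = "system_composition")
}

# Initial species vector c(R, FR, RP, FRP, P) in M from a composition.
initial_state <- function(comp) {
  B <- comp$bound_fraction0 * comp$P0_total
  FRP <- comp$pfr_fraction0 * B
  RP <- B - FRP
  FR <- comp$pfr_fraction0 * comp$R0_total - FRP
  R <- (1 - comp$pfr_fraction0) * comp$R0_total - RP
  if (FR < -1e-15 || R < -1e-15) stop("initial bound pool inconsistent with Pfr split")
  c(R = max(R, 0), FR = max(FR, 0), RP = RP, FRP = FRP, P = comp$P0_total - B)
}

# Right-hand side of the reaction network. `conventional = TRUE` drops the
# photoconversion of the bound complex (the simplified scheme in which only
# free receptor cycles between Pr and Pfr).
network_derivs <- function(t, y, parms) {
  k_p <- parms$k_p; k_q <- parms$k_q
  k3 <- parms$k_aR; k4 <- parms$k_dR; k5 <- parms$k_aFR; k6 <- parms$k_dFR
  kpc <- if (parms$conventional) 0 else k_p
  kqc <- if (parms$conventional) 0 else k_q
  R <- y[1L]; FR <- y[2L]; RP <- y[3L]; FRP <- y[4L]; P <- y[5L]
  dR   <- -k_p * R - k3 * R * P + k_q * FR + k4 * RP
  dFR  <-  k_p * R - k_q * FR - k5 * FR * P + k6 * FRP
  dRP  <-  k3 * R * P - kpc * RP - k4 * RP + kqc * FRP
  dFRP <-  kpc * RP - kqc * FRP - k6 * FRP + k5 * FR * P
  dP   <- -k3 * R * P - k5 * FR * P + k4 * RP + k6 * FRP
  list(c(dR, dFR, dRP, dFRP, dP))
}

#' Integrate the reaction network under an illumination protocol
#'
#' Numerically integrates the five-species ODE system (free Pr, free Pfr,
#' Pr:PIF complex, Pfr:PIF complex, free PIF) with the photoconversion rate
#' constants switched per protocol segment; times outside all segments are
#' dark (k_p = k_q = 0). Thermal dark reversion `k_rec` adds to the
#' Pfr->Pr flux at all times. Integration is piecewise per segment with a
#' stiff-capable solver so that rate discontinuities land exactly on
#' segment boundaries.
#'
#' @param rc a [rate_constants()] object.
#' @param protocol an [illumination_protocol()] (or a single segment).
#' @param composition a [system_composition()].
#' @param times strictly increasing output time grid, s.
#' @param model `"full"` (default) lets the bound complex photoconvert like
#'   the free receptor; `"conventional"` is the simplified scheme without
#'   photoconversion within the complex.
#' @param rtol,atol relative/absolute solver tolerances. `atol = NULL`
#'   scales the absolute tolerance to 1e-10 of the largest total
#'   concentration.
#' @return a data frame of class `trajectory` with columns `time_s`, `R_M`,
#'   `FR_M`, `RP_M`, `FRP_M`, `P_M`. The protocol and composition are
#'   attached as attributes.
#' @export
#' @examples
#' rc <- rate_constants(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 2.5)
#' comp <- system_composition(1e-6, 2e-8)
#' prot <- illumination_protocol(light_segment(0, 20, "red658", 69))
#' traj <- simulate_kinetics(rc, prot, comp, seq(0, 40, 0.1))
simulate_kinetics <- function(rc, protocol, composition, times,
                              model = c("full", "conventional"),
                              rtol = 1e-8, atol = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(rc, "rate_constants"),
            inherits(composition, "system_composition"))
  if (is.data.frame(protocol) && !inherits(protocol, "illumination_protocol"))
    protocol <- illumination_protocol(protocol)
  times <- as.numeric(times)
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is.null(atol))
    atol <- 1e-10 * max(composition$R0_total, composition$P0_total, 1e-9)

  # Piecewise timeline: segment boundaries plus dark gaps covering the grid.
  t0 <- times[1L]; t1 <- times[length(times)]
  cuts <- sort(unique(c(t0, t1,
                        pmax(pmin(protocol$t_start, t1), t0),
                        pmax(pmin(protocol$t_start + protocol$duration, t1), t0))))
  y <- initial_state(composition)
  out <- matrix(NA_real_, nrow = length(times), ncol = 5L,
                dimnames = list(NULL, c("R", "FR", "RP", "FRP", "P")))
  if (times[1L] == t0) out[1L, ] <- y

  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    if (b <= a) next
    mid <- (a + b) / 2
    hit <- which(protocol$t_start - 1e-12 <= mid &
                 mid < protocol$t_start + protocol$duration + 1e-12)
    kpq <- if (length(hit) >= 1L) {
      intensity_to_rates(protocol[hit[1L], ], rc)
    } else list(k_p = 0, k_q = 0)
    parms <- list(k_p = kpq$k_p, k_q = kpq$k_q + rc$k_rec,
                  k_aR = rc$k_aR, k_dR = rc$k_dR,
                  k_aFR = rc$k_aFR, k_dFR = rc$k_dFR,
                  conventional = (model == "conventional"))
    inner <- times[times > a & times < b]
    tt <- unique(c(a, inner, b))
    sol <- deSolve::lsoda(y, tt, network_derivs, parms,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("ODE solver failed in segment [%g, %g] s", a, b))
    sol <- as.matrix(sol)
    keep <- match(times[times >= a & times <= b], sol[, "time"])
    out[times >= a & times <= b, ] <- sol[keep, -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }

  out[out < 0 & out > -atol * 10] <- 0
  traj <- data.frame(time_s = times,
                     R_M = out[, "R"], FR_M = out[, "FR"],
                     RP_M = out[, "RP"], FRP_M = out[, "FRP"],
                     P_M = out[, "P"])
  attr(traj, "protocol") <- protocol
  attr(traj, "composition") <- composition
  attr(traj, "model") <- model
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Observable maps
#'
#' Maps species trajectories to instrument signals. Three channels are
#' supported:
#' * `"fret"`: fluorescence of the labeled PIF partner, quenched on
#'   complexation: `F0 * P/P0 + F1 * (RP + FRP)/P0`, requiring `F1 < F0`.
#' * `"pr_fluorescence"`: the weak intrinsic Pr-state fluorescence,
#'   proportional to the total Pr population: `offset + amplitude *
#'   (R + RP)/R0`.
#' * `"a715"`: absorbance at 715 nm, affine in the total Pfr population:
#'   `offset + amplitude * (FR + FRP)/R0`.
#'
#' @param channel one of `"fret"`, `"pr_fluorescence"`, `"a715"`.
#' @param F0 signal of the fully free PIF pool (FRET channel).
#' @param F1 signal of the fully bound PIF pool (FRET channel; `F1 < F0`).
#' @param amplitude,offset affine map for the receptor channels.
#' @return an object of class `observable_map`.
#' @export
observable_map <- function(channel = c("fret", "pr_fluorescence", "a715"),
                           F0 = 1, F1 = 0.86, amplitude = 1, offset = 0) {
  channel <- match.arg(channel)
  if (channel == "fret" && !(F1 < F0))
    stop("FRET channel requires F1 < F0 (complexation quenches)")
  structure(list(channel = channel, F0 = F0, F1 = F1,
                 amplitude = amplitude, offset = offset),
            class = "observable_map")
}

#' Map a trajectory to a measurement trace
#'
#' @param trajectory a `trajectory` from [simulate_kinetics()].
#' @param map an [observable_map()].
#' @return a data frame of class `time_trace` with columns `time_s`, `signal`.
#' @export
observe <- function(trajectory, map) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(map, "observable_map"))
  P0 <- trajectory$P_M + trajectory$RP_M + trajectory$FRP_M
  R0 <- trajectory$R_M + trajectory$FR_M + trajectory$RP_M + trajectory$FRP_M
  signal <- switch(map$channel,
    fret = {
      if (any(P0 <= 0)) stop("FRET channel undefined for zero total PIF")
      map$F0 * trajectory$P_M / P0 +
        map$F1 * (trajectory$RP_M + trajectory$FRP_M) / P0
    },
    pr_fluorescence = {
      if (any(R0 <= 0)) stop("receptor channel undefined for zero total receptor")
      map$offset + map$amplitude * (trajectory$R_M + trajectory$RP_M) / R0
    },
    a715 = {
      if (any(R0 <= 0)) stop("receptor channel undefined for zero total receptor")
      map$offset + map$amplitude * (trajectory$FR_M + trajectory$FRP_M) / R0
    })
  tr <- data.frame(time_s = trajectory$time_s, signal = signal)
  class(tr) <- c("time_trace", "data.frame")
  tr
}

#' Bound fraction along a trajectory or state
#'
#' Fraction of the PIF pool in complex, `(RP + FRP) / P0`.
#'
#' @param x a `trajectory` or a named species vector/list with elements
#'   `RP_M`, `FRP_M`, `P_M`.
#' @return numeric vector of bound fractions.
#' @export
bound_fraction <- function(x) {
  P0 <- x$P_M + x$RP_M + x$FRP_M
  ifelse(P0 > 0, (x$RP_M + x$FRP_M) / P0, NA_real_)
}
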