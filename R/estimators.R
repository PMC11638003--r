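# Shared helpers -------------------------------------------------------------

# Coerce a trace to (t, y, w): accepts a time_trace/data.frame with columns
# time_s and signal (optional sd used as weights 1/sd^2).
trace_xyw <- function(trace, min_points) {
  if (!is.data.frame(trace) || !all(c("time_s", "signal") %in% names(trace)))
    stop("trace must be a data frame with columns time_s and signal")
  if (nrow(trace) < min_points)
    stop("trace needs at least ", min_points, " points")
  w <- if ("sd" %in% names(trace) && all(is.finite(trace$sd)) && all(trace$sd > 0))
    1 / trace$sd^2 else rep(1, nrow(trace))
  list(t = trace$time_s, y = trace$signal, w = w)
}

fit_se <- function(fit) {
  cf <- summary(fit)$coefficients
  stats::setNames(cf[, "Std. Error"], rownames(cf))
}

new_fit <- function(class, estimates, se, rss, fitted, flags = character(0),
                    extra = list()) {
  structure(c(list(estimates = estimates, se = se, rss = rss,
                   fitted = fitted, flags = flags), extra),
            class = c(class, "phypif_fit"))
}

#' @export
print.phypif_fit <- function(x, ...) {
  cat(class(x)[1L], "\n")
  est <- x$estimates
  for (nm in names(est))
    cat(sprintf("  %-16s %.6g  (se %.3g)\n", nm, est[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA_real_))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Exponential decays ----------------------------------------------------------

#' Fit a single-exponential decay
#'
#' Least-squares fit of `F(t) = F0 + F1 * exp(-k * t)`, the workhorse model
#' for photoconversion traces and pseudo-first-order association decays.
#' Starting values come from the tail level and a log-linear regression of
#' the residual amplitude.
#'
#' @param trace data frame with columns `time_s`, `signal` and optionally
#'   `sd` (per-point noise, used as inverse-variance weights).
#' @return an `exp_fit` object with estimates `F0`, `F1`, `k`, asymptotic
#'   standard errors, residual sum of squares, and flags. A constant trace
#'   yields `F1 = 0` with flag `"amplitude_zero"` (rate unidentifiable).
#' @export
fit_monoexponential <- function(trace) {
  d <- trace_xyw(trace, 5L)
  span <- diff(range(d$y))
  if (span <= 1e-12 * max(abs(d$y), 1)) {
    return(new_fit("exp_fit",
                   estimates = c(F0 = mean(d$y), F1 = 0, k = NA_real_),
                   se = c(F0 = stats::sd(d$y) / sqrt(length(d$y)), F1 = NA, k = NA),
                   rss = sum((d$y - mean(d$y))^2), fitted = rep(mean(d$y), length(d$y)),
                   flags = "amplitude_zero"))
  }
  ntail <- max(3L, ceiling(length(d$y) * 0.1))
  F0s <- mean(utils::tail(d$y, ntail))
  F1s <- d$y[1L] - F0s
  amp <- d$y - F0s
  use <- which(abs(amp) > 0.05 * abs(F1s) & sign(amp) == sign(F1s))
  ks <- if (length(use) >= 3L) {
    sl <- stats::coef(stats::lm(log(abs(amp[use])) ~ d$t[use]))[2L]
    max(-sl, 1e-6)
  } else 1 / max(diff(range(d$t)), 1e-6)
  df <- data.frame(t = d$t, y = d$y)
  fit <- minpack.lm::nlsLM(y ~ F0 + F1 * exp(-k * t), data = df,
                           start = list(F0 = F0s, F1 = F1s, k = ks),
                           weights = d$w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  flags <- character(0)
  if (est[["k"]] <= 0) flags <- c(flags, "rate_at_bound")
  new_fit("exp_fit",
          estimates = c(F0 = est[["F0"]], F1 = est[["F1"]], k = est[["k"]]),
          se = fit_se(fit), rss = sum(stats::resid(fit)^2),
          fitted = stats::fitted(fit), flags = flags)
}

#' Fit a double-exponential decay
#'
#' Least-squares fit of `F(t) = F0 + F1 * exp(-k1 * t) + F2 * exp(-k2 * t)`
#' with the convention `k1 > k2` (fast phase first). Used for thermal
#' dark-recovery traces, for which the slower phase typically carries the
#' larger amplitude; the `slower_phase_dominant` element reports whether
#' `|F2| > |F1|`. If the two rate constants collapse (`k1/k2 < 1.5`) or the
#' five-parameter fit fails, the result degrades gracefully to the
#' single-exponential fit with flag `"effectively_monoexponential"`.
#'
#' @inheritParams fit_monoexponential
#' @return an `exp_fit` object with estimates `F0`, `F1`, `k1`, `F2`, `k2`.
#' @export
fit_biexponential <- function(trace) {
  d <- trace_xyw(trace, 8L)
  mono <- fit_monoexponential(trace)
  if ("amplitude_zero" %in% mono$flags) return(mono)
  me <- mono$estimates
  df <- data.frame(t = d$t, y = d$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + F1 * exp(-k1 * t) + F2 * exp(-k2 * t), data = df,
                      start = list(F0 = me[["F0"]],
                                   F1 = me[["F1"]] / 2, k1 = me[["k"]] * 3,
                                   F2 = me[["F1"]] / 2, k2 = me[["k"]] / 3),
                      weights = d$w,
                      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  degrade <- function() {
    out <- mono
    out$estimates <- c(F0 = me[["F0"]], F1 = me[["F1"]], k1 = me[["k"]],
                       F2 = 0, k2 = NA_real_)
    out$se <- c(mono$se[c("F0", "F1")], k1 = unname(mono$se[["k"]]),
                F2 = NA_real_, k2 = NA_real_)
    out$flags <- unique(c(out$flags, "effectively_monoexponential"))
    out$slower_phase_dominant <- FALSE
    out
  }
  if (is.null(fit)) return(degrade())
  est <- stats::coef(fit)
  se <- fit_se(fit)
  if (est[["k1"]] < est[["k2"]]) {   # enforce k1 > k2
    est <- est[c("F0", "F2", "k2", "F1", "k1")]
    se <- se[c("F0", "F2", "k2", "F1", "k1")]
    names(est) <- names(se) <- c("F0", "F1", "k1", "F2", "k2")
  }
  if (!all(is.finite(est[c("k1", "k2")])) || any(est[c("k1", "k2")] <= 0) ||
      est[["k1"]] / est[["k2"]] < 1.5)
    return(degrade())
  new_fit("exp_fit", estimates = est, se = se,
          rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit),
          extra = list(slower_phase_dominant =
                         abs(est[["F2"]]) > abs(est[["F1"]])))
}

# Consecutive two-step kinetics ----------------------------------------------

# Time course of a two-step consecutive reaction (photoreversion with rate
# k_q, then dissociation with rate k_o), written in a cancellation-safe form
# with the removable singularity at k_o = k_q evaluated by its limit
# (1 + k t) exp(-k t).
consecutive_kernel <- function(t, k_q, k_o) {
  delta <- k_q - k_o
  if (abs(delta) < 1e-6 * k_q) {
    (1 + k_o * t) * exp(-k_o * t)
  } else {
    (k_q * exp(-k_o * t) - k_o * exp(-k_q * t)) / delta
  }
}

#' Fit the consecutive photoreversion-then-dissociation model
#'
#' Far-red-driven complex dissociation is a two-step process: the receptor
#' first photoreverts Pfr->Pr (rate `k_q`, fixed from an independent
#' photoreversion measurement), then the Pr-state complex dissociates (rate
#' `k_o`, fitted). The signal model is
#' `F(t) = F0 + (F1 - F0) * h(t)` with
#' `h(t) = [k_q exp(-k_o t) - k_o exp(-k_q t)] / (k_q - k_o)`,
#' so `F(0) = F1` and `F(Inf) = F0`. `F0` and `F1` enter linearly, so the
#' rate is located by profiling over a log-spaced `k_o` grid before the
#' full nonlinear fit. When the fitted `k_o` lies within 5% of the fixed
#' `k_q` the two steps are barely distinguishable and the fit carries flag
#' `"identifiability_warning"` (such estimates underestimate fast
#' dissociation).
#'
#' @inheritParams fit_monoexponential
#' @param k_q_fixed photoreversion rate constant held fixed, s^-1 (> 0).
#' @return a `consecutive_fit` object with estimates `F0`, `F1`, `k_o` and
#'   element `k_q_fixed`.
#' @export
fit_consecutive <- function(trace, k_q_fixed) {
  if (!is.finite(k_q_fixed) || k_q_fixed <= 0) stop("k_q_fixed must be > 0")
  d <- trace_xyw(trace, 5L)
  # profile the linear amplitudes over a k_o grid
  grid <- exp(seq(log(k_q_fixed / 300), log(k_q_fixed * 30), length.out = 60))
  sse <- vapply(grid, function(ko) {
    h <- consecutive_kernel(d$t, k_q_fixed, ko)
    if (any(!is.finite(h))) return(Inf)
    f <- stats::lm(d$y ~ h, weights = d$w)
    sum(d$w * stats::resid(f)^2)
  }, numeric(1))
  ko0 <- grid[which.min(sse)]
  h0 <- consecutive_kernel(d$t, k_q_fixed, ko0)
  lf <- stats::coef(stats::lm(d$y ~ h0, weights = d$w))
  df <- data.frame(t = d$t, y = d$y)
  fit <- minpack.lm::nlsLM(
    y ~ F0 + (F1 - F0) * consecutive_kernel(t, k_q_fixed, k_o), data = df,
    start = list(F0 = lf[[1L]], F1 = lf[[1L]] + lf[[2L]], k_o = ko0),
    weights = d$w,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  est <- stats::coef(fit)
  flags <- character(0)
  if (abs(est[["k_o"]] - k_q_fixed) < 0.05 * k_q_fixed)
    flags <- "identifiability_warning"
  new_fit("consecutive_fit",
          estimates = c(F0 = est[["F0"]], F1 = est[["F1"]], k_o = est[["k_o"]]),
          se = fit_se(fit), rss = sum(stats::resid(fit)^2),
          fitted = stats::fitted(fit), flags = flags,
          extra = list(k_q_fixed = k_q_fixed))
}

# Pseudo-first-order analysis -------------------------------------------------

#' Pseudo-first-order analysis of observable rates versus concentration
#'
#' Under receptor excess the observable relaxation rate depends linearly on
#' the receptor concentration, `k_obs = k_a * [receptor] + k_d`; a
#' (weighted) linear regression yields the bimolecular association rate as
#' the slope and the unimolecular dissociation rate as the intercept.
#' Because only the Pfr-state receptor binds, the raw slope reflects the
#' Pfr-weighted concentration axis and is divided by the photostationary
#' Pfr fraction to give the corrected association rate constant; the
#' dissociation constant follows as `K_d = k_d / k_a_corrected`.
#'
#' @param k_obs_table data frame with columns `concentration_M`, `k_obs`
#'   (s^-1) and optionally `k_obs_sd` (inverse-variance weights).
#' @param pfr_fraction photostationary Pfr fraction in `(0, 1]`
#'   (default 0.73 for the photosensory core module under 658-nm light).
#' @return a `linear_kinetics_fit` object with estimates `k_a_raw`,
#'   `k_a_corrected`, `k_d`, `K_d`. A non-positive slope is flagged
#'   `"association_unresolved"` (then `k_d` is the weighted mean rate and
#'   `K_d` is NA); a negative intercept is flagged `"negative_intercept"`.
#' @export
fit_pseudo_first_order <- function(k_obs_table, pfr_fraction = 0.73) {
  if (!all(c("concentration_M", "k_obs") %in% names(k_obs_table)))
    stop("table needs columns concentration_M and k_obs")
  if (nrow(k_obs_table) < 3L) stop("need at least 3 concentrations")
  if (!(pfr_fraction > 0 && pfr_fraction <= 1))
    stop("pfr_fraction must be in (0, 1]")
  w <- if ("k_obs_sd" %in% names(k_obs_table) && all(k_obs_table$k_obs_sd > 0))
    1 / k_obs_table$k_obs_sd^2 else rep(1, nrow(k_obs_table))
  lf <- stats::lm(k_obs ~ concentration_M, data = k_obs_table, weights = w)
  cf <- stats::coef(lf)
  se <- summary(lf)$coefficients[, "Std. Error"]
  slope <- cf[[2L]]; icpt <- cf[[1L]]
  flags <- character(0)
  if (slope <= 0) {
    flags <- "association_unresolved"
    kd <- sum(w * k_obs_table$k_obs) / sum(w)
    est <- c(k_a_raw = slope, k_a_corrected = NA_real_, k_d = kd, K_d = NA_real_)
    ses <- c(k_a_raw = se[[2L]], k_a_corrected = NA_real_,
             k_d = stats::sd(k_obs_table$k_obs) / sqrt(nrow(k_obs_table)),
             K_d = NA_real_)
  } else {
    kac <- slope / pfr_fraction
    if (icpt < 0) flags <- "negative_intercept"
    Kd <- icpt / kac
    ses <- c(k_a_raw = se[[2L]], k_a_corrected = se[[2L]] / pfr_fraction,
             k_d = se[[1L]],
             K_d = abs(Kd) * sqrt((se[[1L]] / icpt)^2 + (se[[2L]] / slope)^2))
    est <- c(k_a_raw = slope, k_a_corrected = kac, k_d = icpt, K_d = Kd)
  }
  new_fit("linear_kinetics_fit", estimates = est, se = ses,
          rss = sum(w * stats::resid(lf)^2), fitted = stats::fitted(lf),
          flags = flags, extra = list(pfr_fraction = pfr_fraction))
}

# Binding isotherm ------------------------------------------------------------

#' Fit a single-site binding isotherm
#'
#' Fits `F = F0 + (F1 - F0) * c / (c + K_d)` to an equilibrium titration.
#' When a photostationary Pfr fraction is supplied, the concentration axis
#' is multiplied by it before fitting, because only the Pfr-state receptor
#' binds: the corrected `K_d` then approximately equals `pfr_fraction`
#' times the apparent one. `K_d` is fitted on the log scale to enforce
#' positivity.
#'
#' @param titration_table data frame with columns `concentration_M` and
#'   `signal`; at least 5 concentrations spanning the dissociation constant.
#' @param pfr_fraction optional Pfr fraction in `(0, 1]`; `NULL` (default)
#'   fits the apparent axis uncorrected.
#' @return an `isotherm_fit` object with estimates `F0`, `F1`, `K_d`; a
#'   `K_d` outside the titrated range is flagged `"extrapolated_Kd"`.
#' @export
fit_isotherm <- function(titration_table, pfr_fraction = NULL) {
  if (!all(c("concentration_M", "signal") %in% names(titration_table)))
    stop("table needs columns concentration_M and signal")
  if (nrow(titration_table) < 5L) stop("need at least 5 concentrations")
  conc <- titration_table$concentration_M
  if (!is.null(pfr_fraction)) {
    if (!(pfr_fraction > 0 && pfr_fraction <= 1))
      stop("pfr_fraction must be in (0, 1]")
    conc <- conc * pfr_fraction
  }
  y <- titration_table$signal
  F0s <- y[which.min(conc)]
  F1s <- y[which.max(conc)]
  half <- F0s + 0.5 * (F1s - F0s)
  Kds <- conc[which.min(abs(y - half))]
  if (Kds <= 0) Kds <- stats::median(conc[conc > 0])
  df <- data.frame(conc = conc, y = y)
  fit <- minpack.lm::nlsLM(y ~ F0 + (F1 - F0) * conc / (conc + exp(lKd)),
                           data = df,
                           start = list(F0 = F0s, F1 = F1s, lKd = log(Kds)),
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  est <- stats::coef(fit); se <- fit_se(fit)
  Kd <- exp(est[["lKd"]])
  flags <- character(0)
  pos <- conc[conc > 0]
  if (Kd > max(conc) || Kd < min(pos)) flags <- "extrapolated_Kd"
  new_fit("isotherm_fit",
          estimates = c(F0 = est[["F0"]], F1 = est[["F1"]], K_d = Kd),
          se = c(F0 = unname(se[["F0"]]), F1 = unname(se[["F1"]]),
                 K_d = Kd * unname(se[["lKd"]])),
          rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit),
          flags = flags,
          extra = list(pfr_fraction = if (is.null(pfr_fraction)) 1 else pfr_fraction))
}

# Arrhenius -------------------------------------------------------------------

#' Fit the Arrhenius temperature dependence of a rate constant
#'
#' Fits `k = A * exp(-E_A / (R T))`. The default works on the
#' variance-stabilized log scale (`ln k` linear in `1/T`); a direct
#' nonlinear fit is available via `method = "nonlinear"`.
#'
#' @param k_vs_T_table data frame with columns `temperature_K` (or
#'   `temperature_C`) and `k` (> 0), at least 3 temperatures.
#' @param method `"log_linear"` (default) or `"nonlinear"`.
#' @return an `arrhenius_fit` object with estimates `E_A` (J mol^-1) and
#'   `A` (same units as `k`).
#' @export
fit_arrhenius <- function(k_vs_T_table, method = c("log_linear", "nonlinear")) {
  method <- match.arg(method)
  tb <- k_vs_T_table
  if (!"temperature_K" %in% names(tb)) {
    if ("temperature_C" %in% names(tb))
      tb$temperature_K <- celsius_to_kelvin(tb$temperature_C)
    else stop("table needs a temperature_K (or temperature_C) column")
  }
  if (!"k" %in% names(tb)) stop("table needs a column k")
  if (nrow(tb) < 3L) stop("need at least 3 temperatures")
  if (any(tb$k <= 0)) stop("rate constants must be positive")
  Rgas <- .const$R
  lf <- stats::lm(log(k) ~ I(1 / temperature_K), data = tb)
  cf <- stats::coef(lf); se <- summary(lf)$coefficients[, "Std. Error"]
  EA <- -cf[[2L]] * Rgas
  A <- exp(cf[[1L]])
  ses <- c(E_A = se[[2L]] * Rgas, A = A * se[[1L]])
  rss <- sum(stats::resid(lf)^2)
  fitted <- exp(stats::fitted(lf))
  if (method == "nonlinear") {
    df <- data.frame(T = tb$temperature_K, k = tb$k)
    fit <- minpack.lm::nlsLM(k ~ exp(lA) * exp(-EA / (Rgas * T)), data = df,
                             start = list(lA = log(A), EA = EA),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    est <- stats::coef(fit); s2 <- fit_se(fit)
    A <- exp(est[["lA"]]); EA <- est[["EA"]]
    ses <- c(E_A = unname(s2[["EA"]]), A = A * unname(s2[["lA"]]))
    rss <- sum(stats::resid(fit)^2)
    fitted <- stats::fitted(fit)
  }
  new_fit("arrhenius_fit", estimates = c(E_A = EA, A = A), se = ses,
          rss = rss, fitted = fitted,
          extra = list(method = method))
}

# Two-state thermal unfolding -------------------------------------------------

melt_fraction_unfolded <- function(T_K, dH, Tm_K) {
  dG <- dH * (1 - T_K / Tm_K)
  1 / (1 + exp(dG / (.const$R * T_K)))
}

# two-state melt signal with linear baselines; dH parameterized in units of
# 1e5 J/mol for optimizer conditioning
melt_signal <- function(T_K, dT, af, bf, au, bu, dH5, Tm) {
  fu <- melt_fraction_unfolded(T_K, dH5 * 1e5, Tm)
  (af + bf * dT) * (1 - fu) + (au + bu * dT) * fu
}

#' Fit a two-state thermal unfolding curve
#'
#' Fits a circular-dichroism (or other spectroscopic) melting curve to a
#' two-state unfolding model with `dG(T) = dH * (1 - T/Tm)` (no heat
#' capacity term) and fraction unfolded `1 / (1 + exp(dG / (R T)))`,
#' flanked by temperature-linear folded and unfolded baselines:
#' `signal = (af + bf dT) (1 - fu) + (au + bu dT) fu`, `dT = T - mean(T)`.
#'
#' @param cd_curve data frame with columns `temperature_C` (or
#'   `temperature_K`) and `signal`, spanning both baselines.
#' @return a `melt_fit` object with estimates `T_m_K`, `T_m_C`, `dH`
#'   (J mol^-1) and the four baseline parameters. A midpoint outside the
#'   scanned range or non-positive enthalpy is flagged `"no_transition"`.
#' @export
fit_two_state_melt <- function(cd_curve) {
  tb <- cd_curve
  if (!"temperature_K" %in% names(tb)) {
    if ("temperature_C" %in% names(tb))
      tb$temperature_K <- celsius_to_kelvin(tb$temperature_C)
    else stop("curve needs a temperature_K (or temperature_C) column")
  }
  if (!"signal" %in% names(tb)) stop("curve needs a column signal")
  TT <- tb$temperature_K; y <- tb$signal
  n <- length(y)
  if (n < 10L) stop("melting curve needs at least 10 points")
  Tref <- mean(TT)
  nb <- max(3L, floor(n * 0.15))
  lo <- stats::lm(y[seq_len(nb)] ~ I(TT[seq_len(nb)] - Tref))
  hi <- stats::lm(y[(n - nb + 1L):n] ~ I(TT[(n - nb + 1L):n] - Tref))
  # midpoint start: temperature at which the signal crosses halfway between
  # the extrapolated baselines
  bl_lo <- stats::coef(lo)[[1L]] + stats::coef(lo)[[2L]] * (TT - Tref)
  bl_hi <- stats::coef(hi)[[1L]] + stats::coef(hi)[[2L]] * (TT - Tref)
  fu_emp <- (y - bl_lo) / (bl_hi - bl_lo)
  Tms <- TT[which.min(abs(fu_emp - 0.5))]
  df <- data.frame(T = TT, y = y, dT = TT - Tref)
  fit <- minpack.lm::nlsLM(
    y ~ melt_signal(T, dT, af, bf, au, bu, dH5, Tm),
    data = df,
    start = list(af = stats::coef(lo)[[1L]], bf = stats::coef(lo)[[2L]],
                 au = stats::coef(hi)[[1L]], bu = stats::coef(hi)[[2L]],
                 dH5 = 3, Tm = Tms),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit); se <- fit_se(fit)
  Tm <- est[["Tm"]]; dH <- est[["dH5"]] * 1e5
  flags <- character(0)
  if (Tm < min(TT) || Tm > max(TT) || dH <= 0) flags <- "no_transition"
  new_fit("melt_fit",
          estimates = c(T_m_K = Tm, T_m_C = kelvin_to_celsius(Tm), dH = dH,
                        af = est[["af"]], bf = est[["bf"]],
                        au = est[["au"]], bu = est[["bu"]]),
          se = c(T_m_K = unname(se[["Tm"]]), T_m_C = unname(se[["Tm"]]),
                 dH = 1e5 * unname(se[["dH5"]]),
                 af = unname(se[["af"]]), bf = unname(se[["bf"]]),
                 au = unname(se[["au"]]), bu = unname(se[["bu"]])),
          rss = sum(stats::resid(fit)^2), fitted = stats::fitted(fit),
          flags = flags, extra = list(T_ref = Tref))
}
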