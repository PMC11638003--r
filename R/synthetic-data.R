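# Seeded generators producing every input data type the estimators consume,
# with the published kinetic structure and parameter presets, so the full
# pipeline is testable without any measured data.

# Run expr with a local, fully seed-determined RNG state, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.generator_kinds <- c("association_trace", "dissociation_trace",
                      "photoconversion_trace", "titration", "k_vs_T",
                      "melt_curve", "fcs_curve")

#' Specify a synthetic data set
#'
#' A generator spec names the measurement kind, the parameter preset
#' supplying the truth values, optional truth overrides, the sampling grid,
#' the noise level, and the seed; the seed fully determines the output.
#' Defaults emulate the published experimental designs: 0.1-s fluorescence
#' cadence, 20 nM labeled PIF partner, 69 mW cm^-2 0.5-s red pulses,
#' 42 mW cm^-2 far-red photoreversion (2.4 s^-1), a 14% FRET contrast, a
#' 15-90 C melt scan at 1 C steps, and log-spaced FCS lags.
#'
#' @param kind one of `"association_trace"`, `"dissociation_trace"`,
#'   `"photoconversion_trace"`, `"titration"`, `"k_vs_T"`, `"melt_curve"`,
#'   `"fcs_curve"`.
#' @param preset preset name (see [pif_preset()]) supplying truth defaults.
#' @param truth named list of kind-specific truth overrides.
#' @param grid sampling grid override (times in s, concentrations in M,
#'   temperatures in C, or lags in s, depending on kind).
#' @param noise_sd additive Gaussian noise, as a fraction of the signal
#'   span (>= 0).
#' @param seed integer seed.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(kind, preset = "P6A", truth = list(),
                           grid = NULL, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind, .generator_kinds)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kind = kind, preset = preset, truth = truth,
                 grid = grid, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

add_noise <- function(y, noise_sd) {
  span <- diff(range(y))
  if (span <= 0) span <- max(abs(y), 1)
  y + stats::rnorm(length(y), sd = noise_sd * span)
}

#' Generate a synthetic data set
#'
#' Produces one deterministic (seeded) data set of the requested kind.
#' Association and dissociation observables come from the forward kinetic
#' models (the full ODE network for association under a red pulse; the
#' consecutive two-step model for far-red dissociation); the remaining
#' kinds use their closed-form models (single exponential, binding
#' isotherm, Arrhenius, two-state melt, 3-D diffusion correlogram). The
#' truth parameters are attached as the `"truth"` attribute -- metadata for
#' recovery tests, never consumed by the estimators.
#'
#' @param spec a [generator_spec()].
#' @return a data frame whose columns depend on the kind (`time_s`/`signal`
#'   for traces, `concentration_M`/`signal` for titrations,
#'   `temperature_K`/`k` for rate tables, `temperature_C`/`signal` for melt
#'   curves, `lag_s`/`G` for FCS), with attributes `truth` and `spec`.
#' @export
#' @examples
#' spec <- generator_spec("dissociation_trace", "P6A", noise_sd = 0.01, seed = 7)
#' tr <- generate_dataset(spec)
#' attr(tr, "truth")$k_o
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  p <- pif_preset(spec$preset)
  out <- with_local_seed(spec$seed, switch(spec$kind,
    association_trace = {
      truth <- utils::modifyList(list(
        k_aFR = p$k_aFR, k_dFR = p$k_dFR, k_dR = p$k_dR,
        R0_total = 1e-6, P0_total = 2e-8,
        intensity = 69, pulse_s = 0.5, F0 = 1, F1 = 0.86), spec$truth)
      grid <- if (is.null(spec$grid)) seq(0, 20, by = 0.1) else spec$grid
      rc <- rate_constants(k_aFR = truth$k_aFR, k_dFR = truth$k_dFR,
                           k_dR = truth$k_dR)
      prot <- illumination_protocol(
        light_segment(0, truth$pulse_s, "red658", truth$intensity))
      comp <- system_composition(truth$R0_total, truth$P0_total)
      traj <- simulate_kinetics(rc, prot, comp, grid)
      tr <- observe(traj, observable_map("fret", F0 = truth$F0, F1 = truth$F1))
      tr$signal <- add_noise(tr$signal, spec$noise_sd)
      list(data = tr, truth = truth)
    },
    dissociation_trace = {
      truth <- utils::modifyList(list(
        k_q = photoconversion_calibration("farred")$rate_s,
        k_o = p$k_dR, F0 = 1, F1 = 0.9), spec$truth)
      grid <- if (is.null(spec$grid)) seq(0, 8, by = 0.1) else spec$grid
      y <- truth$F0 + (truth$F1 - truth$F0) *
        consecutive_kernel(grid, truth$k_q, truth$k_o)
      d <- data.frame(time_s = grid, signal = add_noise(y, spec$noise_sd))
      list(data = d, truth = truth)
    },
    photoconversion_trace = {
      truth <- utils::modifyList(list(
        rate = photoconversion_calibration("farred")$rate_s,
        F0 = 0.2, F1 = 0.8), spec$truth)
      grid <- if (is.null(spec$grid)) seq(0, 5, by = 0.1) else spec$grid
      y <- truth$F0 + truth$F1 * exp(-truth$rate * grid)
      d <- data.frame(time_s = grid, signal = add_noise(y, spec$noise_sd))
      list(data = d, truth = truth)
    },
    titration = {
      truth <- utils::modifyList(list(
        K_d_apparent = 180e-9, F0 = 1, F1 = 0.86,
        pfr_fraction = p$pfr_fraction), spec$truth)
      grid <- if (is.null(spec$grid))
        c(0, 2.5e-8, 5e-8, 1e-7, 2e-7, 4e-7, 8e-7, 1.6e-6, 3.2e-6) else spec$grid
      y <- truth$F0 + (truth$F1 - truth$F0) * grid / (grid + truth$K_d_apparent)
      d <- data.frame(concentration_M = grid,
                      signal = add_noise(y, spec$noise_sd))
      list(data = d, truth = truth)
    },
    k_vs_T = {
      truth <- utils::modifyList(list(
        E_A = p$E_A_dissoc, k_ref = p$k_dFR, T_ref_K = 288.15), spec$truth)
      grid <- if (is.null(spec$grid)) c(15, 18, 22, 26, 30) else spec$grid
      TK <- celsius_to_kelvin(grid)
      A <- truth$k_ref / exp(-truth$E_A / (.const$R * truth$T_ref_K))
      k <- A * exp(-truth$E_A / (.const$R * TK))
      k <- k * exp(stats::rnorm(length(k), sd = spec$noise_sd))  # log-normal noise
      d <- data.frame(temperature_K = TK, k = k)
      list(data = d, truth = c(truth, A = A))
    },
    melt_curve = {
      truth <- utils::modifyList(list(
        T_m_C = 49.9, dH = 3e5, af = -20, bf = 0.02, au = -2, bu = 0.01),
        spec$truth)
      grid <- if (is.null(spec$grid)) seq(15, 90, by = 1) else spec$grid
      TK <- celsius_to_kelvin(grid)
      Tref <- mean(TK)
      fu <- melt_fraction_unfolded(TK, truth$dH, celsius_to_kelvin(truth$T_m_C))
      y <- (truth$af + truth$bf * (TK - Tref)) * (1 - fu) +
        (truth$au + truth$bu * (TK - Tref)) * fu
      d <- data.frame(temperature_C = grid,
                      signal = add_noise(y, spec$noise_sd))
      list(data = d, truth = truth)
    },
    fcs_curve = {
      truth <- utils::modifyList(list(
        G0 = 0.08, D = 80e-12, omega_r = 250e-9, gamma = 9,
        noise_model = "gaussian"), spec$truth)
      grid <- if (is.null(spec$grid))
        exp(seq(log(1e-6), log(1), length.out = 64)) else spec$grid
      tau_D <- truth$omega_r^2 / (4 * truth$D)
      G <- fcs_model(grid, truth$G0, tau_D, truth$gamma)
      G <- if (identical(truth$noise_model, "poisson_like")) {
        # photon-counting-style noise growing toward short, sparsely
        # occupied lag bins
        G + stats::rnorm(length(G), sd = spec$noise_sd * truth$G0 /
                           sqrt(grid / min(grid)))
      } else add_noise(G, spec$noise_sd)
      d <- data.frame(lag_s = grid, G = G)
      list(data = d, truth = c(truth, tau_D = tau_D))
    }))
  res <- out$data
  attr(res, "truth") <- out$truth
  attr(res, "spec") <- spec
  res
}

#' Write a benchmark fixture suite
#'
#' Writes one seeded fixture per estimator (CSV data plus a JSON sidecar
#' holding the truth metadata) covering the presets, including a
#' four-intensity association set mirroring the 1/10/30/69 mW cm^-2
#' experimental design and a receptor concentration series for
#' pseudo-first-order analysis. Truth parameters live only in the sidecars
#' so estimators cannot see them.
#'
#' @param dir target directory (created if needed).
#' @param seed integer master seed; sub-seeds are derived per fixture, so
#'   two different seeds share truth parameters but differ in noise.
#' @param noise_sd noise level for all fixtures (fraction of span).
#' @return invisibly, a character vector of the files written.
#' @export
make_benchmark_suite <- function(dir, seed = 1L, noise_sd = 0.01) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- as.integer(seed)
  files <- character(0)
  emit <- function(name, data, truth) {
    fd <- file.path(dir, paste0(name, ".csv"))
    fm <- file.path(dir, paste0(name, "_truth.json"))
    utils::write.csv(data, fd, row.names = FALSE)
    jsonlite::write_json(truth, fm, auto_unbox = TRUE, digits = NA)
    files <<- c(files, fd, fm)
  }
  sub <- function(i) (seed * 1000L + i) %% .Machine$integer.max

  # four-intensity association set (20-s constant-light design)
  for (i in seq_along(c(1, 10, 30, 69))) {
    I <- c(1, 10, 30, 69)[i]
    spec <- generator_spec("association_trace", "P6A",
                           truth = list(intensity = I, pulse_s = 20),
                           noise_sd = noise_sd, seed = sub(i))
    d <- generate_dataset(spec)
    emit(sprintf("association_%02dmW", I), d, attr(d, "truth"))
  }
  # shutter-pulse receptor series for pseudo-first-order analysis
  concs <- c(5e-7, 1e-6, 1.5e-6, 2e-6)
  for (j in seq_along(concs)) {
    spec <- generator_spec("association_trace", "P6A",
                           truth = list(R0_total = concs[j]),
                           noise_sd = noise_sd, seed = sub(10L + j))
    d <- generate_dataset(spec)
    emit(sprintf("association_pulse_%04.0fnM", concs[j] * 1e9), d,
         attr(d, "truth"))
  }
  others <- list(
    dissociation = generator_spec("dissociation_trace", "P6A",
                                  noise_sd = noise_sd, seed = sub(20L)),
    photoreversion = generator_spec("photoconversion_trace", "P6A",
                                    noise_sd = noise_sd, seed = sub(21L)),
    titration = generator_spec("titration", "P6A",
                               noise_sd = noise_sd, seed = sub(22L)),
    arrhenius = generator_spec("k_vs_T", "P6A",
                               noise_sd = noise_sd, seed = sub(23L)),
    melt = generator_spec("melt_curve", "P6A",
                          noise_sd = noise_sd, seed = sub(24L)),
    fcs = generator_spec("fcs_curve", "P6A",
                         noise_sd = noise_sd, seed = sub(25L)))
  for (nm in names(others)) {
    d <- generate_dataset(others[[nm]])
    emit(nm, d, attr(d, "truth"))
  }
  invisible(files)
}
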