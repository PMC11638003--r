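test_that("monoexponential fit is exact on noiseless data and flags constants", {
  t <- seq(0, 2, by = 0.02)
  for (k_true in c(0.19, 2.4, 5.2)) {
    tr <- data.frame(time_s = t, signal = 0.3 + 0.7 * exp(-k_true * t))
    fit <- fit_monoexponential(tr)
    expect_equal(fit$estimates[["k"]], k_true, tolerance = 1e-8)
    expect_equal(fit$estimates[["F0"]], 0.3, tolerance = 1e-8)
    expect_lt(fit$rss, 1e-18)
  }
  flat <- fit_monoexponential(data.frame(time_s = t, signal = rep(1, length(t))))
  expect_true("amplitude_zero" %in% flat$flags)
  expect_equal(flat$estimates[["F1"]], 0)
  expect_true(is.na(flat$estimates[["k"]]))
})

test_that("monoexponential errors are calibrated over a seeded ensemble", {
  set.seed(2024)
  t <- seq(0, 3, by = 0.1)
  model <- 0.2 + 0.8 * exp(-2.4 * t)
  khat <- se <- numeric(500)
  for (i in 1:500) {
    tr <- data.frame(time_s = t, signal = model + rnorm(length(t), sd = 0.02 * 0.8))
    f <- fit_monoexponential(tr)
    khat[i] <- f$estimates[["k"]]; se[i] <- f$se[["k"]]
  }
  expect_lt(abs(mean(khat) - 2.4) / 2.4, 0.01)       # unbiased recovery
  expect_gt(sd(khat) / mean(se), 0.7)                # asymptotic SE calibrated
  expect_lt(sd(khat) / mean(se), 1.3)
})

test_that("biexponential fit resolves two phases and respects the nested limit", {
  t <- seq(0, 40, by = 0.25)
  y <- 0.1 + 0.3 * exp(-1.0 * t) + 0.6 * exp(-0.1 * t)
  fit <- fit_biexponential(data.frame(time_s = t, signal = y))
  expect_equal(fit$estimates[["k1"]], 1.0, tolerance = 1e-6)
  expect_equal(fit$estimates[["k2"]], 0.1, tolerance = 1e-6)
  expect_gt(fit$estimates[["k1"]], fit$estimates[["k2"]])  # ordering convention
  expect_true(fit$slower_phase_dominant)

  # single-phase data: degrades to the monoexponential solution
  y1 <- 0.1 + 0.9 * exp(-0.5 * t)
  nested <- fit_biexponential(data.frame(time_s = t, signal = y1))
  if ("effectively_monoexponential" %in% nested$flags) {
    expect_equal(nested$estimates[["k1"]], 0.5, tolerance = 1e-6)
  } else {
    ks <- nested$estimates[c("k1", "k2")]
    amps <- nested$estimates[c("F1", "F2")]
    main <- which.max(abs(amps))
    expect_equal(unname(ks[main]), 0.5, tolerance = 1e-4)
    expect_lt(abs(amps[-main]) / abs(amps[main]), 1e-3)
  }
})

test_that("dark-recovery speed-up across temperatures implies ~1e5 J/mol activation energy", {
  # biexponential slow phases that accelerate 10-fold between 15 and 30 C
  t <- seq(0, 3000, by = 10)
  temps <- c(15, 22, 30)
  k15 <- 1e-3
  EA_true <- log(10) * 8.314462618 /
    (1 / celsius_to_kelvin(15) - 1 / celsius_to_kelvin(30))
  ks <- k15 * exp(-EA_true / 8.314462618 *
                    (1 / celsius_to_kelvin(temps) - 1 / celsius_to_kelvin(15)))
  kslow <- vapply(ks, function(k) {
    y <- 0.1 + 0.25 * exp(-20 * k * t) + 0.65 * exp(-k * t)
    f <- fit_biexponential(data.frame(time_s = t, signal = y))
    f$estimates[["k2"]]
  }, numeric(1))
  arr <- fit_arrhenius(data.frame(temperature_C = temps, k = kslow))
  expect_gt(arr$estimates[["E_A"]], 5e4)
  expect_lt(arr$estimates[["E_A"]], 2e5)
})

test_that("consecutive two-step fit recovers the downstream rate with k_q fixed", {
  t <- seq(0, 40, by = 0.05)
  y <- 1 + (0.9 - 1) * phypif:::consecutive_kernel(t, 2.4, 0.11)
  fit <- fit_consecutive(data.frame(time_s = t, signal = y), k_q_fixed = 2.4)
  expect_equal(fit$estimates[["k_o"]], 0.11, tolerance = 1e-8)
  expect_equal(fit$estimates[["F0"]], 1, tolerance = 1e-8)
  expect_length(fit$flags, 0)

  # k_o << k_q: the late decay is a delayed monoexponential with rate k_o
  y2 <- 1 - 0.1 * phypif:::consecutive_kernel(t, 2.4, 0.02)
  f2 <- fit_consecutive(data.frame(time_s = t, signal = y2), 2.4)
  late <- t > 3
  mono <- fit_monoexponential(data.frame(time_s = t[late], signal = y2[late]))
  expect_equal(f2$estimates[["k_o"]], mono$estimates[["k"]], tolerance = 0.01)

  # near-coincident rates trigger the identifiability warning
  set.seed(5)
  y3 <- 1 - 0.1 * phypif:::consecutive_kernel(t, 2.4, 2.5) +
    rnorm(length(t), sd = 1e-4)
  f3 <- fit_consecutive(data.frame(time_s = t, signal = y3), 2.4)
  expect_true("identifiability_warning" %in% f3$flags)
  expect_equal(f3$estimates[["k_o"]], 2.5, tolerance = 0.1)
})

test_that("consecutive kernel handles the removable singularity at k_o = k_q", {
  t <- seq(0, 5, by = 0.5)
  lim <- phypif:::consecutive_kernel(t, 2, 2)
  expect_equal(lim, (1 + 2 * t) * exp(-2 * t), tolerance = 1e-12)
  near <- phypif:::consecutive_kernel(t, 2, 2 * (1 + 1e-9))
  expect_equal(near, lim, tolerance = 1e-7)
})

test_that("pseudo-first-order analysis extracts corrected slope, intercept and K_d", {
  conc <- c(5e-7, 1e-6, 1.5e-6, 2e-6)
  tbl <- data.frame(concentration_M = conc, k_obs = 4.4e5 * conc + 0.11)
  fit <- fit_pseudo_first_order(tbl, pfr_fraction = 0.73)
  expect_equal(fit$estimates[["k_a_raw"]], 4.4e5, tolerance = 1e-10)
  expect_equal(fit$estimates[["k_a_corrected"]], 4.4e5 / 0.73, tolerance = 1e-10)
  expect_equal(fit$estimates[["k_a_corrected"]], 6.1e5, tolerance = 0.02)
  expect_equal(fit$estimates[["k_d"]], 0.11, tolerance = 1e-10)
  # K_d consistency: K_d * k_a_corrected = k_d exactly
  expect_identical(fit$estimates[["K_d"]] * fit$estimates[["k_a_corrected"]],
                   fit$estimates[["k_d"]])

  ident <- fit_pseudo_first_order(tbl, pfr_fraction = 1)
  expect_identical(ident$estimates[["k_a_corrected"]], ident$estimates[["k_a_raw"]])

  # concentration-independent rates: dissociation-dominated regime
  flat <- fit_pseudo_first_order(
    data.frame(concentration_M = conc, k_obs = rep(2.5, 4)))
  expect_true("association_unresolved" %in% flat$flags)
  expect_equal(flat$estimates[["k_d"]], 2.5)
  expect_true(is.na(flat$estimates[["K_d"]]))
})

test_that("binding isotherm fit recovers the corrected dissociation constant", {
  conc <- c(0, 5e-8, 1e-7, 2e-7, 4e-7, 8e-7, 1.6e-6, 3.2e-6)
  y <- 1 + (0.86 - 1) * conc / (conc + 180e-9)
  fit <- fit_isotherm(data.frame(concentration_M = conc, signal = y),
                      pfr_fraction = 0.73)
  expect_equal(fit$estimates[["K_d"]] * 1e9, 131.4, tolerance = 0.01)
  expect_equal(fit$estimates[["F1"]], 0.86, tolerance = 1e-6)

  # infinite-affinity limit: signal steps to the bound plateau immediately
  ystep <- ifelse(conc > 0, 0.86, 1)
  step <- fit_isotherm(data.frame(concentration_M = conc, signal = ystep))
  expect_lt(step$estimates[["K_d"]], 5e-9)
  expect_true("extrapolated_Kd" %in% step$flags)

  # seeded noisy recovery
  set.seed(77)
  Kds <- replicate(100, {
    yn <- y + rnorm(length(y), sd = 0.03 * 0.14)
    fit_isotherm(data.frame(concentration_M = conc, signal = yn),
                 pfr_fraction = 0.73)$estimates[["K_d"]]
  })
  expect_lt(abs(median(Kds) - 131.4e-9) / 131.4e-9, 0.10)
})

test_that("Arrhenius fit recovers activation energies and the viscosity correction", {
  TK <- c(288.15, 295.15, 303.15)
  A <- 1e17
  k <- A * exp(-7.1e4 / (8.314462618 * TK))
  fit <- fit_arrhenius(data.frame(temperature_K = TK, k = k))
  expect_equal(fit$estimates[["E_A"]], 7.1e4, tolerance = 1e-8)
  expect_equal(fit$estimates[["A"]], A, tolerance = 1e-6)
  nl <- fit_arrhenius(data.frame(temperature_K = TK, k = k), method = "nonlinear")
  expect_equal(nl$estimates[["E_A"]], 7.1e4, tolerance = 1e-6)

  flatfit <- fit_arrhenius(data.frame(temperature_K = TK, k = rep(0.5, 3)))
  expect_equal(flatfit$estimates[["E_A"]], 0, tolerance = 1e-10)
  expect_error(fit_arrhenius(data.frame(temperature_K = TK, k = c(1, -1, 1))),
               "positive")

  # diffusion-limited association: dividing by the water-viscosity ratio
  # removes most of the apparent temperature dependence
  kdiff <- 1e5 * (TK / 288.15) * (water_viscosity(288.15) / water_viscosity(TK))
  raw <- fit_arrhenius(data.frame(temperature_K = TK, k = kdiff))
  corr <- fit_arrhenius(data.frame(
    temperature_K = TK, k = kdiff * water_viscosity(TK) / water_viscosity(288.15)))
  expect_gt(raw$estimates[["E_A"]], 1e4)
  # residual apparent activation energy of the corrected data is just the
  # k_B T scale (~2.5 kJ/mol), far below the raw value
  expect_lt(abs(corr$estimates[["E_A"]]), 3e3)
})

test_that("two-state melt fit recovers the midpoint and behaves at the midpoint", {
  tr <- generate_dataset(generator_spec("melt_curve", noise_sd = 0))
  truth <- attr(tr, "truth")
  fit <- fit_two_state_melt(tr)
  expect_equal(fit$estimates[["T_m_C"]], truth$T_m_C, tolerance = 1e-7)
  expect_equal(fit$estimates[["dH"]], truth$dH, tolerance = 1e-5)
  # at T = T_m the two-state signal sits midway between the baselines
  TmK <- celsius_to_kelvin(truth$T_m_C)
  Tref <- fit$T_ref
  bl_f <- fit$estimates[["af"]] + fit$estimates[["bf"]] * (TmK - Tref)
  bl_u <- fit$estimates[["au"]] + fit$estimates[["bu"]] * (TmK - Tref)
  mid_model <- (bl_f + bl_u) / 2
  idx <- which.min(abs(tr$temperature_C - truth$T_m_C))
  expect_equal(tr$signal[idx], mid_model, tolerance = 0.02 * abs(diff(c(bl_f, bl_u))))
})

test_that("melt midpoint precision at 1% noise matches the sub-degree regime", {
  set.seed(99)
  tms <- ses <- numeric(60)
  for (i in 1:60) {
    tr <- generate_dataset(generator_spec("melt_curve", noise_sd = 0.01, seed = i))
    f <- fit_two_state_melt(tr)
    tms[i] <- f$estimates[["T_m_C"]]; ses[i] <- f$se[["T_m_C"]]
  }
  expect_lt(sd(tms), 0.3)                       # sub-degree scatter
  expect_gt(sd(tms) / mean(ses), 0.7)           # calibrated asymptotic errors
  expect_lt(sd(tms) / mean(ses), 1.3)
})
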