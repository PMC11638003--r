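test_that("light segments map to photoconversion rates with the fixed red ratio", {
  rc <- p6a_rates()
  r <- intensity_to_rates(light_segment(0, 20, "red658", 69), rc)
  expect_equal(r$k_p, 7.3, tolerance = 1e-12)
  expect_equal(r$k_q, 2.7, tolerance = 1e-12)
  expect_equal(r$k_p / r$k_q, 0.73 / 0.27, tolerance = 1e-12)

  d <- intensity_to_rates(light_segment(5, 1, "dark", 0), rc)
  expect_identical(c(d$k_p, d$k_q), c(0, 0))

  fr <- intensity_to_rates(light_segment(0, 10, "farred733", 42), rc)
  expect_equal(fr$k_p, 0)
  expect_equal(fr$k_q, 2.4, tolerance = 1e-12)

  expect_error(intensity_to_rates(data.frame(channel = "red658", intensity = -1), rc),
               ">= 0")
  # realized ratio independent of intensity under red light
  for (I in c(0.1, 3, 69)) {
    ri <- intensity_to_rates(data.frame(channel = "red658", intensity = I), rc)
    expect_equal(ri$k_p / ri$k_q, 0.73 / 0.27, tolerance = 1e-12)
  }
})

test_that("photon flux converts to irradiance and back", {
  expect_equal(photon_flux_to_irradiance(1, 660), 0.018, tolerance = 0.03)
  expect_identical(photon_flux_to_irradiance(0, 500), 0)
  expect_equal(photon_flux_to_irradiance(10, 660),
               10 * photon_flux_to_irradiance(1, 660), tolerance = 1e-14)
  expect_equal(irradiance_to_photon_flux(photon_flux_to_irradiance(7.5, 658), 658),
               7.5, tolerance = 1e-12)
  expect_error(photon_flux_to_irradiance(1, 0), "wavelength")
  expect_error(photon_flux_to_irradiance(-1, 660), "non-negative")
})

test_that("free-receptor photostationary Pfr fraction follows the rate balance", {
  expect_equal(photostationary_pfr_fraction(7.3, 2.7), 0.73, tolerance = 1e-12)
  expect_equal(photostationary_pfr_fraction(1, 1), 0.5)
  expect_equal(photostationary_pfr_fraction(7.3, 2.7, 2.7), 7.3 / 12.7,
               tolerance = 1e-12)
  expect_error(photostationary_pfr_fraction(0, 0, 0), "undefined")
})

test_that("trajectories conserve mass and stay non-negative", {
  set.seed(11)
  for (i in 1:8) {
    d <- random_draw()
    prot <- illumination_protocol(
      light_segment(0, 5, "red658", d$intensity),
      light_segment(8, 4, "farred733", 10))
    traj <- simulate_kinetics(d$rc, prot, d$comp, seq(0, 15, by = 0.25))
    Rtot <- traj$R_M + traj$FR_M + traj$RP_M + traj$FRP_M
    Ptot <- traj$P_M + traj$RP_M + traj$FRP_M
    expect_lt(max(abs(Rtot - d$comp$R0_total)) / d$comp$R0_total, 1e-6)
    expect_lt(max(abs(Ptot - d$comp$P0_total)) / d$comp$P0_total, 1e-6)
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("without driving terms a dark trajectory is constant", {
  rc <- rate_constants(k_aFR = 0, k_dFR = 0.1, k_dR = 1, k_aR = 0)
  comp <- system_composition(1e-6, 2e-8, pfr_fraction0 = 0)
  prot <- illumination_protocol(light_segment(0, 1e-3, "dark", 0))
  traj <- simulate_kinetics(rc, prot, comp, seq(0, 50, by = 10))
  expect_equal(traj$R_M, rep(1e-6, 6), tolerance = 1e-12)
  expect_equal(traj$P_M, rep(2e-8, 6), tolerance = 1e-12)
  expect_true(all(traj$FRP_M == 0))
})

test_that("high fluence depletes the complex during light; post-light signals converge", {
  rc <- p6a_rates()
  comp <- standard_mix()
  times <- seq(0, 120, by = 0.5)
  run <- function(I) {
    prot <- illumination_protocol(light_segment(0, 20, "red658", I))
    simulate_kinetics(rc, prot, comp, times)
  }
  lo <- run(1); hi <- run(69)
  bf_lo <- bound_fraction(lo); bf_hi <- bound_fraction(hi)
  i20 <- which(times == 20)
  expect_lt(bf_hi[i20], bf_lo[i20])        # attenuation under strong light
  # dark re-equilibration converges to a near-common level (a ~1% memory of
  # the light-off Pr:Pfr partition persists without thermal reversion)
  iend <- length(times)
  expect_equal(bf_hi[iend], bf_lo[iend], tolerance = 0.02)
})

test_that("long constant-light trajectories reach the analytic photostationary state", {
  set.seed(21)
  for (i in 1:5) {
    d <- random_draw()
    st <- solve_photostationary(d$rc, d$comp, d$intensity)
    horizon <- equilibration_time(d$rc, d$comp, d$intensity)
    prot <- illumination_protocol(
      light_segment(0, horizon * 1.01, "red658", d$intensity))
    traj <- simulate_kinetics(d$rc, prot, d$comp, c(0, horizon))
    term <- unlist(traj[nrow(traj), -1])
    names(term) <- names(st)
    scale <- max(d$comp$R0_total, d$comp$P0_total)
    expect_lt(max(abs(term - st)) / scale, 1e-5)
  }
})

test_that("observable maps interpolate between free and bound plateaus", {
  # hand-built trajectories at the boundaries of the affine FRET map
  base <- data.frame(time_s = 0, R_M = 1e-6, FR_M = 0, RP_M = 0, FRP_M = 0,
                     P_M = 2e-8)
  class(base) <- c("trajectory", "data.frame")
  map <- observable_map("fret", F0 = 1, F1 = 0.86)
  expect_equal(observe(base, map)$signal, 1)
  bound <- base; bound$FRP_M <- 2e-8; bound$P_M <- 0
  expect_equal(observe(bound, map)$signal, 0.86)
  half <- base; half$FRP_M <- 1e-8; half$P_M <- 1e-8
  expect_equal(observe(half, map)$signal, 0.93)
  expect_error(observable_map("fret", F0 = 1, F1 = 1.2), "F1 < F0")

  # receptor channels are affine in the respective state populations
  prmap <- observable_map("pr_fluorescence", amplitude = 2, offset = 0.5)
  expect_equal(observe(base, prmap)$signal, 2.5)
  amap <- observable_map("a715", amplitude = 1, offset = 0.1)
  expect_equal(observe(bound, amap)$signal, 0.1 + 2e-8 / 1.02e-6)
})

test_that("protocol validation rejects malformed segment sets", {
  expect_error(light_segment(0, -1, "red658", 5), "duration")
  expect_error(light_segment(0, 1, "dark", 3), "intensity 0")
  expect_error(illumination_protocol(light_segment(0, 10, "red658", 5),
                                     light_segment(5, 10, "red658", 5)),
               "overlap")
})

test_that("photostationary Pfr ratio of free receptor is intensity-independent", {
  rc <- p6a_rates()
  comp <- system_composition(1e-6, 0)   # no PIF
  fr <- vapply(c(0.069, 0.69, 6.9, 69), function(I) {
    st <- solve_photostationary(rc, comp, I)
    st[["FR_M"]] / (st[["R_M"]] + st[["FR_M"]])
  }, numeric(1))
  expect_lt(max(abs(fr - fr[1])), 1e-6)
  expect_equal(fr[1], 0.73, tolerance = 1e-9)
})

test_that("Pr-state escape controls whether intensity response is monotone", {
  # thermal dark reversion (warm / extended-receptor regime) sets the
  # low-intensity rising flank; Pr-state escape sets the falling one
  comp <- standard_mix()
  grid <- 10^seq(-3, 2, length.out = 25)
  # no escape out of Pr: bound fraction non-decreasing in intensity
  rc0 <- rate_constants(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 0, k_aR = 0,
                        k_rec = 1e-3)
  bf0 <- vapply(grid, function(I) ss_bound_fraction(rc0, comp, I), numeric(1))
  expect_true(all(diff(bf0) > -1e-12))
  # with escape: single interior maximum (up then down)
  rc1 <- p6a_rates(k_rec = 1e-3)
  bf1 <- vapply(grid, function(I) ss_bound_fraction(rc1, comp, I), numeric(1))
  ipk <- which.max(bf1)
  expect_gt(ipk, 1); expect_lt(ipk, length(grid))
  expect_true(all(diff(bf1[1:ipk]) > 0))
  expect_true(all(diff(bf1[ipk:length(bf1)]) < 0))
})

test_that("speeding photoconversion at fixed ratio changes only the bound steady state", {
  rc <- p6a_rates()
  rc2 <- rate_constants(k_aFR = rc$k_aFR, k_dFR = rc$k_dFR, k_dR = rc$k_dR,
                        k_p_coeff = 2 * rc$k_p_coeff,
                        k_q_coeff = 2 * rc$k_q_coeff)
  # free receptor photoequilibrium unchanged
  nofif <- system_composition(1e-6, 0)
  expect_equal(solve_photostationary(rc, nofif, 10),
               solve_photostationary(rc2, nofif, 10), tolerance = 1e-9)
  # with PIF and k_dR > 0, the doubled cycling depletes the complex further
  comp <- standard_mix()
  expect_lt(ss_bound_fraction(rc2, comp, 10), ss_bound_fraction(rc, comp, 10))
})
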