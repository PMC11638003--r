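test_that("analytic steady state matches the ODE terminal state on random draws", {
  set.seed(101)
  for (i in 1:25) {
    d <- random_draw()
    st <- solve_photostationary(d$rc, d$comp, d$intensity)
    horizon <- equilibration_time(d$rc, d$comp, d$intensity)
    prot <- illumination_protocol(
      light_segment(0, horizon * 1.01, "red658", d$intensity))
    traj <- simulate_kinetics(d$rc, prot, d$comp, c(0, horizon))
    term <- unlist(traj[nrow(traj), -1]); names(term) <- names(st)
    scale <- max(d$comp$R0_total, d$comp$P0_total)
    expect_lt(max(abs(term - st)) / scale, 1e-5)
  }
})

test_that("fully photoactivated limit reduces to the single-site binding quadratic", {
  # k_q = 0, k_rec = 0, k_aR = 0: all receptor driven to Pfr, so the bound
  # complex is the root of the standard quadratic with K_d = k_dFR / k_aFR
  rc <- rate_constants(k_aFR = 6.1e5, k_dFR = 0.11, k_dR = 2.5,
                       k_q_coeff = 0)
  R0 <- 1e-6; P0 <- 2e-8
  st <- solve_photostationary(rc, system_composition(R0, P0), 69)
  Kd <- rc$k_dFR / rc$k_aFR
  b <- R0 + P0 + Kd
  complex_quad <- (b - sqrt(b^2 - 4 * R0 * P0)) / 2   # independent closed form
  expect_equal(st[["FRP_M"]], complex_quad, tolerance = 1e-9)
  expect_equal(st[["RP_M"]], 0, tolerance = 1e-15)
})

test_that("zero PIF reduces to the two-state photoequilibrium", {
  rc <- p6a_rates(k_rec = 0.05)
  st <- solve_photostationary(rc, system_composition(1e-6, 0), 10)
  kpq <- intensity_to_rates(data.frame(channel = "red658", intensity = 10), rc)
  phi <- kpq$k_p / (kpq$k_p + kpq$k_q + rc$k_rec)
  expect_equal(st[["FR_M"]] / 1e-6, phi, tolerance = 1e-12)
  expect_identical(st[["RP_M"]], 0)
  expect_identical(st[["FRP_M"]], 0)
})

test_that("quadratic (k_aR = 0) and near-degenerate cubic paths agree", {
  comp <- standard_mix()
  rc0 <- p6a_rates()                                    # k_aR = 0
  rc1 <- rate_constants(k_aFR = rc0$k_aFR, k_dFR = rc0$k_dFR,
                        k_dR = rc0$k_dR, k_aR = 1e-12 * rc0$k_aFR)
  for (I in c(0.05, 1, 30)) {
    s0 <- solve_photostationary(rc0, comp, I)
    s1 <- solve_photostationary(rc1, comp, I)
    expect_equal(s0, s1, tolerance = 1e-8)
  }
})

test_that("free-receptor Pfr:Pr ratio is invariant under intensity rescaling", {
  rc <- p6a_rates()
  comp <- system_composition(1e-6, 0)
  ratio <- vapply(c(1, 3.7, 12), function(cscale) {
    st <- solve_photostationary(rc, comp, 0.5 * cscale)
    st[["FR_M"]] / st[["R_M"]]
  }, numeric(1))
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-9)
  # with PIF present the invariance is only approximate: complex
  # dissociation feeds the free Pr pool, a contribution that dies off as
  # the photoconversion accelerates
  mix <- standard_mix()
  dev <- vapply(c(1, 10, 100), function(I) {
    st <- solve_photostationary(rc, mix, I)
    abs(st[["FR_M"]] / st[["R_M"]] - 0.73 / 0.27)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("dose-response curve shows rise, peak, attenuation, and high-light plateau", {
  # finite thermal reversion puts the rising flank inside the scanned window
  rc <- pif6_rates(k_rec = 1e-3)
  comp <- standard_mix()
  grid <- 10^seq(-4, 2.5, length.out = 60)
  dr <- dose_response(rc, comp, grid, attenuation_drop = 0.03)
  expect_true(all(dr$bound_fraction >= 0 & dr$bound_fraction <= 1))
  pk <- attr(dr, "peak_bound_fraction")
  ipk <- which.max(dr$bound_fraction)
  expect_gt(ipk, 1); expect_lt(ipk, nrow(dr))
  # attenuation develops in the mW cm^-2 regime, levelling off above ~10
  onset <- attr(dr, "attenuation_onset")
  expect_gt(onset, 0.1); expect_lt(onset, 10)
  top <- dr$bound_fraction[dr$intensity_mW_cm2 > 10]
  expect_lt(diff(range(top)) / pk, 0.08)

  # k_dR -> 0 removes the attenuation limb
  rc0 <- rate_constants(k_aFR = rc$k_aFR, k_dFR = rc$k_dFR, k_dR = 0,
                        k_rec = 1e-3)
  dr0 <- dose_response(rc0, comp, grid)
  expect_true(is.na(attr(dr0, "attenuation_onset")))
  expect_gt(min(dr0$bound_fraction[-seq_len(30)]),
            attr(dr0, "peak_bound_fraction") * 0.99)
})

test_that("slowing Pfr binding kinetics jointly shifts attenuation onset, not affinity", {
  rc <- pif6_rates(k_rec = 1e-3)
  comp <- standard_mix()
  grid <- 10^seq(-5, 2, length.out = 60)
  dr_ref <- dose_response(rc, comp, grid, attenuation_drop = 0.05)
  rc_slow <- rate_constants(k_aFR = rc$k_aFR / 10, k_dFR = rc$k_dFR / 10,
                            k_dR = rc$k_dR, k_rec = 1e-3)
  dr_slow <- dose_response(rc_slow, comp, grid, attenuation_drop = 0.05)
  expect_equal(rc_slow$k_dFR / rc_slow$k_aFR, rc$k_dFR / rc$k_aFR)  # K_d fixed
  expect_lt(attr(dr_slow, "attenuation_onset"), attr(dr_ref, "attenuation_onset"))
})

test_that("scan panels reproduce the family behaviours", {
  rc <- pif6_rates(k_rec = 1e-3)
  comp <- standard_mix()
  grid <- 10^seq(-4, 2, length.out = 30)

  # receptor abundance: bound fraction monotone increasing at every intensity
  fam <- scan_panel(rc, comp, "R0_total", c(0.1, 0.3, 1, 3, 10), grid)
  bf <- sapply(fam, function(d) d$bound_fraction)
  expect_true(all(apply(bf, 1, function(r) all(diff(r) > -1e-12))))

  # pure forward driving (k_q = 0): monotone non-decreasing, no attenuation
  pure <- scan_panel(rc, comp, "kp_kq_ratio", Inf, grid)[[1]]
  expect_true(all(diff(pure$bound_fraction) > -1e-12))
  expect_true(is.na(attr(pure, "attenuation_onset")))

  # identity scan reproduces the reference curve exactly
  ident <- scan_panel(rc, comp, "k_dR", 1, grid)[[1]]
  ref <- dose_response(rc, comp, grid)
  expect_identical(ident$bound_fraction, ref$bound_fraction)

  expect_error(scan_panel(rc, comp, "k_p_alone", 1, grid), "unknown scan dimension")
})
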