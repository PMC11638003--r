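# Shared fixtures built in code.

p6a_rates <- function(...) {
  p <- pif_preset("P6A")
  rate_constants(k_aFR = p$k_aFR, k_dFR = p$k_dFR, k_dR = p$k_dR, ...)
}

pif6_rates <- function(...) {
  p <- pif_preset("PIF6")
  rate_constants(k_aFR = p$k_aFR, k_dFR = p$k_dFR, k_dR = p$k_dR, ...)
}

standard_mix <- function() system_composition(1e-6, 2e-8)

# steady-state bound fraction of the PIF pool
ss_bound_fraction <- function(rc, comp, intensity) {
  st <- solve_photostationary(rc, comp, intensity)
  (st[["RP_M"]] + st[["FRP_M"]]) / comp$P0_total
}

# random physically plausible parameter/composition draw (log-uniform)
random_draw <- function() {
  lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  list(rc = rate_constants(
         k_aFR = lu(1e4, 1e6), k_dFR = lu(0.02, 1), k_dR = lu(0.05, 5),
         k_aR = sample(c(0, lu(1e3, 1e5)), 1),
         k_p_coeff = lu(0.01, 0.3), k_q_coeff = lu(0.01, 0.3)),
       comp = system_composition(lu(1e-7, 5e-6), lu(5e-9, 1e-7)),
       intensity = lu(0.01, 100))
}

withr_like_tempdir <- function() {
  d <- tempfile("phypif-test-")
  dir.create(d)
  d
}

# slowest relaxation scale -> generous equilibration horizon for ODE oracle
equilibration_time <- function(rc, comp, intensity) {
  kpq <- intensity_to_rates(
    data.frame(channel = "red658", intensity = intensity), rc)
  rates <- c(kpq$k_p + kpq$k_q + rc$k_rec, rc$k_dR, rc$k_dFR,
             rc$k_aFR * comp$R0_total)
  60 / min(rates[rates > 0])
}
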