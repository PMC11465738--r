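# Stopped-flow kinetics: rates, the Q buffering factor, and MM fitting.

test_that("post-mixing concentrations follow the mixing ratio", {
  expect_equal(reaction_concentration(34e-3), 17e-3)
  expect_equal(reaction_concentration(6.8e-3), 3.4e-3)
  expect_equal(reaction_concentration(5e-3, c(1, 0)), 5e-3)
  expect_equal(reaction_concentration(9e-3, c(1, 2)), 3e-3)
})

test_that("initial rate recovers exact slopes and flags short windows", {
  t <- seq(0, 30, by = 0.5)
  lin <- data.frame(time = t, absorbance = 1 - 0.01 * t)
  r <- initial_rate(lin, c(10, 20))
  expect_equal(r$dA_dt, -0.01)
  expect_equal(r$r_squared, 1)
  flat <- data.frame(time = t, absorbance = rep(0.7, length(t)))
  expect_equal(initial_rate(flat, c(10, 20))$dA_dt, 0)
  expect_error(initial_rate(lin, c(0, 0.6)), "fewer than 3")
  expect_error(initial_rate(lin, c(20, 40)), "outside")
})

test_that("measured slope matches the analytic derivative of a noiseless trace", {
  sp <- trace_spec(enzyme_conc = 0, co2_init = 3.4e-3, noise_sd = 0, dt = 0.05, duration = 25)
  tr <- make_stopped_flow_trace(sp)
  tru <- attr(tr, "truth")
  w <- c(10, 12)
  slope <- initial_rate(tr, w)$dA_dt
  # finite-difference derivative of the clean absorbance at the window midpoint
  mid <- mean(w)
  i <- which.min(abs(tru$time - mid))
  fd <- (tru$absorbance_clean[i + 1] - tru$absorbance_clean[i - 1]) /
    (tru$time[i + 1] - tru$time[i - 1])
  expect_equal(slope, fd, tolerance = 0.02)
})

test_that("net rate subtracts the uncatalyzed slope and flags inversions", {
  expect_equal(net_rate(-0.03, -0.01)$net_dA_dt, -0.02)
  expect_equal(net_rate(-0.02, -0.02)$net_dA_dt, 0)
  expect_warning(out <- net_rate(-0.01, -0.03), "uncatalyzed")
  expect_true(out$suspect)
  expect_equal(out$net_dA_dt, 0.02)
})

test_that("Q factor has the closed-form indicator-only limit and grows with buffer", {
  # indicator-only system held at its pKa: Q = indicator_total / epsilon_path
  cond <- assay_conditions(
    buffer_total = 0, indicator_total = 2e-4,
    indicator_pKa = 7.9, pH_init = 7.9, epsilon_path = 0.8
  )
  expect_equal(buffer_factor(cond), 2e-4 / 0.8)
  c1 <- assay_conditions(buffer_total = 10e-3)
  c2 <- assay_conditions(buffer_total = 20e-3)
  expect_gt(buffer_factor(c2), buffer_factor(c1))
  expect_error(buffer_factor(assay_conditions(epsilon_path = 0)), "optics")
  # Q does not depend on enzyme concentration anywhere in its inputs
  expect_equal(buffer_factor(c1), buffer_factor(c1))
})

test_that("Q converts early absorbance slopes back to the generator's CO2 rate", {
  cond <- assay_conditions()
  for (S0 in c(3.4e-3, 17e-3)) {
    sp <- trace_spec(enzyme_conc = 0, co2_init = S0, noise_sd = 0, dt = 0.1, duration = 30)
    tr <- make_stopped_flow_trace(sp)
    tru <- attr(tr, "truth")
    est <- co2_rate(initial_rate(tr, c(0, 5))$dA_dt, buffer_factor(cond))
    true_rate <- abs(stats::approx(tru$time, tru$dS_dt, xout = 2.5)$y)
    expect_equal(est, true_rate, tolerance = 0.05)
  }
})

test_that("co2_rate is linear in both arguments", {
  expect_equal(co2_rate(0.01, 2e-3), 2e-5)
  expect_equal(co2_rate(0, 5), 0)
  expect_equal(co2_rate(0.02, 2e-3), 2 * co2_rate(0.01, 2e-3))
  expect_equal(co2_rate(0.01, 4e-3), 2 * co2_rate(0.01, 2e-3))
})

test_that("MM fit recovers noiseless parameters to 0.1% and is order/unit invariant", {
  S <- c(3.4, 6.8, 10.2, 13.6, 17) * 1e-3
  E <- 350e-9
  v <- 1.2e3 * E * S / (4.9e-3 + S)
  fit <- fit_mm(S, v, E)
  expect_equal(fit$kcat, 1.2e3, tolerance = 1e-3)
  expect_equal(fit$KM, 4.9e-3, tolerance = 1e-3)
  expect_equal(fit$Vmax, fit$kcat * E, tolerance = 1e-9)
  expect_equal(fit$kcat_over_KM, fit$kcat / fit$KM, tolerance = 1e-12)
  # reordering the data points changes nothing
  ord <- c(3, 1, 5, 2, 4)
  fit2 <- fit_mm(S[ord], v[ord], E)
  expect_equal(fit2$KM, fit$KM, tolerance = 1e-9)
  # substrate rescaling mM <-> M rescales KM accordingly
  fit_mM <- fit_mm(S * 1e3, v, E)
  expect_equal(fit_mM$KM, fit$KM * 1e3, tolerance = 1e-6)
  expect_equal(fit_mM$Vmax, fit$Vmax, tolerance = 1e-6)
  # fitted curve passes through Vmax/2 at S = KM
  expect_equal(fit$Vmax * fit$KM / (fit$KM + fit$KM), fit$Vmax / 2)
})

test_that("saturating designs leave KM poorly determined", {
  set.seed(2)
  S <- c(0.5, 1, 1.5, 2) # all >> KM = 4.9 mM
  v <- 1.2e3 * 350e-9 * S / (4.9e-3 + S) * (1 + rnorm(4, 0, 0.01))
  fit <- fit_mm(S, v, 350e-9)
  expect_equal(fit$Vmax, mean(v), tolerance = 0.05)
  expect_gt(fit$se[["KM"]] / fit$KM, 0.25) # relative SE blows up
})

test_that("full trace pipeline recovers Table-style kinetic constants from noiseless traces", {
  cond <- assay_conditions()
  S_mix <- c(3.4, 6.8, 10.2, 13.6, 17) * 1e-3
  rates <- vapply(S_mix, function(S0) {
    cat_tr <- make_stopped_flow_trace(
      trace_spec(co2_init = S0, noise_sd = 0, dt = 0.02, duration = 2)
    )
    unc_tr <- make_stopped_flow_trace(
      trace_spec(co2_init = S0, noise_sd = 0, dt = 0.02, duration = 2, enzyme_conc = 0)
    )
    trace_to_rate(cat_tr, unc_tr, cond, window = c(0, 0.4))$rate
  }, numeric(1))
  fit <- fit_mm(S_mix, rates, 350e-9)
  expect_equal(fit$kcat, 1.2e3, tolerance = 0.10)
  expect_equal(fit$KM, 4.9e-3, tolerance = 0.10)
})

test_that("catalytic efficiency and unit conversions match standard reporting", {
  expect_equal(efficiency(1.2e3, 4.9e-3), 2.4e5)
  expect_equal(efficiency(1.6e6, 9.9e-3), 1.6e8)
  expect_equal(efficiency(1, 1), 1)
  expect_equal(molar_to_mass(340e-9, 19000, "ug_per_ml"), 6.46, tolerance = 1e-3)
  expect_equal(signif_report(molar_to_mass(340e-9, 19000, "ug_per_ml")), 6.5)
  expect_equal(signif_report(molar_to_mass(36.8e-6, 19000, "mg_per_ml"), 1), 0.7)
  expect_equal(molar_to_mass(0, 19000), 0)
})
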