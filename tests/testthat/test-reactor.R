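# Ideal-gas mass balance, absorption metrics, and the forward simulator.

cfg90 <- reactor_config(temperature = 363.15)

test_that("gas inventory follows the ideal-gas headspace calculation", {
  # 0.2 * 7e5 Pa * 1e-4 m^3 / (R * T)
  expect_equal(gas_inventory(cfg90)$n_co2,
    0.2 * 7e5 * 1e-4 / (8.314462618 * 363.15),
    tolerance = 1e-12
  )
  expect_equal(gas_inventory(cfg90)$n_co2, 4.64e-3, tolerance = 1e-3)
  cfg20 <- reactor_config(temperature = 293.15)
  expect_equal(gas_inventory(cfg20)$n_co2, 5.74e-3, tolerance = 1e-3)
  expect_equal(gas_inventory(cfg90)$n_n2, 4 * gas_inventory(cfg90)$n_co2)
})

test_that("absorbed CO2 tracks the pressure drop and clips at the inventory", {
  t <- seq(0, 210, by = 5)
  const <- data.frame(time = t, pressure = rep(7e5, length(t)))
  expect_equal(absorbed_from_pressure(const, cfg90)$absorbed, rep(0, length(t)))
  # full CO2 partial-pressure drop of 1.4 bar -> inventory / 0.050 L
  drop <- data.frame(
    time = c(0, 30, 210),
    pressure = c(7e5, 6.3e5, 5.6e5)
  )
  ab <- absorbed_from_pressure(drop, cfg90)
  expect_equal(ab$absorbed[3], 92.7, tolerance = 1e-3)
  expect_equal(ab$absorbed_mol[3], gas_inventory(cfg90)$n_co2, tolerance = 1e-12)
  # a drop beyond the CO2 partial pressure is clipped with a warning
  over <- data.frame(time = c(0, 30, 210), pressure = c(7e5, 6e5, 5.4e5))
  expect_warning(ab2 <- absorbed_from_pressure(over, cfg90), "inventory")
  expect_equal(max(ab2$absorbed_mol), gas_inventory(cfg90)$n_co2)
  # transient pressure above P0 is flagged, not fatal
  wob <- data.frame(time = c(0, 5, 10, 30), pressure = c(7e5, 7.005e5, 6.9e5, 6.8e5))
  expect_warning(absorbed_from_pressure(wob, cfg90), "above initial")
})

test_that("initial absorption rate recovers exact slopes", {
  t <- seq(0, 210, by = 5)
  a <- pmin(5 * t, 90) # 5 mmol/(L min) up to 90 mmol/L
  r <- initial_absorption_rate(data.frame(time = t, absorbed = a), window = c(0, 15))
  expect_equal(r$rate, 5)
  flat <- data.frame(time = t, absorbed = rep(0, length(t)))
  expect_equal(initial_absorption_rate(flat)$rate, 0)
  expect_error(
    initial_absorption_rate(data.frame(time = c(0, 10), absorbed = c(0, 1)),
      window = c(0, 10)
    ),
    "fewer than 3"
  )
})

test_that("plateau detection and productivity match the piecewise-linear construction", {
  t <- seq(0, 210, by = 5)
  fast <- data.frame(time = t, absorbed = pmin(90 * t / 60, 90))
  p1 <- plateau_and_productivity(fast)
  expect_equal(p1$plateau_time, 60)
  expect_equal(p1$productivity, 1.5)
  expect_false(p1$no_plateau)
  slow <- data.frame(time = t, absorbed = pmin(90 * t / 120, 90))
  p2 <- plateau_and_productivity(slow)
  expect_equal(p2$plateau_time, 120)
  expect_equal(p2$productivity, 0.75)
  expect_equal(p2$productivity, p1$productivity / 2)
  rising <- data.frame(time = t, absorbed = 0.4 * t)
  p3 <- plateau_and_productivity(rising)
  expect_true(p3$no_plateau)
  expect_equal(p3$plateau_time, max(t))
})

test_that("removal efficiency is the absorbed share of the CO2 inventory", {
  inv <- gas_inventory(cfg90)$n_co2
  expect_equal(removal_efficiency(inv, cfg90), 100)
  expect_equal(removal_efficiency(0.9 * inv, cfg90), 90)
  expect_equal(removal_efficiency(0, cfg90), 0)
  expect_warning(removal_efficiency(1.01 * inv, cfg90), "capping")
})

test_that("simulator matches the analytic exponential solution to 1e-6 relative", {
  pp <- forward_params(kla = 0.05, enhancement = 2, equilibrium_pressure = 0.02e5)
  t <- seq(0, 210, by = 1)
  ser <- simulate_pressure(cfg90, pp, t)
  analytic <- pp$equilibrium_pressure +
    (cfg90$co2_fraction * cfg90$initial_pressure - pp$equilibrium_pressure) *
      exp(-pp$kla * pp$enhancement * t)
  expect_lt(max(abs(ser$p_co2 - analytic) / analytic), 1e-6)
  expect_true(all(diff(ser$pressure) <= 0))
  # kla = 0 -> constant pressure
  flat <- simulate_pressure(cfg90, forward_params(0), t)
  expect_equal(flat$pressure, rep(7e5, length(t)))
  # doubling the enhancement halves the time to any fractional approach
  s1 <- simulate_pressure(cfg90, forward_params(0.05, 1, 0), seq(0, 100, 0.1))
  s2 <- simulate_pressure(cfg90, forward_params(0.05, 2, 0), seq(0, 100, 0.1))
  target <- 0.5 * (max(s1$p_co2) + min(s1$p_co2))
  t_half1 <- s1$time[which(s1$p_co2 <= target)[1]]
  t_half2 <- s2$time[which(s2$p_co2 <= target)[1]]
  expect_equal(t_half1 / t_half2, 2, tolerance = 0.01)
  expect_error(forward_params(-1), "kla")
})

test_that("mole conservation holds at every step of the metrics pipeline", {
  pp <- forward_params(kla = 0.04, enhancement = 1.5, equilibrium_pressure = 0.01e5)
  ser <- simulate_pressure(cfg90, pp, seq(0, 210, by = 2))
  ab <- absorbed_from_pressure(ser, cfg90)
  vh <- (cfg90$total_volume - cfg90$liquid_volume) / 1e3
  gas_co2 <- ser$p_co2 * vh / (8.314462618 * cfg90$temperature)
  expect_lt(
    max(abs(ab$absorbed_mol + gas_co2 - gas_inventory(cfg90)$n_co2)), 1e-9
  )
})

test_that("metrics round-trip recovers configured rate ratios and equilibrium removal", {
  g <- seq(0, 210, by = 0.25)
  m2 <- reactor_metrics(
    simulate_pressure(cfg90, forward_params(0.02, 2, 0), g), cfg90,
    rate_window = c(0, 1)
  )
  m1 <- reactor_metrics(
    simulate_pressure(cfg90, forward_params(0.02, 1, 0), g), cfg90,
    rate_window = c(0, 1)
  )
  expect_equal(m2$initial_rate / m1$initial_rate, 2, tolerance = 0.02)
  # equilibrium at P_eq = 10% of initial CO2 partial pressure -> 90% removal
  peq <- 0.1 * cfg90$co2_fraction * cfg90$initial_pressure
  m3 <- reactor_metrics(
    simulate_pressure(cfg90, forward_params(0.2, 1, peq), g), cfg90
  )
  expect_equal(m3$removal_efficiency, 90, tolerance = 0.02)
  # the enzyme-promoted run reaches its plateau earlier
  expect_lt(m2$plateau_time, m1$plateau_time)
})
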