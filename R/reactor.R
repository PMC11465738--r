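# Pressurized batch-reactor CO2 absorption: ideal-gas mass balance from the
# recorded pressure drop, the derived performance metrics (initial absorption
# rate, productivity to plateau, removal efficiency), and a pseudo-first-order
# forward simulator used to validate the inverse metrics.

R_GAS <- 8.314462618 # J/(mol K)

#' Batch-reactor configuration
#'
#' Geometry and starting state of the closed absorption vessel.  Defaults
#' describe a 150 mL vessel with 50 mL of solvent, pressurized to 7 bar
#' (absolute) with a 20:80 v/v CO2:N2 mixture.
#'
#' @param total_volume vessel volume, L.
#' @param liquid_volume solvent volume, L (< `total_volume`).
#' @param temperature K (> 273).
#' @param initial_pressure absolute pressure at t = 0, Pa.
#' @param co2_fraction CO2 mole fraction of the feed gas, in (0, 1].
#' @return List of class `"reactor_config"`.
#' @export
reactor_config <- function(total_volume = 0.150, liquid_volume = 0.050,
                           temperature = 363.15, initial_pressure = 7e5,
                           co2_fraction = 0.20) {
  stopifnot(
    liquid_volume > 0, liquid_volume < total_volume,
    temperature > 273, initial_pressure > 0,
    co2_fraction > 0, co2_fraction <= 1
  )
  structure(
    list(
      total_volume = total_volume, liquid_volume = liquid_volume,
      temperature = temperature, initial_pressure = initial_pressure,
      co2_fraction = co2_fraction
    ),
    class = "reactor_config"
  )
}

headspace_m3 <- function(config) (config$total_volume - config$liquid_volume) / 1e3

#' Initial gas inventory of the headspace
#'
#' Ideal-gas moles of CO2 and N2 in the headspace at the initial pressure.
#'
#' @param config a [reactor_config()].
#' @return List with `n_co2` and `n_n2`, mol.
#' @export
#' @examples
#' gas_inventory(reactor_config(temperature = 363.15))$n_co2 # ~4.64e-3 mol
gas_inventory <- function(config) {
  n_total <- config$initial_pressure * headspace_m3(config) /
    (R_GAS * config$temperature)
  list(
    n_co2 = config$co2_fraction * n_total,
    n_n2 = (1 - config$co2_fraction) * n_total
  )
}

#' Absorbed CO2 from a pressure series
#'
#' Converts the total-pressure drop to absorbed CO2 by the ideal-gas mass
#' balance, assuming only CO2 leaves the gas phase:
#' \deqn{n_{abs}(t) = (P_0 - P(t)) V_h / (R T)}
#' expressed per litre of solvent.  Pressures transiently above the initial
#' pressure (thermal fluctuation) are flagged with a warning and clipped to
#' zero absorption; absorption beyond the CO2 inventory is clipped with a
#' warning.
#'
#' @param series data frame with columns `time` (min, ascending) and
#'   `pressure` (Pa absolute); must start near the configured initial
#'   pressure.
#' @param config a [reactor_config()].
#' @return Data frame with columns `time` (min), `absorbed` (mmol CO2 per L
#'   of solvent) and `absorbed_mol` (mol).
#' @export
absorbed_from_pressure <- function(series, config) {
  stopifnot(all(c("time", "pressure") %in% names(series)))
  P0 <- config$initial_pressure
  if (abs(series$pressure[1] - P0) > 0.02 * P0) {
    stop_invalid("pressure series does not start at the configured initial pressure")
  }
  n_abs <- (P0 - series$pressure) * headspace_m3(config) /
    (R_GAS * config$temperature)
  if (any(n_abs < -1e-12)) {
    warning("pressure above initial value mid-series; clipping to zero absorption",
      call. = FALSE
    )
  }
  n_abs <- pmax(n_abs, 0)
  inv <- gas_inventory(config)$n_co2
  if (any(n_abs > inv + 1e-12)) {
    warning("apparent absorption exceeds the CO2 inventory; clipping",
      call. = FALSE
    )
    n_abs <- pmin(n_abs, inv)
  }
  data.frame(
    time = series$time,
    absorbed = 1e3 * n_abs / config$liquid_volume,
    absorbed_mol = n_abs
  )
}

#' Initial CO2 absorption rate
#'
#' Least-squares slope of absorbed CO2 versus time over the initial linear
#' segment.  By default the window runs from t = 0 until absorption first
#' exceeds 20% of its final value, capped at 15 min.
#'
#' @param absorbed data frame from [absorbed_from_pressure()] (columns
#'   `time`, `absorbed`).
#' @param window optional `c(t_start, t_end)` in min overriding the default
#'   rule.
#' @return List with `rate` (mmol/(L min)), `window` and `r_squared`.
#' @export
initial_absorption_rate <- function(absorbed, window = NULL) {
  stopifnot(all(c("time", "absorbed") %in% names(absorbed)))
  if (is.null(window)) {
    final <- absorbed$absorbed[nrow(absorbed)]
    past <- absorbed$time[absorbed$absorbed > 0.2 * final & absorbed$absorbed > 0]
    t_end <- min(c(past, 15, max(absorbed$time)))
    window <- c(0, max(t_end, absorbed$time[3])) # ensure >= 3 points
  }
  sel <- absorbed$time >= window[1] & absorbed$time <= window[2]
  if (sum(sel) < 3L) stop_invalid("fewer than 3 points in the initial-rate window")
  fit <- lm(absorbed ~ time, data = absorbed[sel, , drop = FALSE])
  ss <- suppressWarnings(summary(fit)) # exact linear data triggers a benign warning
  list(
    rate = unname(coef(fit)[2]), window = window,
    r_squared = if (is.nan(ss$r.squared)) 1 else ss$r.squared
  )
}

#' Plateau time and productivity
#'
#' The plateau is the earliest time from which the rolling 3-point slope of
#' the absorption curve stays below 2% of the initial absorption rate for
#' the remainder of the run.  Productivity is total absorbed CO2 at the
#' plateau divided by the plateau time (mmol/(L min)).  If no plateau is
#' found the series end is used and flagged.
#'
#' @inheritParams initial_absorption_rate
#' @return List with `plateau_time` (min), `productivity` (mmol/(L min)),
#'   `absorbed_at_plateau` (mmol/L) and logical `no_plateau`.
#' @export
plateau_and_productivity <- function(absorbed) {
  stopifnot(nrow(absorbed) >= 4, max(absorbed$time) >= 30)
  t <- absorbed$time
  a <- absorbed$absorbed
  n <- length(t)
  r0 <- initial_absorption_rate(absorbed)$rate
  # forward-looking 3-point slopes: slope[i] over points i..i+2
  slopes <- vapply(seq_len(n - 2L), function(i) {
    unname(coef(lm(a[i:(i + 2L)] ~ t[i:(i + 2L)]))[2])
  }, numeric(1))
  thr <- 0.02 * abs(r0)
  below <- abs(slopes) < thr
  ok_from <- rev(cumprod(rev(below))) == 1
  idx <- which(ok_from)
  if (abs(r0) <= 0 || length(idx) == 0L) {
    pt <- t[n]
    no_plateau <- TRUE
  } else {
    pt <- t[idx[1]]
    no_plateau <- FALSE
  }
  if (pt <= 0) pt <- t[2]
  a_pt <- stats::approx(t, a, xout = pt)$y
  list(
    plateau_time = pt, productivity = a_pt / pt,
    absorbed_at_plateau = a_pt, no_plateau = no_plateau
  )
}

#' CO2 removal efficiency
#'
#' Percentage of the initial gas-phase CO2 inventory absorbed by the
#' solvent.
#'
#' @param total_absorbed absorbed CO2, mol (>= 0).
#' @param config a [reactor_config()].
#' @return Percentage in `[0, 100]` (capped with a warning).
#' @export
removal_efficiency <- function(total_absorbed, config) {
  stopifnot(total_absorbed >= 0)
  out <- 100 * total_absorbed / gas_inventory(config)$n_co2
  if (out > 100 + 1e-9) {
    warning("absorbed CO2 exceeds inventory; capping removal efficiency at 100%",
      call. = FALSE
    )
  }
  min(out, 100)
}

#' Forward-model parameters for the absorption simulator
#'
#' Pseudo-first-order approach of the CO2 partial pressure to a fixed
#' equilibrium value, with the enzymatic rate promotion expressed as a
#' multiplicative enhancement of the volumetric mass-transfer coefficient.
#'
#' @param kla volumetric mass-transfer coefficient, 1/min (>= 0).
#' @param enhancement dimensionless factor >= 1 (1 = non-enzymatic).
#' @param equilibrium_pressure CO2 partial pressure at solvent saturation,
#'   Pa (>= 0).
#' @return List of class `"forward_params"`.
#' @export
forward_params <- function(kla, enhancement = 1, equilibrium_pressure = 0) {
  if (kla < 0 || enhancement < 1 || equilibrium_pressure < 0) {
    stop_invalid("forward parameters must satisfy kla >= 0, enhancement >= 1, equilibrium_pressure >= 0")
  }
  structure(
    list(
      kla = kla, enhancement = enhancement,
      equilibrium_pressure = equilibrium_pressure
    ),
    class = "forward_params"
  )
}

#' Simulate the reactor pressure series
#'
#' Integrates \eqn{dP_{CO2}/dt = -k_La E (P_{CO2} - P_{eq})} with N2 inert,
#' so the total pressure is \eqn{P_{CO2}(t) + P_{N2}}.  The noiseless curve
#' is monotone non-increasing and approaches \eqn{P_{N2} + P_{eq}}.
#'
#' @param config a [reactor_config()].
#' @param params a [forward_params()].
#' @param t_grid times in min, sorted, starting at 0.
#' @return Data frame of class `"pressure_series"` with columns `time`
#'   (min), `pressure` (Pa, total) and `p_co2` (Pa, CO2 partial pressure).
#' @export
simulate_pressure <- function(config, params, t_grid) {
  stopifnot(
    inherits(params, "forward_params"),
    !is.unsorted(t_grid), t_grid[1] == 0
  )
  p_co2_0 <- config$co2_fraction * config$initial_pressure
  p_n2 <- (1 - config$co2_fraction) * config$initial_pressure
  k <- params$kla * params$enhancement
  if (k == 0) {
    p_co2 <- rep(p_co2_0, length(t_grid))
  } else {
    sol <- deSolve::ode(
      y = c(P = p_co2_0), times = t_grid,
      func = function(t, y, parms) {
        list(-k * (y[1] - params$equilibrium_pressure))
      },
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-6
    )
    p_co2 <- sol[, "P"]
  }
  out <- data.frame(time = t_grid, pressure = p_co2 + p_n2, p_co2 = p_co2)
  class(out) <- c("pressure_series", "data.frame")
  out
}

#' All performance metrics for one reactor run
#'
#' Converts a pressure series to absorbed CO2 and computes the initial
#' absorption rate, plateau time, productivity, removal efficiency (from the
#' final absorbed amount) and total absorbed CO2.
#'
#' @param series pressure series (columns `time` min, `pressure` Pa).
#' @param config a [reactor_config()].
#' @param rate_window optional initial-rate window override, min.
#' @return List of class `"absorption_metrics"`.
#' @export
reactor_metrics <- function(series, config, rate_window = NULL) {
  ab <- absorbed_from_pressure(series, config)
  ir <- initial_absorption_rate(ab, rate_window)
  pl <- plateau_and_productivity(ab)
  total_mol <- ab$absorbed_mol[nrow(ab)]
  structure(
    list(
      initial_rate = ir$rate, rate_window = ir$window,
      plateau_time = pl$plateau_time, productivity = pl$productivity,
      removal_efficiency = removal_efficiency(total_mol, config),
      total_absorbed = ab$absorbed[nrow(ab)],
      no_plateau = pl$no_plateau, absorbed = ab
    ),
    class = "absorption_metrics"
  )
}

#' @export
print.absorption_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Batch absorption metrics\n",
      "  initial rate       = %.3g mmol/(L min) over [%g, %g] min\n",
      "  plateau time       = %.3g min%s\n",
      "  productivity       = %.3g mmol/(L min)\n",
      "  removal efficiency = %.1f %%\n",
      "  total absorbed     = %.3g mmol/L\n"
    ),
    x$initial_rate, x$rate_window[1], x$rate_window[2], x$plateau_time,
    if (x$no_plateau) " (no plateau reached)" else "",
    x$productivity, x$removal_efficiency, x$total_absorbed
  ))
  invisible(x)
}
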