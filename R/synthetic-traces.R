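# Seeded generators for instrument-like data: stopped-flow absorbance
# traces from a forward model of the indicator assay, residual-activity
# decay series, and reactor pressure curves.

#' Specification of a synthetic stopped-flow trace
#'
#' Reaction-cell (post-mixing) parameters of the forward model.  Defaults
#' describe the CO2-hydration assay: 17 mM CO2, an uncatalyzed rate
#' constant of 3.5e-2 1/s, 10 mM Tris (pKa 8.07) with 0.1 mM phenol red
#' (pKa 7.9) starting at pH 8.3, read as the deprotonated-indicator
#' absorbance at a single wavelength.
#'
#' @param kcat,KM,enzyme_conc Michaelis-Menten parameters of the catalyzed
#'   path (1/s, mol/L, mol/L); `enzyme_conc = 0` disables catalysis.
#' @param co2_init initial CO2 in the cell, mol/L.
#' @param k_uncat uncatalyzed first-order hydration constant, 1/s.
#' @param buffer_total,buffer_pKa,indicator_total,indicator_pKa,epsilon_path,pH_init
#'   optical/buffering parameters as in [assay_conditions()].
#' @param noise_sd additive Gaussian noise on absorbance (A.U.).
#' @param seed integer seed for the noise.
#' @param dt,duration sampling interval and trace length, s.
#' @return List of class `"trace_spec"`.
#' @export
trace_spec <- function(kcat = 1.2e3, KM = 4.9e-3, enzyme_conc = 350e-9,
                       co2_init = 17e-3, k_uncat = 3.5e-2,
                       buffer_total = 10e-3, buffer_pKa = 8.07,
                       indicator_total = 0.1e-3, indicator_pKa = 7.9,
                       epsilon_path = 1.0, pH_init = 8.3,
                       noise_sd = 0.002, seed = 1, dt = 0.1, duration = 60) {
  stopifnot(
    kcat >= 0, KM > 0, enzyme_conc >= 0, co2_init >= 0, k_uncat >= 0,
    buffer_total >= 0, indicator_total >= 0, noise_sd >= 0,
    dt > 0, duration > 0, pH_init > 6, pH_init < 10
  )
  structure(
    list(
      kcat = kcat, KM = KM, enzyme_conc = enzyme_conc, co2_init = co2_init,
      k_uncat = k_uncat, buffer_total = buffer_total, buffer_pKa = buffer_pKa,
      indicator_total = indicator_total, indicator_pKa = indicator_pKa,
      epsilon_path = epsilon_path, pH_init = pH_init, noise_sd = noise_sd,
      seed = seed, dt = dt, duration = duration
    ),
    class = "trace_spec"
  )
}

#' Simulate a stopped-flow absorbance trace
#'
#' Integrates the CO2 consumption
#' \deqn{dS/dt = -(k_{uncat} + k_{cat} E / (K_M + S)) S,}
#' accumulates the released protons into the buffer and indicator
#' protonation equilibria (Henderson-Hasselbalch for both species, plus the
#' free-proton term), and maps the deprotonated-indicator fraction to
#' absorbance through `epsilon_path`.  Gaussian noise of sd `noise_sd` is
#' added per point; the noiseless component is independent of the seed.
#'
#' @param spec a [trace_spec()].
#' @return Data frame with columns `time` (s) and `absorbance`, carrying the
#'   noiseless ground truth (`time`, `co2`, `pH`, `absorbance_clean`,
#'   `dS_dt`) as attribute `"truth"`.
#' @export
make_stopped_flow_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  times <- seq(0, spec$duration, by = spec$dt)
  rate_const <- function(S) {
    spec$k_uncat + spec$kcat * spec$enzyme_conc / (spec$KM + S)
  }
  sol <- deSolve::ode(
    y = c(S = spec$co2_init), times = times,
    func = function(t, y, p) list(-rate_const(y[1]) * y[1]),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  S <- pmax(sol[, "S"], 0)
  released <- spec$co2_init - S # mol/L H+ released

  fB0 <- protonated_fraction(spec$pH_init, spec$buffer_pKa)
  fI0 <- protonated_fraction(spec$pH_init, spec$indicator_pKa)
  consumed <- function(pH) {
    spec$buffer_total * (protonated_fraction(pH, spec$buffer_pKa) - fB0) +
      spec$indicator_total * (protonated_fraction(pH, spec$indicator_pKa) - fI0) +
      (10^(-pH) - 10^(-spec$pH_init))
  }
  pH <- vapply(released, function(h) {
    if (h <= 0) {
      return(spec$pH_init)
    }
    uniroot(function(p) consumed(p) - h,
      lower = 0.5, upper = spec$pH_init,
      tol = 1e-12
    )$root
  }, numeric(1))

  clean <- spec$epsilon_path *
    (1 - protonated_fraction(pH, spec$indicator_pKa))
  noisy <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, clean + rnorm(length(clean), 0, spec$noise_sd))
  } else {
    clean
  }
  out <- data.frame(time = times, absorbance = noisy)
  attr(out, "truth") <- data.frame(
    time = times, co2 = S, pH = pH, absorbance_clean = clean,
    dS_dt = -rate_const(S) * S
  )
  out
}

#' Generate a residual-activity decay series
#'
#' First-order decay `residual(t) = 100 * 2^(-t / half_life)`, optionally
#' modulated by a transient activation bump peaking at the second timepoint
#' (multiplier `1 + activation_bump * (t/t2) * exp(1 - t/t2)`, which is 1 at
#' t = 0), plus additive Gaussian noise in percentage points.
#'
#' @param half_life true half-life, h (> 0).
#' @param timepoints sampling times, h, non-negative and sorted.
#' @param activation_bump relative height of the transient activation peak
#'   (0 = none).
#' @param noise_sd Gaussian noise sd, percentage points.
#' @param seed integer seed.
#' @return Data frame with columns `time_h` and `residual_pct`.
#' @export
#' @examples
#' make_decay_series(24, c(0, 24), 0, 0, 1)$residual_pct # 100 50
make_decay_series <- function(half_life, timepoints, activation_bump = 0,
                              noise_sd = 0, seed = 1) {
  if (half_life <= 0) stop_invalid("half_life must be positive")
  stopifnot(
    all(timepoints >= 0), !is.unsorted(timepoints),
    activation_bump >= 0, noise_sd >= 0
  )
  res <- 100 * 2^(-timepoints / half_life)
  if (activation_bump > 0 && length(timepoints) >= 2 && timepoints[2] > 0) {
    t2 <- timepoints[2]
    res <- res * (1 + activation_bump * (timepoints / t2) * exp(1 - timepoints / t2))
  }
  if (noise_sd > 0) {
    res <- with_seed(seed, res + rnorm(length(res), 0, noise_sd))
  }
  data.frame(time_h = timepoints, residual_pct = res)
}

#' Generate a noisy reactor pressure curve
#'
#' Delegates to [simulate_pressure()] and adds Gaussian noise to the total
#' pressure; the noiseless component is monotone non-increasing.
#'
#' @param config a [reactor_config()].
#' @param params a [forward_params()].
#' @param t_grid times in min, sorted, starting at 0.
#' @param noise_sd Gaussian noise sd, Pa.
#' @param seed integer seed.
#' @return Data frame with columns `time` and `pressure`, with the clean
#'   series as attribute `"truth"`.
#' @export
make_pressure_curve <- function(config, params, t_grid, noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0)
  clean <- simulate_pressure(config, params, t_grid)
  pressure <- if (noise_sd > 0) {
    with_seed(seed, clean$pressure + rnorm(length(t_grid), 0, noise_sd))
  } else {
    clean$pressure
  }
  out <- data.frame(time = t_grid, pressure = pressure)
  attr(out, "truth") <- clean
  out
}

#' Generate a synthetic Michaelis-Menten rate dataset
#'
#' Rates at the given substrate levels from `v = Vmax S / (KM + S)` with
#' `Vmax = kcat * enzyme_conc`, replicated and perturbed by multiplicative
#' Gaussian noise — the dataset [fit_mm()] consumes.
#'
#' @param kcat,KM,enzyme_conc true kinetic parameters (1/s, mol/L, mol/L).
#' @param substrate substrate levels, mol/L (post-mixing).
#' @param noise_cv multiplicative noise coefficient of variation (e.g. 0.03
#'   for 3%).
#' @param replicates technical replicates per level.
#' @param seed integer seed.
#' @return Data frame with columns `substrate` (mol/L) and `rate`
#'   (mol/(L s)).
#' @export
make_mm_dataset <- function(kcat = 1.2e3, KM = 4.9e-3, enzyme_conc = 350e-9,
                            substrate = c(3.4, 6.8, 10.2, 13.6, 17) * 1e-3,
                            noise_cv = 0.03, replicates = 3, seed = 1) {
  stopifnot(kcat > 0, KM > 0, enzyme_conc > 0, noise_cv >= 0, replicates >= 1)
  S <- rep(substrate, each = replicates)
  v <- kcat * enzyme_conc * S / (KM + S)
  if (noise_cv > 0) {
    v <- with_seed(seed, v * (1 + rnorm(length(v), 0, noise_cv)))
  }
  data.frame(substrate = S, rate = pmax(v, 0))
}
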