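# Stopped-flow pH-indicator kinetics: initial absorbance rates, uncatalyzed
# subtraction, the Q buffering factor converting absorbance rates to
# CO2-hydration rates, and Michaelis-Menten fitting.

#' Assay conditions for the stopped-flow CO2 hydration assay
#'
#' Post-mixing reaction-cell conditions.  Defaults describe a 1:1 mix of a
#' 20 mM Tris / 0.2 mM phenol red pH 8.3 buffer syringe with CO2-saturated
#' water: 10 mM Tris (pKa 8.07 at 25 degrees C), 0.1 mM phenol red
#' (pKa 7.9), read at a single wavelength where only the deprotonated
#' indicator absorbs.
#'
#' @param buffer_total buffer concentration, mol/L.
#' @param buffer_pKa buffer pKa.
#' @param indicator_total indicator concentration, mol/L (> 0).
#' @param indicator_pKa indicator pKa.
#' @param epsilon_path absorbance units per mole-fraction of deprotonated
#'   indicator (extinction coefficient times path length, folded into one
#'   parameter).
#' @param pH_init working pH at the start of the reaction.
#' @param mix_ratio two-vector `c(sample, other)` of syringe volume parts
#'   (default 1:1).
#' @param temperature assay temperature, degrees C (recorded only).
#' @return List of class `"assay_conditions"`.
#' @export
assay_conditions <- function(buffer_total = 10e-3, buffer_pKa = 8.07,
                             indicator_total = 0.1e-3, indicator_pKa = 7.9,
                             epsilon_path = 1.0, pH_init = 8.3,
                             mix_ratio = c(1, 1), temperature = 25) {
  stopifnot(
    buffer_total >= 0, indicator_total >= 0,
    length(mix_ratio) == 2, all(mix_ratio >= 0), sum(mix_ratio) > 0
  )
  structure(
    list(
      buffer_total = buffer_total, buffer_pKa = buffer_pKa,
      indicator_total = indicator_total, indicator_pKa = indicator_pKa,
      epsilon_path = epsilon_path, pH_init = pH_init,
      mix_ratio = mix_ratio, temperature = temperature
    ),
    class = "assay_conditions"
  )
}

#' Post-mixing reagent concentration
#'
#' Concentration of a syringe reagent after rapid mixing: a 1:1 mix halves
#' the stock (34 mM CO2-saturated water becomes 17 mM in the cell).
#'
#' @param syringe_conc stock concentration in the syringe, mol/L (>= 0).
#' @param mix_ratio two-vector `c(sample, other)` of volume parts.
#' @return Reaction-cell concentration, mol/L.
#' @export
#' @examples
#' reaction_concentration(34e-3) # 17 mM
reaction_concentration <- function(syringe_conc, mix_ratio = c(1, 1)) {
  stopifnot(all(syringe_conc >= 0), length(mix_ratio) == 2, sum(mix_ratio) > 0)
  syringe_conc * mix_ratio[1] / sum(mix_ratio)
}

#' Initial rate of absorbance change
#'
#' Ordinary-least-squares slope of absorbance versus time over a window;
#' sign is preserved (a decaying trace gives a negative slope).
#'
#' @param trace data frame with columns `time` (s, strictly increasing) and
#'   `absorbance`.
#' @param window numeric `c(t_start, t_end)` in seconds, within the trace
#'   span.  The conventional assay window is 10--20 s.
#' @return List of class `"rate_estimate"` with `dA_dt` (absorbance/s),
#'   `window`, `r_squared` and `n_points`.
#' @export
initial_rate <- function(trace, window = c(10, 20)) {
  stopifnot(
    all(c("time", "absorbance") %in% names(trace)),
    length(window) == 2, window[1] < window[2]
  )
  if (window[1] < min(trace$time) - 1e-9 || window[2] > max(trace$time) + 1e-9) {
    stop_invalid("rate window outside trace span")
  }
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(sel) < 3L) stop_invalid("fewer than 3 trace points in rate window")
  fit <- lm(absorbance ~ time, data = trace[sel, , drop = FALSE])
  ss <- suppressWarnings(summary(fit)) # exact linear data triggers a benign warning
  structure(
    list(
      dA_dt = unname(coef(fit)[2]), window = window,
      r_squared = if (is.nan(ss$r.squared)) 1 else ss$r.squared,
      n_points = sum(sel)
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "dA/dt = %.4g /s over [%g, %g] s (r^2 = %.4f, n = %d)\n",
    x$dA_dt, x$window[1], x$window[2], x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Net (enzyme-attributable) absorbance rate
#'
#' Subtracts the uncatalyzed rate from the catalyzed one, both taken over
#' the same window convention.  If the uncatalyzed reaction is faster in
#' magnitude than the catalyzed one the result is flagged.
#'
#' @param catalyzed,uncatalyzed [initial_rate()] results or bare slopes
#'   (absorbance/s).
#' @return List with `net_dA_dt` and logical `suspect` (uncatalyzed faster
#'   than catalyzed).
#' @export
#' @examples
#' net_rate(-0.03, -0.01)$net_dA_dt # -0.02
net_rate <- function(catalyzed, uncatalyzed) {
  cval <- if (inherits(catalyzed, "rate_estimate")) catalyzed$dA_dt else catalyzed
  uval <- if (inherits(uncatalyzed, "rate_estimate")) uncatalyzed$dA_dt else uncatalyzed
  net <- cval - uval
  suspect <- abs(cval) < abs(uval)
  if (suspect) {
    warning("uncatalyzed rate exceeds catalyzed rate in magnitude",
      call. = FALSE
    )
  }
  list(net_dA_dt = net, suspect = suspect)
}

# protonated fraction of a monoprotic acid/base at a given pH
protonated_fraction <- function(pH, pKa) 1 / (1 + 10^(pH - pKa))

#' Q buffering factor of the indicator assay
#'
#' Converts an absorbance-change rate into a proton-release (hence CO2
#' hydration) rate.  At the working pH, `Q` is the ratio of the system's
#' buffering capacity (moles of H+ taken up by buffer plus indicator per
#' unit pH drop, from Henderson-Hasselbalch derivatives) to the optical
#' sensitivity (absorbance change per unit pH drop, from the indicator's
#' deprotonation curve scaled by `epsilon_path`):
#' \deqn{Q = \frac{B f_B (1 - f_B) + I f_I (1 - f_I)}
#'             {\varepsilon \ell \, f_I (1 - f_I)}}
#' where \eqn{f} are protonated fractions at `pH_init`.  The free-proton
#' term is negligible at working pH and omitted.
#'
#' @param conditions an [assay_conditions()].
#' @return Q in mol/(L x absorbance unit), strictly positive.
#' @export
buffer_factor <- function(conditions) {
  stopifnot(inherits(conditions, "assay_conditions"))
  if (conditions$indicator_total <= 0) {
    stop_invalid("indicator_total must be positive")
  }
  if (conditions$epsilon_path == 0) {
    stop_invalid("epsilon_path = 0: no optical response (degenerate optics)")
  }
  fB <- protonated_fraction(conditions$pH_init, conditions$buffer_pKa)
  fI <- protonated_fraction(conditions$pH_init, conditions$indicator_pKa)
  buffering <- conditions$buffer_total * fB * (1 - fB) +
    conditions$indicator_total * fI * (1 - fI)
  optical <- conditions$epsilon_path * fI * (1 - fI)
  buffering / optical
}

#' CO2 hydration rate from a net absorbance rate
#'
#' @param net_dA_dt net absorbance rate (absorbance/s); the magnitude is
#'   used.
#' @param Q buffering factor from [buffer_factor()], mol/(L x A.U.) (> 0).
#' @return CO2 conversion rate, mol/(L s).
#' @export
co2_rate <- function(net_dA_dt, Q) {
  stopifnot(Q > 0)
  Q * abs(net_dA_dt)
}

#' Fit the Michaelis-Menten equation to rate data
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)} with fixed,
#' data-driven initialisation (`Vmax0 = max(v)`, `KM0 = median(S)`), so the
#' fit is deterministic given the data.  `kcat` is derived from the enzyme
#' concentration; standard errors come from the fit covariance (delta method
#' for derived quantities).
#'
#' @param substrate substrate concentrations, mol/L (>= 4 distinct levels);
#'   post-mixing values.
#' @param rates CO2 hydration rates, mol/(L s), non-negative.
#' @param enzyme_conc enzyme concentration in the reaction, mol/L.
#' @return List of class `"mm_fit"`: `kcat` (1/s), `KM` (mol/L), `Vmax`
#'   (mol/(L s)), `kcat_over_KM` (1/(M s)), `se` (named standard errors),
#'   `enzyme_conc`, and the underlying `fit`.
#' @export
fit_mm <- function(substrate, rates, enzyme_conc) {
  stopifnot(
    length(substrate) == length(rates), length(unique(substrate)) >= 4,
    all(rates >= 0), all(substrate > 0), enzyme_conc > 0
  )
  dat <- data.frame(S = substrate, v = rates)
  start <- list(Vmax = max(dat$v), KM = stats::median(unique(dat$S)))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (KM + S),
      data = dat, start = start,
      lower = c(Vmax = 0, KM = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop_invalid(paste0(
        "Michaelis-Menten fit did not converge: ", conditionMessage(e),
        " [n = ", nrow(dat), ", Vmax0 = ", signif(start$Vmax, 3),
        ", KM0 = ", signif(start$KM, 3), "]"
      ))
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) c(Vmax = NA_real_, KM = NA_real_)
  )
  kcat <- unname(est["Vmax"]) / enzyme_conc
  KM <- unname(est["KM"])
  structure(
    list(
      kcat = kcat, KM = KM, Vmax = unname(est["Vmax"]),
      kcat_over_KM = kcat / KM,
      se = c(
        Vmax = unname(se["Vmax"]), KM = unname(se["KM"]),
        kcat = unname(se["Vmax"]) / enzyme_conc
      ),
      enzyme_conc = enzyme_conc, fit = fit
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Michaelis-Menten fit\n",
      "  kcat      = %.3g 1/s  (SE %.2g)\n",
      "  KM        = %.3g mM   (SE %.2g mM)\n",
      "  kcat/KM   = %.2g 1/(M s)\n",
      "  Vmax      = %.3g mol/(L s) at [E] = %.3g M\n"
    ),
    x$kcat, x$se[["kcat"]], x$KM * 1e3, x$se[["KM"]] * 1e3,
    signif_report(x$kcat_over_KM), x$Vmax, x$enzyme_conc
  ))
  invisible(x)
}

#' Catalytic efficiency kcat/KM
#'
#' @param kcat turnover number, 1/s.
#' @param KM Michaelis constant, mol/L.
#' @param digits significant figures for the reported value (`NULL` to skip
#'   rounding).
#' @return kcat/KM in 1/(M s).
#' @export
#' @examples
#' efficiency(1.2e3, 4.9e-3) # 2.4e5
efficiency <- function(kcat, KM, digits = 2) {
  stopifnot(kcat > 0, KM > 0)
  out <- kcat / KM
  if (!is.null(digits)) out <- signif(out, digits)
  out
}

#' Convert a molar concentration to a mass concentration
#'
#' @param conc molar concentration, mol/L (>= 0).
#' @param molecular_weight g/mol (> 0).
#' @param unit output unit: `"g_per_l"`, `"mg_per_ml"` (same scale) or
#'   `"ug_per_ml"`.
#' @return Mass concentration in the requested unit.
#' @export
#' @examples
#' molar_to_mass(340e-9, 19000, "ug_per_ml") # ~6.5
molar_to_mass <- function(conc, molecular_weight,
                          unit = c("g_per_l", "mg_per_ml", "ug_per_ml")) {
  unit <- match.arg(unit)
  stopifnot(all(conc >= 0), molecular_weight > 0)
  g_per_l <- conc * molecular_weight
  switch(unit,
    g_per_l = g_per_l,
    mg_per_ml = g_per_l,
    ug_per_ml = g_per_l * 1e3
  )
}

#' Full trace-to-rate convenience pipeline
#'
#' Measures the initial absorbance rate of a catalyzed and (optionally) an
#' uncatalyzed trace over the same window, subtracts, and converts to a CO2
#' hydration rate through the Q buffering factor.
#'
#' @param catalyzed,uncatalyzed traces (data frames `time`/`absorbance`);
#'   `uncatalyzed` may be `NULL` for no subtraction.
#' @param conditions an [assay_conditions()].
#' @param window rate window in seconds.
#' @return List with `rate` (mol/(L s)), `net_dA_dt`, `Q`, and the two
#'   [initial_rate()] estimates.
#' @export
trace_to_rate <- function(catalyzed, uncatalyzed = NULL,
                          conditions = assay_conditions(),
                          window = c(10, 20)) {
  rc <- initial_rate(catalyzed, window)
  ru <- if (is.null(uncatalyzed)) NULL else initial_rate(uncatalyzed, window)
  net <- if (is.null(ru)) {
    list(net_dA_dt = rc$dA_dt, suspect = FALSE)
  } else {
    net_rate(rc, ru)
  }
  Q <- buffer_factor(conditions)
  list(
    rate = co2_rate(net$net_dA_dt, Q), net_dA_dt = net$net_dA_dt,
    Q = Q, catalyzed = rc, uncatalyzed = ru, suspect = net$suspect
  )
}
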