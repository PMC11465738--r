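# Thermal and alkaline stability analytics: Wilbur-Anderson activity units,
# residual activity/solubility percentages, and half-life estimation from
# residual-activity decay series.

#' Wilbur-Anderson activity units
#'
#' Classical indicator-assay activity unit from the time for the pH
#' indicator to traverse a fixed pH drop without and with enzyme:
#' \eqn{WA = (t_0 - t) / t}.  Outputs carry a note that the formula is the
#' reconstructed classical definition.
#'
#' @param t_uncatalyzed,t_catalyzed transition times in seconds (> 0);
#'   normally `t_catalyzed <= t_uncatalyzed`.
#' @return WA units (numeric), with attribute `formula`.
#' @export
#' @examples
#' wa_units(60, 20) # 2
wa_units <- function(t_uncatalyzed, t_catalyzed) {
  if (any(t_catalyzed <= 0) || any(t_uncatalyzed <= 0)) {
    stop_invalid("transition times must be positive")
  }
  structure((t_uncatalyzed - t_catalyzed) / t_catalyzed,
    formula = "reconstructed Wilbur-Anderson definition (t0 - t)/t"
  )
}

#' Residual activity or solubility percentage
#'
#' @param value_t measurement after incubation (>= 0).
#' @param value_0 measurement at time zero (> 0).
#' @return `100 * value_t / value_0`; values above 100 are permitted
#'   (thermal activation).
#' @export
#' @examples
#' residual_fraction(0.9, 1.0) # 90
residual_fraction <- function(value_t, value_0) {
  if (any(value_0 <= 0)) stop_invalid("time-zero value must be positive")
  if (any(value_t < 0)) stop_invalid("measurements must be non-negative")
  100 * value_t / value_0
}

#' Half-life from a residual-activity decay series
#'
#' Restricts the series to the maximal suffix starting at its maximum (so a
#' transient thermal-activation bump is discarded), then returns the first
#' time the residual crosses 50% of its initial (t = 0) value, by log-linear
#' interpolation between the bracketing points (first-order decay between
#' samples).  The threshold is taken relative to the first point, so the
#' estimate is invariant to uniform rescaling of the residual axis.  Returns
#' `NA` if the threshold is never reached within the series; this is a value
#' ("not observed within the experiment"), not an error.
#'
#' @param series data frame with columns `time_h` (ascending) and
#'   `residual_pct`, at least 2 points.
#' @return Half-life in hours, or `NA_real_` if the series never crosses
#'   50%.
#' @export
#' @examples
#' half_life(data.frame(time_h = c(0, 24), residual_pct = c(100, 50))) # 24
half_life <- function(series) {
  stopifnot(
    all(c("time_h", "residual_pct") %in% names(series)),
    nrow(series) >= 2, !is.unsorted(series$time_h)
  )
  thr <- series$residual_pct[1] / 2
  i0 <- which.max(series$residual_pct)
  t <- series$time_h[i0:nrow(series)]
  r <- series$residual_pct[i0:nrow(series)]
  if (r[1] <= thr) {
    return(t[1])
  }
  k <- which(r <= thr)
  if (length(k) == 0L) {
    return(NA_real_)
  }
  k <- k[1]
  t1 <- t[k - 1L]
  t2 <- t[k]
  r1 <- r[k - 1L]
  r2 <- r[k]
  if (r2 <= 0) {
    # log interpolation undefined; fall back to linear
    return(t1 + (t2 - t1) * (r1 - thr) / (r1 - r2))
  }
  t1 + (t2 - t1) * log(r1 / thr) / log(r1 / r2)
}

#' Summarise a stability experiment
#'
#' @param series residual series as in [half_life()].
#' @param condition description of the incubation condition (e.g.
#'   `"80 degC"` or `"20% K2CO3 pH 11.5"`).
#' @return List of class `"stability_result"` with `half_life`, the
#'   `residuals` series and the `condition`.
#' @export
stability_result <- function(series, condition = "") {
  structure(
    list(half_life = half_life(series), residuals = series, condition = condition),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  hl <- if (is.na(x$half_life)) {
    "not reached within the series"
  } else {
    sprintf("%.3g h", x$half_life)
  }
  cat(
    "Stability result", if (nzchar(x$condition)) paste0("(", x$condition, ")"),
    "\n  half-life:", hl, "\n  points:", nrow(x$residuals), "\n"
  )
  invisible(x)
}
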