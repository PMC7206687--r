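## Kinetic endpoints and tumor-response classification.

#' Post-treatment regression percentage
#'
#' The minimum volume \eqn{V_{min}} reached after treatment is located on
#' the interpolated post-treatment curve (first occurrence; a raw-point
#' mode is available) and the regression percentage
#' \eqn{|(V_{min} - V_0)/V_0| \times 100} is reported as a magnitude when
#' the tumor regressed, and 0 otherwise. The signed raw value is retained.
#'
#' @param series post-treatment data.frame with `day` and `volume_cm3`
#'   (or `volume`); at least one observation.
#' @param V0 volume at the treatment day (cm^3), > 0.
#' @param use_interpolation locate `Vmin` on the daily Hermite interpolant
#'   (default) instead of the raw observations (automatic fallback to raw
#'   when fewer than 3 points are available).
#' @return list with `regression_percent` (magnitude, 0 if no regression),
#'   `signed_percent`, `Vmin`, `Vmin_day`, `regressed`.
#' @export
regression_percent <- function(series, V0, use_interpolation = TRUE) {
  if (V0 <= 0) stop("'V0' must be > 0")
  vcol <- if ("volume_cm3" %in% names(series)) "volume_cm3" else "volume"
  if (!nrow(series)) stop("empty post-treatment window")
  if (use_interpolation && nrow(series) >= 3) {
    cv <- hermite_interpolate(series$day, series[[vcol]])
    vals <- cv$values; days <- cv$grid
  } else {
    o <- order(series$day)
    vals <- series[[vcol]][o]; days <- series$day[o]
  }
  imin <- which.min(vals)[1]
  vmin <- vals[imin]
  signed <- (vmin - V0) / V0 * 100
  list(regression_percent = if (vmin < V0) abs(signed) else 0,
       signed_percent = signed,
       Vmin = vmin, Vmin_day = days[imin], regressed = vmin < V0)
}

#' Doubling time read from an interpolated curve
#'
#' First day at which the curve reaches twice the reference volume,
#' refined by linear interpolation between the bracketing grid days.
#' Returns `Inf` ("not reached") when the curve stays below `2 V0` over the
#' whole window.
#'
#' @param curve an [hermite_interpolate()] result whose grid starts at the
#'   window origin.
#' @param V0 reference volume (cm^3); defaults to the curve's first value.
#' @return Days from the window origin to volume doubling, or `Inf`.
#' @export
doubling_time_from_data <- function(curve, V0 = curve$values[1]) {
  stopifnot(inherits(curve, "interp_curve"))
  if (V0 <= 0) stop("'V0' must be > 0")
  target <- 2 * V0
  above <- which(curve$values >= target)
  if (!length(above)) return(Inf)
  j <- above[1]
  if (j == 1) return(curve$grid[1] - curve$grid[1])  # already doubled at origin
  g <- curve$grid; v <- curve$values
  frac <- (target - v[j - 1]) / (v[j] - v[j - 1])
  (g[j - 1] + frac * (g[j] - g[j - 1])) - g[1]
}

#' Tumor growth delay
#'
#' Ratio between the mean doubling time of a treated group and that of its
#' control group. Non-finite doubling times ("never doubled") are excluded
#' from the means with a warning; if no treated animal doubled, `Inf` is
#' returned with a warning.
#'
#' @param treated_DTs,control_DTs numeric vectors of doubling times (days).
#' @return Dimensionless delay ratio.
#' @export
growth_delay <- function(treated_DTs, control_DTs) {
  if (!length(treated_DTs) || !length(control_DTs)) {
    stop("both groups must be non-empty")
  }
  tfin <- treated_DTs[is.finite(treated_DTs)]
  cfin <- control_DTs[is.finite(control_DTs)]
  if (length(tfin) < length(treated_DTs) || length(cfin) < length(control_DTs)) {
    warning("non-finite doubling times excluded from group means")
  }
  if (!length(cfin) || mean(cfin) == 0) stop("control mean doubling time is zero")
  if (!length(tfin)) {
    warning("no treated animal doubled; delay is infinite")
    return(Inf)
  }
  mean(tfin) / mean(cfin)
}

#' Classify the post-treatment tumor response
#'
#' Assigns exactly one of the standard preclinical response classes from
#' the post-treatment series: complete response (CR) when the minimum
#' volume falls to the detection limit; partial response (PR) when the
#' regression percentage reaches the PR threshold; progressive disease
#' (PD) when the final volume reaches `pd_growth` times the treatment-day
#' volume without meaningful regression; stable disease (SD) otherwise.
#' The thresholds are conventional defaults and fully configurable.
#'
#' @inheritParams regression_percent
#' @param thresholds list with `cr_volume` (cm^3, detection limit),
#'   `pr_regression` (\%), `pd_growth` (fold increase of `V0`),
#'   `pd_max_regression` (\%; regressions above this rule PD out).
#' @return list with `response` (one of `"PD"`, `"SD"`, `"PR"`, `"CR"`),
#'   the `regression` sub-report, and the resolved `thresholds`.
#' @export
classify_response <- function(series, V0,
                              thresholds = list(cr_volume = 0.01,
                                                pr_regression = 50,
                                                pd_growth = 2,
                                                pd_max_regression = 25),
                              use_interpolation = TRUE) {
  reg <- regression_percent(series, V0, use_interpolation)
  vcol <- if ("volume_cm3" %in% names(series)) "volume_cm3" else "volume"
  v_final <- series[[vcol]][which.max(series$day)]
  response <- if (reg$Vmin <= thresholds$cr_volume) {
    "CR"
  } else if (reg$regression_percent >= thresholds$pr_regression) {
    "PR"
  } else if (v_final >= thresholds$pd_growth * V0 &&
             reg$regression_percent < thresholds$pd_max_regression) {
    "PD"
  } else {
    "SD"
  }
  list(response = response, regression = reg, thresholds = thresholds)
}

#' Overall treatment effectiveness
#'
#' Percentage of responders, \eqn{100 (PR + CR) / N}, rounded to one
#' decimal as conventionally reported.
#'
#' @param responses character vector of per-animal classes
#'   (`"PD"`, `"SD"`, `"PR"`, `"CR"`).
#' @return Effectiveness in percent (one decimal).
#' @export
#' @examples
#' overall_effectiveness(c("PR", "PR", "PR", "PR", "SD"))  # 80
overall_effectiveness <- function(responses) {
  if (!length(responses)) stop("'responses' is empty")
  bad <- setdiff(unique(responses), c("PD", "SD", "PR", "CR"))
  if (length(bad)) stop("unknown response classes: ", paste(bad, collapse = ", "))
  round(100 * mean(responses %in% c("PR", "CR")), 1)
}
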