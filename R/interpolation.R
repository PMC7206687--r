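#' Shape-preserving Hermite interpolation of a volume series
#'
#' Interpolates sparse caliper observations onto a (by default daily) grid
#' with a shape-preserving piecewise-cubic Hermite interpolant
#' (Fritsch--Carlson tangent limiting with zero tangents at interior
#' extrema, via [pracma::pchip()]). The interpolant passes through every
#' observation exactly and never overshoots the bracketing observations,
#' so non-negative observations can never produce negative interpolated
#' volumes. Extrapolation outside the observation span is refused.
#'
#' @param day observation days (strictly increasing after sorting).
#' @param volume observed volumes (cm^3), same length as `day`, >= 3 points.
#' @param grid target grid (days); defaults to daily steps across the
#'   observation span. Must lie within `[min(day), max(day)]`.
#' @param source optional label (animal id or group) carried in the result.
#' @return An object of class `"interp_curve"`: list with `grid`, `values`,
#'   `source`.
#' @export
#' @examples
#' cv <- hermite_interpolate(c(0, 3, 7, 10), c(0.1, 0.25, 0.6, 1.1))
#' plot(cv$grid, cv$values, type = "l")
hermite_interpolate <- function(day, volume, grid = NULL, source = NA_character_) {
  if (length(day) != length(volume)) stop("'day' and 'volume' lengths differ")
  o <- order(day)
  day <- day[o]; volume <- volume[o]
  if (length(day) < 3L) stop("at least 3 observations are required")
  if (anyDuplicated(day)) stop("duplicate observation days")
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("volumes must be finite and non-negative")
  }
  if (is.null(grid)) grid <- seq(min(day), max(day), by = 1)
  if (min(grid) < min(day) || max(grid) > max(day)) {
    stop("requested grid extends beyond the observation span (no extrapolation)")
  }
  structure(list(grid = grid, values = pracma::pchip(day, volume, grid),
                 source = source),
            class = "interp_curve")
}

#' Pointwise group-mean curve with standard errors
#'
#' Averages a list of interpolated curves day by day. Curves may have
#' different spans (animals leaving the study early contribute only on the
#' days they were observed), but their grids must be mutually aligned
#' (identical values on shared days). The standard error of the mean is
#' sd/sqrt(N) with the pointwise N; days with a single contributing curve
#' get `sem = NA` and are flagged.
#'
#' @param curves list of [hermite_interpolate()] results.
#' @param source optional label for the averaged curve.
#' @return An `"interp_curve"` with extra fields `sem` and `n` per grid day.
#' @export
group_mean_curve <- function(curves, source = NA_character_) {
  if (!length(curves)) stop("'curves' is empty")
  stopifnot(all(vapply(curves, inherits, TRUE, "interp_curve")))
  grid <- sort(unique(unlist(lapply(curves, `[[`, "grid"))))
  ## alignment check: within each curve's span, the union of all grids must
  ## coincide with the curve's own grid (otherwise the grids interleave)
  for (cv in curves) {
    inside <- grid[grid >= min(cv$grid) & grid <= max(cv$grid)]
    if (length(inside) != length(cv$grid) || any(inside != cv$grid)) {
      stop("curve grids are not mutually aligned")
    }
  }
  vals <- vapply(curves, function(cv) {
    out <- rep(NA_real_, length(grid))
    out[match(cv$grid, grid)] <- cv$values
    out
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  if (any(n == 0)) stop("internal: grid day with no contributing curve")
  mean_v <- rowMeans(vals, na.rm = TRUE)
  sem <- apply(vals, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  structure(list(grid = grid, values = mean_v, sem = sem, n = n,
                 source = source),
            class = "interp_curve")
}
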