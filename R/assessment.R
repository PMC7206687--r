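## Fit-assessment statistics: SSE, SE, r^2 and adjusted r^2, leave-one-out
## PRESS, fit-first-m MPRESS, and the Dmax/RMSE distance between
## interpolated treated and control group-mean curves.

#' Sum of squared errors
#'
#' \eqn{SSE = \sum_j (\hat V_j - V_j)^2}, the quantity minimized by the
#' Marquardt--Levenberg fits.
#'
#' @param observed,predicted numeric vectors of equal length (cm^3).
#' @return SSE (cm^6, conventionally reported in the cm^3 column of
#'   summary tables).
#' @export
sse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  sum((predicted - observed)^2)
}

#' Standard error of the estimate
#'
#' \eqn{SE = \sqrt{SSE / (n_1 - k)}} with `k` the number of free
#' parameters.
#'
#' @inheritParams sse
#' @param k number of fitted parameters; must be < number of points.
#' @return SE (cm^3).
#' @export
se_estimate <- function(observed, predicted, k) {
  n1 <- length(observed)
  if (n1 <= k) stop("need more points than parameters (n1 > k)")
  sqrt(sse(observed, predicted) / (n1 - k))
}

#' Goodness of fit and its small-sample adjustment
#'
#' \eqn{1 - r^2 = SSE / [\sum V_j^2 - (\sum V_j)^2/n_1]} (total sum of
#' squares about the mean) and
#' \eqn{r_a^2 = [(n_1 - 1) r^2 - k + 1] / (n_1 - k)}. A fit is flagged
#' satisfactory when \eqn{r_a^2 > 0.98}.
#'
#' @inheritParams se_estimate
#' @return list with `r2`, `ra2`, `satisfactory`.
#' @export
r2_ra2 <- function(observed, predicted, k) {
  n1 <- length(observed)
  if (n1 <= k) stop("need more points than parameters (n1 > k)")
  sst <- sum(observed^2) - sum(observed)^2 / n1
  if (sst <= 0) stop("observed values have zero variance")
  r2 <- 1 - sse(observed, predicted) / sst
  ra2 <- ((n1 - 1) * r2 - k + 1) / (n1 - k)
  list(r2 = r2, ra2 = ra2, satisfactory = ra2 > 0.98)
}

#' Leave-one-out predicted residual error sum of squares (PRESS)
#'
#' For each deleted observation the model is refitted on the remaining
#' points and the deleted volume predicted; squared prediction residuals
#' are then aggregated. The default `"printed"` mode follows the form the
#' statistic is usually tabulated in for this protocol -- summation over
#' the first \eqn{n_1 - 1} deletions, normalized by \eqn{n_1 - k} -- while
#' `"standard"` gives the conventional unnormalized full sum over all
#' \eqn{n_1} deletions. Deleting the origin point does not move the model's
#' anchoring: `V0` is a protocol constant captured by the fitter (see
#' [tgk1_fitter()]).
#'
#' A deletion whose refit fails is skipped with a warning (the denominator
#' is unchanged).
#'
#' @param t times (days, window-re-zeroed).
#' @param volume observed volumes (cm^3).
#' @param fitter a fitter factory result, e.g. [tgk1_fitter()] or
#'   [tgk2_fitter()].
#' @param k number of free parameters of the stage (2).
#' @param mode `"printed"` or `"standard"`.
#' @return PRESS value (cm^3 column convention).
#' @export
press <- function(t, volume, fitter, k = 2,
                  mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  n1 <- length(t)
  if (length(volume) != n1) stop("length mismatch")
  idx <- if (mode == "printed") seq_len(n1 - 1) else seq_len(n1)
  acc <- 0
  for (j in idx) {
    fj <- tryCatch(fitter(t[-j], volume[-j]), error = function(e) NULL)
    if (is.null(fj)) {
      warning("leave-one-out refit failed for point ", j, "; point skipped")
      next
    }
    acc <- acc + (fj$predict(t[j]) - volume[j])^2
  }
  if (mode == "printed") acc / (n1 - k) else acc
}

#' Forecast residual error from a truncated fit (MPRESS)
#'
#' Fits the model to the first `m` observations only and measures the
#' squared forecast error on the remaining \eqn{n_1 - m} points:
#' \eqn{MPRESS(m) = \sum_{j=m+1}^{n_1} [(\hat V_j)' - V_j]^2 / (n_1 - m)}.
#' Values for m = 3, 4, 5 are typically similar; m = 3 is the conventional
#' reporting choice.
#'
#' @inheritParams press
#' @param m number of initial points fitted (>= 3, < n1).
#' @return MPRESS(m) value.
#' @export
mpress <- function(t, volume, fitter, m = 3) {
  n1 <- length(t)
  if (length(volume) != n1) stop("length mismatch")
  if (m < 3 || m >= n1) stop("'m' must satisfy 3 <= m < n1")
  fm <- fitter(t[seq_len(m)], volume[seq_len(m)])
  rest <- (m + 1):n1
  sum((fm$predict(t[rest]) - volume[rest])^2) / (n1 - m)
}

#' Maximum and root-mean-square distance between two curves
#'
#' Compares a treated group-mean curve against its control reference on a
#' common grid of M points: \eqn{D_{max} = \max_i |F_i - G_i|} and
#' \eqn{RMSE = \sqrt{\sum_i (F_i - G_i)^2 / M}}.
#'
#' @param reference control [hermite_interpolate()] curve (the F series).
#' @param compared treated curve on the identical grid (the G series).
#' @return list with `Dmax` and `RMSE` (cm^3).
#' @export
curve_distance <- function(reference, compared) {
  stopifnot(inherits(reference, "interp_curve"),
            inherits(compared, "interp_curve"))
  if (length(reference$grid) != length(compared$grid) ||
      any(reference$grid != compared$grid)) {
    stop("curves must share an identical grid")
  }
  d <- reference$values - compared$values
  list(Dmax = max(abs(d)), RMSE = sqrt(mean(d^2)))
}
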