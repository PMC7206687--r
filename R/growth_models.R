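#' Parameter bundle for the unperturbed Gompertz growth law
#'
#' Bundles the initial volume and the two kinetic rates of the Gompertz
#' model \deqn{V(t) = V_0 \exp\{(\alpha/\beta)(1 - e^{-\beta t})\}.}
#' `alpha` is the intrinsic growth rate of the tumor and `beta` the growth
#' deceleration factor associated with endogenous anti-angiogenic processes;
#' both are in days\eqn{^{-1}}, volumes in cm\eqn{^3}.
#'
#' `beta = 0` is rejected here because the closed form degenerates
#' (\eqn{\alpha/\beta} is undefined); use [exp_growth_volume()] for the
#' exponential limit.
#'
#' @param V0 initial tumor volume (cm^3), > 0.
#' @param alpha intrinsic growth rate (days^-1), > 0.
#' @param beta growth deceleration factor (days^-1), > 0.
#' @return An object of class `"gompertz_params"`.
#' @seealso [gompertz_volume()], [echt_params()]
#' @export
#' @examples
#' gompertz_params(0.5, 0.462, 0.024)
gompertz_params <- function(V0, alpha, beta) {
  for (nm in c("V0", "alpha", "beta")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (V0 <= 0) stop("'V0' must be > 0")
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (beta <= 0) {
    stop("'beta' must be > 0; use exp_growth_volume() for the beta = 0 limit")
  }
  structure(list(V0 = V0, alpha = alpha, beta = beta),
            class = "gompertz_params")
}

#' Parameter bundle for the direct-current treatment term
#'
#' The treatment enters the modified Gompertz equation only through the
#' applied direct-current intensity `i`, the polarization current `i0`
#' induced in the tumor, and the first-order exponential decay rate `gamma`
#' of the net effect after the current is removed. Exposure time and
#' electrode-array geometry act implicitly through `i0` and `gamma`.
#'
#' @param i applied DC intensity (mA), >= 0.
#' @param i0 polarization current (mA), > 0.
#' @param gamma decay rate of the net treatment effect (days^-1), >= 0.
#' @return An object of class `"echt_params"`.
#' @export
#' @examples
#' echt_params(i = 6, i0 = 4.061, gamma = 12.9)
echt_params <- function(i, i0, gamma) {
  for (nm in c("i", "i0", "gamma")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (i < 0) stop("'i' must be >= 0")
  if (i0 <= 0) stop("'i0' must be > 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  structure(list(i = i, i0 = i0, gamma = gamma), class = "echt_params")
}

#' Dimensionless current-ratio terms of the modified growth rate
#'
#' Computes `r = i / i0` and the two dimensionless coefficients
#' \deqn{a_1 = r(2 - r), \qquad a_2 = 1 - r,}
#' which weight, respectively, the build-up and the instantaneous parts of
#' the treatment-modified growth rate. They satisfy
#' \eqn{a_1 + a_2 = 1 + r - r^2}, the factor that controls the asymptotic
#' volume of a treated tumor.
#'
#' For `r > 2` the coefficient `a1` turns negative; this is permitted (no
#' clamping) but flagged with a warning, since fitted ratios for this model
#' in practice stay below about 1.5.
#'
#' @param i applied DC intensity (mA), >= 0.
#' @param i0 polarization current (mA), > 0.
#' @return A list with components `r`, `a1`, `a2`.
#' @export
#' @examples
#' current_ratio_terms(6, 4.061)$r  # 1.477 to 3 dp
current_ratio_terms <- function(i, i0) {
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0) {
    stop("'i0' must be a single finite number > 0")
  }
  if (!is.numeric(i) || length(i) != 1L || !is.finite(i) || i < 0) {
    stop("'i' must be a single finite number >= 0")
  }
  r <- i / i0
  if (r > 2) warning("i/i0 ratio exceeds 2; a1 is negative")
  list(r = r, a1 = r * (2 - r), a2 = 1 - r)
}

#' Treatment-modified growth rate
#'
#' The modified growth rate
#' \deqn{\alpha^*(t) = [a_1 (1 - e^{-\gamma t}) + a_2]\,\alpha}
#' starts at \eqn{a_2 \alpha} at the moment of treatment and relaxes to
#' \eqn{(1 + r - r^2)\,\alpha} on the timescale \eqn{1/\gamma}.
#'
#' @param t time since treatment (days), vectorized, >= 0.
#' @param alpha intrinsic growth rate (days^-1).
#' @param e an [echt_params()] bundle.
#' @return Modified growth rate(s), days^-1.
#' @export
alpha_star <- function(t, alpha, e) {
  stopifnot(inherits(e, "echt_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  ct <- current_ratio_terms(e$i, e$i0)
  (ct$a1 * (1 - exp(-e$gamma * t)) + ct$a2) * alpha
}

#' Unperturbed Gompertz tumor volume
#'
#' Closed-form solution of the Gompertz growth law,
#' \eqn{V(t) = V_0 \exp\{(\alpha/\beta)(1 - e^{-\beta t})\}}: strictly
#' increasing from `V0` towards the plateau \eqn{V_0 e^{\alpha/\beta}}.
#'
#' @param t time (days), vectorized, >= 0.
#' @param p a [gompertz_params()] bundle.
#' @return Tumor volume(s) in cm^3.
#' @export
#' @examples
#' p <- gompertz_params(0.5, 0.462, 0.024)
#' gompertz_volume(c(0, 7, 14), p)
gompertz_volume <- function(t, p) {
  stopifnot(inherits(p, "gompertz_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  p$V0 * exp((p$alpha / p$beta) * (1 - exp(-p$beta * t)))
}

#' Exponential-growth limit of the Gompertz law
#'
#' The `beta -> 0` limit of [gompertz_volume()],
#' \eqn{V(t) = V_0 e^{\alpha t}}, kept as an explicitly flagged helper so
#' that the main closed form never evaluates the indeterminate
#' \eqn{\alpha/\beta} at `beta = 0`.
#'
#' @param t time (days), vectorized, >= 0.
#' @param V0 initial volume (cm^3), > 0.
#' @param alpha growth rate (days^-1), > 0.
#' @return Tumor volume(s) in cm^3.
#' @export
exp_growth_volume <- function(t, V0, alpha) {
  if (V0 <= 0 || alpha <= 0) stop("'V0' and 'alpha' must be > 0")
  if (any(t < 0)) stop("'t' must be >= 0")
  V0 * exp(alpha * t)
}

#' Modified Gompertz tumor volume under direct-current treatment
#'
#' Evaluates the modified Gompertz equation
#' \deqn{V^*(t) = V_0 \exp\{(\alpha^*(t)/\beta)(1 - e^{-\beta t})\},}
#' with the treatment-modified rate [alpha_star()] substituted pointwise
#' into the closed form (the equation as used for fitting, not a re-derived
#' time-varying-rate ODE solution). With `i = 0` it reduces algebraically to
#' [gompertz_volume()] for all `t`, and its large-`t` asymptote is
#' \eqn{V_0 \exp\{(1 + r - r^2)\alpha/\beta\}}: above `V0` for
#' \eqn{r < (1+\sqrt 5)/2}, below `V0` (net regression) beyond that root.
#'
#' @param t time since treatment (days), vectorized, >= 0.
#' @param p a [gompertz_params()] bundle (`V0` is the volume at treatment).
#' @param e an [echt_params()] bundle.
#' @return Tumor volume(s) in cm^3.
#' @export
#' @examples
#' p <- gompertz_params(0.5, 0.49, 0.055)
#' e <- echt_params(6, 4.061, 12.9)
#' mge_volume(c(0, 3, 9, 18), p, e)
mge_volume <- function(t, p, e) {
  stopifnot(inherits(p, "gompertz_params"), inherits(e, "echt_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  a_mod <- alpha_star(t, p$alpha, e)
  p$V0 * exp((a_mod / p$beta) * (1 - exp(-p$beta * t)))
}

#' Asymptotic volume of the modified Gompertz model
#'
#' @param p a [gompertz_params()] bundle.
#' @param e an [echt_params()] bundle.
#' @return The limiting volume \eqn{V_0 \exp\{(1+r-r^2)\alpha/\beta\}} (cm^3).
#' @export
mge_asymptote <- function(p, e) {
  stopifnot(inherits(p, "gompertz_params"), inherits(e, "echt_params"))
  ct <- current_ratio_terms(e$i, e$i0)
  p$V0 * exp((1 + ct$r - ct$r^2) * p$alpha / p$beta)
}

#' Closed-form doubling time of the unperturbed Gompertz law
#'
#' Inverts the Gompertz solution at \eqn{V = 2 V_0}:
#' \deqn{t_2 = -\frac{1}{\beta}\ln\left(1 - \frac{\beta \ln 2}{\alpha}\right).}
#' When \eqn{\alpha \le \beta \ln 2} the plateau
#' \eqn{V_0 e^{\alpha/\beta}} never reaches \eqn{2 V_0}; the function then
#' returns `Inf` as the "never doubles" sentinel. As \eqn{\beta \to 0} the
#' formula tends to the exponential doubling time \eqn{\ln 2 / \alpha}.
#'
#' @param p a [gompertz_params()] bundle.
#' @return Doubling time in days, or `Inf` if the volume never doubles.
#' @export
#' @examples
#' analytic_doubling_time(gompertz_params(0.5, 0.462, 0.024))
analytic_doubling_time <- function(p) {
  stopifnot(inherits(p, "gompertz_params"))
  if (p$alpha <= p$beta * log(2)) return(Inf)
  -(1 / p$beta) * log(1 - p$beta * log(2) / p$alpha)
}

#' Steel doubling time from cell-kinetic quantities
#'
#' The Steel relation links the volume doubling time to the cell-cycle time
#' `Tc`, the cell-loss factor `phi` and the growth fraction `GF`:
#' \deqn{DT = \frac{T_c \ln 2}{(1 - \varphi)\ln(1 + GF)}.}
#'
#' @param Tc cell-cycle time (days), > 0.
#' @param phi cell-loss factor, in [0, 1).
#' @param GF growth fraction, in (0, 1].
#' @return Doubling time (days).
#' @seealso [growth_fraction()]
#' @export
steel_doubling_time <- function(Tc, phi, GF) {
  if (Tc <= 0) stop("'Tc' must be > 0")
  if (phi < 0 || phi >= 1) stop("'phi' must be in [0, 1)")
  if (GF <= 0 || GF > 1) stop("'GF' must be in (0, 1]")
  Tc * log(2) / ((1 - phi) * log(1 + GF))
}

#' Growth fraction from cycling and non-cycling cell counts
#'
#' `GF = Ncc / (Ncc + Nncc)`, the fraction of tumor cells in the cell cycle.
#'
#' @param Ncc number of cells in the cell cycle, >= 0.
#' @param Nncc number of cells not in the cell cycle, >= 0.
#' @return Growth fraction in [0, 1].
#' @export
growth_fraction <- function(Ncc, Nncc) {
  if (Ncc < 0 || Nncc < 0) stop("cell counts must be >= 0")
  if (Ncc + Nncc == 0) stop("at least one cell count must be > 0")
  Ncc / (Ncc + Nncc)
}

#' Asymptotic response regime of a treated tumor
#'
#' Classifies the long-time behavior predicted by the modified Gompertz
#' model from the current ratio `r = i/i0`. The asymptote crosses `V0`
#' exactly at the positive root of \eqn{1 + r - r^2 = 0}, i.e. the golden
#' ratio \eqn{r = (1 + \sqrt 5)/2}. Separately, complete response has been
#' observed experimentally only above a threshold ratio (reported as 1.50
#' for this tumor line), which is the default `threshold`.
#'
#' Labels: `"progression"` (asymptote above `V0`, ratio below threshold),
#' `"threshold"` (ratio within `tol` of the threshold), `"above_threshold"`
#' (ratio above threshold but asymptote still above `V0`), `"regression"`
#' (asymptote below `V0`).
#'
#' @param p a [gompertz_params()] bundle.
#' @param e an [echt_params()] bundle.
#' @param threshold current-ratio threshold for expected complete response.
#' @param tol half-width of the band treated as "at threshold".
#' @return A character label.
#' @export
response_regime <- function(p, e, threshold = 1.50, tol = 0.01) {
  stopifnot(inherits(p, "gompertz_params"), inherits(e, "echt_params"))
  if (threshold <= 0) stop("'threshold' must be > 0")
  r <- e$i / e$i0
  asym <- mge_asymptote(p, e)
  if (abs(r - threshold) <= tol) return("threshold")
  if (asym < p$V0) return("regression")
  if (r < threshold) return("progression")
  "above_threshold"
}
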