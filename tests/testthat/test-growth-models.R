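test_that("Gompertz volume honors the initial condition and plateau", {
  set.seed(11)
  for (rep in 1:25) {
    p <- gompertz_params(runif(1, 0.05, 2), runif(1, 0.1, 1), runif(1, 0.01, 0.2))
    expect_equal(gompertz_volume(0, p), p$V0)
    plateau <- p$V0 * exp(p$alpha / p$beta)
    expect_equal(gompertz_volume(1e4 / p$beta, p), plateau, tolerance = 1e-12)
    tt <- sort(runif(20, 0, 60))
    expect_true(all(diff(gompertz_volume(tt, p)) > 0))
    expect_true(all(gompertz_volume(tt, p) <= plateau))
  }
  # plateau for a typical fast-growing control parameter set
  p <- gompertz_params(0.5, 0.462, 0.024)
  expect_equal(gompertz_volume(1e6, p), 0.5 * exp(0.462 / 0.024),
               tolerance = 1e-10)
})

test_that("closed form agrees with numerical integration of the growth ODE", {
  skip_if_not_installed("deSolve")
  # d(log V)/dt = alpha - beta * log(V / V0): same law, independent route
  set.seed(21)
  for (rep in 1:10) {
    p <- gompertz_params(runif(1, 0.1, 1), runif(1, 0.2, 0.6), runif(1, 0.01, 0.1))
    times <- seq(0, 30, by = 1)
    sol <- deSolve::ode(
      y = c(lv = log(p$V0)), times = times,
      func = function(t, y, parms) {
        list(parms$alpha - parms$beta * (y[["lv"]] - log(parms$V0)))
      },
      parms = p, rtol = 1e-10, atol = 1e-12)
    expect_equal(exp(sol[, "lv"]), gompertz_volume(times, p),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("current-ratio terms follow their defining algebra", {
  z <- current_ratio_terms(0, 3)
  expect_equal(z, list(r = 0, a1 = 0, a2 = 1))
  z <- current_ratio_terms(4.2, 4.2)
  expect_equal(z, list(r = 1, a1 = 1, a2 = 0))
  # a fitted polarization current of 4.061 mA at 6 mA applied
  expect_equal(round(current_ratio_terms(6, 4.061)$r, 3), 1.477)
  set.seed(31)
  for (rep in 1:50) {
    i <- runif(1, 0, 8); i0 <- runif(1, 0.5, 8)
    z <- suppressWarnings(current_ratio_terms(i, i0))
    expect_equal(z$a1 + z$a2, 1 + z$r - z$r^2)
  }
  expect_error(current_ratio_terms(2, 0), "i0")
  expect_warning(current_ratio_terms(9, 4), "exceeds 2")
})

test_that("modified growth rate interpolates between its limits", {
  e <- echt_params(6, 4.061, 12.9)
  r <- 6 / 4.061
  expect_equal(alpha_star(0, 0.49, e), (1 - r) * 0.49)
  expect_equal(alpha_star(1e3, 0.49, e), (1 + r - r^2) * 0.49, tolerance = 1e-12)
  # no treatment: rate reverts to alpha at all times
  e0 <- echt_params(0, 1, 5)
  expect_equal(alpha_star(c(0, 1, 10), 0.4, e0), rep(0.4, 3))
  # golden-ratio current ratio nulls the asymptotic rate
  gr <- (1 + sqrt(5)) / 2
  eg <- echt_params(gr * 2, 2, 1)
  expect_equal(alpha_star(1e4, 0.5, eg), 0, tolerance = 1e-10)
})

test_that("MGE reduces to Gompertz without current and has the stated asymptote", {
  p <- gompertz_params(0.5, 0.49, 0.055)
  tt <- seq(0, 100, by = 0.1)
  e0 <- echt_params(0, 3, 8)
  expect_identical(mge_volume(tt, p, e0), gompertz_volume(tt, p))
  expect_equal(mge_volume(0, p, echt_params(6, 4.061, 12.9)), p$V0)
  set.seed(41)
  for (rep in 1:20) {
    p <- gompertz_params(runif(1, 0.1, 1), runif(1, 0.2, 0.6),
                         runif(1, 0.02, 0.1))
    i <- runif(1, 0, 3)
    e <- echt_params(i, runif(1, max(0.8, i / 1.9), 4), runif(1, 0.2, 5))
    expect_equal(mge_volume(0, p, e), p$V0)
    thoriz <- 50 / min(p$beta, max(e$gamma, 1e-3))
    expect_equal(mge_volume(thoriz, p, e), mge_asymptote(p, e),
                 tolerance = 1e-6)
  }
  # beyond the golden ratio the model predicts net regression
  p <- gompertz_params(0.5, 0.49, 0.055)
  e_reg <- echt_params(7, 4, 5)  # r = 1.75 > (1 + sqrt(5))/2
  expect_lt(mge_asymptote(p, e_reg), p$V0)
})

test_that("analytic doubling time matches root finding and its limits", {
  p <- gompertz_params(0.5, 0.462, 0.024)
  dt <- analytic_doubling_time(p)
  expect_equal(gompertz_volume(dt, p), 2 * p$V0, tolerance = 1e-9)
  bis <- uniroot(function(t) gompertz_volume(t, p) - 2 * p$V0,
                 c(0, 100), tol = 1e-12)$root
  expect_equal(dt, bis, tolerance = 1e-9)
  # beta -> 0 limit tends to the exponential doubling time
  expect_equal(analytic_doubling_time(gompertz_params(0.5, 0.4, 1e-8)),
               log(2) / 0.4, tolerance = 1e-6)
  # plateau below 2 V0: never doubles
  expect_identical(analytic_doubling_time(gompertz_params(1, 0.1, 0.1 / log(2))),
                   Inf)
  expect_identical(analytic_doubling_time(gompertz_params(1, 0.05, 0.2)), Inf)
})

test_that("Steel relation and growth fraction behave as defined", {
  expect_equal(steel_doubling_time(1, 0, 1), 1)
  expect_equal(steel_doubling_time(2, 0.5, 0.5), 2 * log(2) / (0.5 * log(1.5)))
  dts <- vapply(seq(0, 0.9, by = 0.1), steel_doubling_time,
                numeric(1), Tc = 3, GF = 0.4)
  expect_true(all(diff(dts) > 0))
  expect_error(steel_doubling_time(1, 1, 0.5), "phi")
  expect_error(steel_doubling_time(1, 0.2, 0), "GF")
  expect_equal(growth_fraction(30, 70), 0.3)
  expect_error(growth_fraction(0, 0), "at least one")
})

test_that("response regime classifies asymptotic behavior", {
  p <- gompertz_params(0.5, 0.49, 0.05)
  expect_identical(response_regime(p, echt_params(0, 1, 0)), "progression")
  gr <- (1 + sqrt(5)) / 2
  expect_equal(mge_asymptote(p, echt_params(gr * 3, 3, 1)), p$V0,
               tolerance = 1e-12)
  expect_identical(response_regime(p, echt_params(7, 4, 5)), "regression")
  # a fitted ratio of 1.477 stays below the 1.50 complete-response threshold
  e <- echt_params(6, 4.061, 12.9)
  expect_lt(e$i / e$i0, 1.50)
  expect_identical(response_regime(p, e, threshold = 1.50, tol = 0.01),
                   "progression")
  expect_identical(response_regime(p, echt_params(1.5, 1, 1)), "threshold")
})

test_that("parameter bundles reject invalid domains", {
  expect_error(gompertz_params(0, 0.4, 0.02), "V0")
  expect_error(gompertz_params(0.5, -1, 0.02), "alpha")
  expect_error(gompertz_params(0.5, 0.4, 0), "exp_growth_volume")
  expect_error(echt_params(-1, 2, 1), "'i'")
  expect_error(echt_params(2, 0, 1), "i0")
  expect_equal(exp_growth_volume(3, 0.5, 0.231), 0.5 * exp(0.693),
               tolerance = 1e-12)
})
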