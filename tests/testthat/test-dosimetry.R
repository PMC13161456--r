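test_that("noise-free biexponential parameters are recovered exactly", {
  t <- c(2, 24, 48, 168)
  p0 <- c(A1 = 10, A2 = -6, lambda1 = 0.01, lambda2 = 0.5)
  y <- p0["A1"] * exp(-p0["lambda1"] * t) + p0["A2"] * exp(-p0["lambda2"] * t)
  fit <- fit_biexp(times_h = t, conc = y)
  expect_false(fit$fallback)
  expect_true(all(abs(coef(fit) - p0) / abs(p0) < 1e-4))
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("pure monoexponential data yields the monoexponential integral", {
  t <- c(2, 24, 48, 168)
  y <- 8 * exp(-0.02 * t)
  fit <- fit_biexp(times_h = t, conc = y)
  tia <- time_integrated_concentration(fit)
  expect_equal(tia, 8 / 0.02, tolerance = 1e-3)
})

test_that("rates are recovered from noisy curves across replicates", {
  t <- c(2, 24, 48, 168)
  truth <- function(tt) 10 * exp(-0.01 * tt) - 6 * exp(-0.5 * tt)
  set.seed(99)
  l1 <- replicate(100, {
    y <- pmax(truth(t) * (1 + rnorm(4, 0, 0.05)), 0)
    unname(coef(fit_biexp(times_h = t, conc = y))["lambda1"])
  })
  expect_lt(abs(median(l1) - 0.01) / 0.01, 0.10)
})

test_that("the analytic integral matches adaptive quadrature to 0.1%", {
  set.seed(4)
  for (i in 1:20) {
    p <- c(A1 = runif(1, 1, 20), A2 = runif(1, -5, 5),
           lambda1 = runif(1, 0.005, 0.05), lambda2 = runif(1, 0.1, 1))
    fit <- structure(list(coefficients = p), class = "biexp_fit")
    tia <- time_integrated_concentration(fit)
    quad <- integrate(function(tt) p["A1"] * exp(-p["lambda1"] * tt) +
                        p["A2"] * exp(-p["lambda2"] * tt),
                      0, Inf, rel.tol = 1e-9)$value
    expect_equal(tia, quad, tolerance = 1e-3)
  }
  # exact cancellation
  fitc <- structure(list(coefficients = c(A1 = 3, A2 = -3, lambda1 = 0.2,
                                          lambda2 = 0.2)),
                    class = "biexp_fit")
  expect_equal(time_integrated_concentration(fitc), 0)
  bad <- structure(list(coefficients = c(A1 = 1, A2 = 0, lambda1 = -1,
                                         lambda2 = 1)), class = "biexp_fit")
  expect_error(time_integrated_concentration(bad), "positive")
})

test_that("degenerate series are rejected", {
  expect_error(fit_biexp(times_h = c(2, 24, 48, 168), conc = rep(0, 4)),
               "all-zero")
  expect_error(fit_biexp(times_h = c(2, 24), conc = c(1, 2)), "3 time points")
})

test_that("the fitted model behaves like a classed R model object", {
  s <- time_activity_series(c(2, 24, 48, 168), c(0.03, 0.05, 0.04, 0.013),
                            source = "L3")
  fit <- fit_biexp(s)
  expect_s3_class(fit, "biexp_fit")
  expect_named(coef(fit), c("A1", "A2", "lambda1", "lambda2"))
  expect_length(fitted(fit), 4)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit), s$conc, tolerance = 1e-12)
  expect_output(print(fit), "biexp_fit")
  expect_output(print(summary(fit)), "time-integrated")
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(4L, 3L))
})

test_that("absorbed dose follows the marrow constants (unit oracle)", {
  # hand unit analysis: 1 MBq.h/mL * 3.6e9 decays/(MBq.h) * 2.37e-14 J
  #   * 0.645 / (0.574 * 1.03e-3 kg/mL) = 0.09308 Gy -> 12.579 mGy/GBq at
  #   7.4 GBq injected
  d <- absorbed_dose(1, dosimetry_constants(), injected_GBq = 7.4)
  expect_equal(d$dose_mGy_per_GBq, 12.5785, tolerance = 1e-4)
  expect_equal(absorbed_dose(0)$dose_mGy_per_GBq, 0)
  expect_equal(absorbed_dose(2)$dose_mGy_per_GBq,
               2 * absorbed_dose(1)$dose_mGy_per_GBq)
  expect_error(absorbed_dose(-1), "non-negative")
  expect_error(dosimetry_constants(volume_fraction = 0))
})

test_that("delta AD has the documented sign convention", {
  expect_equal(delta_ad(2, 2), 0)
  expect_equal(delta_ad(2, 1), 0.5)
  expect_lt(delta_ad(1, 2), 0)
  expect_error(delta_ad(0, 1), "non-zero")
  d1 <- absorbed_dose(1); d2 <- absorbed_dose(2)
  expect_equal(delta_ad(d2, d1), 0.5)
})

test_that("time-activity CSV round trip preserves the series", {
  s <- list(L3 = time_activity_series(c(2, 24, 48, 168),
                                      c(0.03, 0.05, 0.04, 0.013), "L3"),
            L4 = time_activity_series(c(2, 24, 48, 168),
                                      c(0.02, 0.04, 0.03, 0.01), "L4"))
  path <- file.path(tempdir(), "tac.csv")
  write_tac_csv(s, path)
  r <- read_tac_csv(path)
  expect_named(r, c("L3", "L4"))
  expect_equal(r$L3$conc, s$L3$conc)
  expect_equal(r$L4$times_h, s$L4$times_h)
})
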