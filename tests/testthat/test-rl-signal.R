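# trace integration, dose-response slopes, linearity index, LCF

test_that("trace integration equals the closed-form N*h for random rectangular pulses", {
  set.seed(622)
  for (k in 1:100) {
    n_win <- sample(50:400, 1)
    h <- stats::runif(1, 0.5, 5000)
    b <- stats::runif(1, 0, 200)
    tr <- pulse_trace(n_win, h, b)
    expect_equal(integrate_trace(tr), n_win * h, tolerance = 1e-9)
  }
})

test_that("trace integration is invariant to constant offsets and linear in counts", {
  tr <- pulse_trace(100, 40, 10)
  d0 <- integrate_trace(tr)
  tr_shift <- tr
  tr_shift$counts <- tr$counts + 123.4
  expect_equal(integrate_trace(tr_shift), d0, tolerance = 1e-8)
  tr_scaled <- tr
  tr_scaled$counts <- tr$counts * 3
  expect_equal(integrate_trace(tr_scaled), 3 * d0, tolerance = 1e-9)
  # constant trace integrates to zero
  flat <- pulse_trace(100, 0, 7)
  expect_equal(integrate_trace(flat), 0)
})

test_that("background segments shorter than requested are refused", {
  tr <- pulse_trace(50, 10, 5, n_bg = 10)
  expect_error(integrate_trace(tr, n_background = 25), "shorter")
  expect_error(rl_trace(c(1, 2, -3), window = c(1, 2),
                        pre_background = c(1, 1),
                        post_background = c(3, 3)), "non-negative")
})

test_that("through-origin slope matches the closed-form estimator", {
  # exact line
  D <- c(0.2, 0.5, 1, 2, 5)
  s <- fit_dose_response(dose_response_set(D, 2.405 * D))
  expect_equal(s$slope, 2.405, tolerance = 1e-12)
  expect_equal(s$se, 0, tolerance = 1e-9)
  # noisy set vs independent closed form sum(D*y)/sum(D^2)
  set.seed(12)
  y <- 3.1 * D + stats::rnorm(5, 0, 0.1)
  got <- fit_dose_response(dose_response_set(D, y))$slope
  expect_equal(got, sum(D * y) / sum(D^2), tolerance = 1e-12)
  # adding a point at the origin leaves the slope unchanged
  got2 <- fit_dose_response(dose_response_set(c(D, 1e-12), c(y, 0)))$slope
  expect_equal(got2, got, tolerance = 1e-9)
})

test_that("linearity index: normalization at D0, hand-checked quadratic, scale invariance", {
  D <- c(0.5, 1, 2, 4)
  # perfectly linear -> index 1 everywhere
  lin <- linearity_index(dose_response_set(D, 7 * D))
  expect_equal(lin$index, rep(1, 4), tolerance = 1e-12)
  # y = D + 0.1 D^2 with D0 = 1: index(2) = (2.4/2)/(1.1/1) = 12/11
  sup <- linearity_index(dose_response_set(D, D + 0.1 * D^2))
  expect_equal(sup$index[sup$dose_gy == 2], 12 / 11, tolerance = 1e-12)
  expect_equal(sup$index[sup$dose_gy == 1], 1, tolerance = 1e-12)
  # invariant under common rescaling of the signal
  sup2 <- linearity_index(dose_response_set(D, 5 * (D + 0.1 * D^2)))
  expect_equal(sup2$index, sup$index, tolerance = 1e-12)
  # D0 outside the measured range
  expect_error(linearity_index(dose_response_set(c(2, 4), c(2, 4))),
               "outside")
})

test_that("LCF fit round-trips the published cubic to 1e-10", {
  # '38 um' carbon-400 correction: -0.02 D^3 + 0.09 D^2 - 0.07 D + 1.01
  co <- c(1.01, -0.07, 0.09, -0.02)
  D <- seq(0.2, 3, length.out = 10)
  idx <- drop(outer(D, 0:3, `^`) %*% co)
  fit <- fit_lcf(D, idx, degree = 3)
  expect_equal(fit$coefficients, co, tolerance = 1e-10)
  # constant index 1 -> identity polynomial
  fit1 <- fit_lcf(D, rep(1, 10), degree = 3)
  expect_equal(fit1$coefficients, c(1, 0, 0, 0), tolerance = 1e-10)
  expect_error(fit_lcf(c(1, 2, 3), c(1, 1, 1), degree = 3), "distinct")
})

test_that("published LCF system: degrees, evaluation, correction direction", {
  presets <- lcf_presets()
  degs <- vapply(presets, `[[`, 0L, "degree")
  expect_identical(unname(degs[names(degs) == "single_crystal.He150"]), 4L)
  expect_true(all(degs[names(degs) != "single_crystal.He150"] == 3L))
  # printed '38 um' C400 value at 1 Gy: -0.02 + 0.09 - 0.07 + 1.01 = 1.01
  l38 <- presets[["grain_38um.C400"]]
  expect_equal(lcf_eval(l38, 1), 1.01, tolerance = 1e-12)
  expect_equal(apply_lcf(2.02, l38, 1), 2, tolerance = 1e-12)
  # identity LCF leaves values unchanged
  ident <- linearity_correction(c(1, 0, 0, 0), validity_range = c(0.1, 60))
  expect_equal(apply_lcf(5, ident, 3), 5)
  # extrapolation is refused
  expect_error(apply_lcf(1, l38, 1e4), "validity")
})

test_that("apply_lcf after fit_lcf restores a supralinear index to 1 within 0.5%", {
  D <- seq(0.25, 6, length.out = 12)
  y <- 100 * (D + 0.03 * D^2 + 0.002 * D^3)
  set <- dose_response_set(D, y)
  idx <- linearity_index(set)
  fit <- fit_lcf(idx$dose_gy, idx$index, degree = 3)
  y_corr <- apply_lcf(y, fit, D)
  idx_corr <- linearity_index(dose_response_set(D, y_corr))
  expect_true(all(abs(idx_corr$index - 1) < 0.005))
})

test_that("trace round-trips through CSV plus YAML sidecar", {
  tr <- pulse_trace(80, 33.5, 12)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$counts, tr$counts)
  expect_identical(back$window, tr$window)
  expect_equal(integrate_trace(back), integrate_trace(tr))
  unlink(c(f, paste0(f, ".yaml")))
})

test_that("dose-response CSV round trip", {
  set <- dose_response_set(c(0.5, 1, 2), c(50, 101, 205),
                           probe = "grain_4um", beam = "He150")
  f <- tempfile(fileext = ".csv")
  write_dose_response_csv(set, f)
  back <- read_dose_response_csv(f)
  expect_equal(back$dose_gy, set$dose_gy)
  expect_equal(back$delta_rl, set$delta_rl)
  expect_identical(back$probe, "grain_4um")
  unlink(f)
})
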