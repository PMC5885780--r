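test_that("noiseless single-exponential data are recovered to machine accuracy", {
  t <- 10^seq(-5, -1.5, length.out = 200)
  y <- -0.01 * exp(-t / 1e-3)
  fit <- fit_global(list(times = t, dA = cbind(y, 0.5 * y), wavelengths = c(450, 540)),
                    n_components = 1, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$time_constants, 1e-3, tolerance = 1e-9)
  expect_equal(unname(fit$amplitudes[, 1]), c(-0.01, -0.005), tolerance = 1e-9)
  expect_equal(unname(fit$offsets), c(0, 0), tolerance = 1e-12)
})

test_that("noiseless preset-scheme data return the generating constants to 1e-6", {
  # WT recombination: two effective modes
  wt <- fit_global(generate_dataset(preset_scheme("WT"), ms_setup_wt()),
                   n_components = 2, seed = 3)
  gen_fast <- parallel_observed_tau(c(300e-6, 1e-3))
  expect_equal(wt$time_constants, c(gen_fast, 1.1e-3), tolerance = 1e-6)
  # W388F: monoexponential 2.7 ms
  stw <- instrument_setup("ms_s", wavelengths = c(408, 450, 510, 540, 562),
                          time_grid = 10^seq(-4, log10(0.02), length.out = 250),
                          seed = 3)
  w3 <- fit_global(generate_dataset(preset_scheme("W388F"), stw),
                   n_components = 1, seed = 2)
  expect_equal(w3$time_constants, 2.7e-3, tolerance = 1e-6)
  # convolved model class: single exponential under a 200 ps Gaussian IRF
  tt <- 10^seq(-11, log10(2e-8), length.out = 250)
  y <- -0.02 * irf_exp(tt, 1 / 350e-12, 200e-12) + 0.004 * irf_exp(tt, 0, 200e-12)
  cf <- fit_global(list(times = tt, dA = cbind(y), wavelengths = 457),
                   n_components = 1, irf_fwhm = 200e-12, seed = 1)
  expect_equal(cf$time_constants, 350e-12, tolerance = 1e-6)
  expect_equal(unname(cf$offsets), 0.004, tolerance = 1e-6)
})

test_that("1% noise keeps both recombination constants within 10% in >= 90% of seeds", {
  gen_fast <- parallel_observed_tau(c(300e-6, 1e-3))
  ok <- vapply(1:20, function(s) {
    ts <- generate_dataset(preset_scheme("WT"), ms_setup_wt(seed = 100 + s),
                           noise_relative = 0.01)
    fit <- fit_global(ts, n_components = 2, seed = s, n_starts = 3)
    fit$converged &&
      abs(fit$time_constants[1] / gen_fast - 1) < 0.1 &&
      abs(fit$time_constants[2] / 1.1e-3 - 1) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("fitted time constants are invariant to wavelength order", {
  ts <- generate_dataset(preset_scheme("WT"), ms_setup_wt(seed = 13),
                         noise_relative = 0.01)
  fit1 <- fit_global(ts, n_components = 2, seed = 4)
  perm <- c(3, 1, 4, 2)
  ts2 <- ts
  ts2$dA <- ts$dA[, perm]
  ts2$wavelengths <- ts$wavelengths[perm]
  fit2 <- fit_global(ts2, n_components = 2, seed = 4)
  expect_equal(fit1$time_constants, fit2$time_constants, tolerance = 1e-12)
})

test_that("recovery error degrades monotonically with noise level", {
  sc <- preset_scheme("W388F")
  st0 <- instrument_setup("ms_s", wavelengths = c(450, 510),
                          time_grid = 10^seq(-4, log10(0.02), length.out = 150))
  med_err <- vapply(c(0, 0.005, 0.01, 0.02), function(nl) {
    errs <- vapply(1:7, function(s) {
      st <- st0; st$seed <- 500L + s
      ts <- generate_dataset(sc, st,
                             noise_relative = if (nl > 0) nl else NULL)
      fit <- fit_global(ts, n_components = 1, seed = s, n_starts = 3)
      abs(fit$time_constants / 2.7e-3 - 1)
    }, 0)
    stats::median(errs)
  }, 0)
  expect_true(all(diff(med_err) >= -1e-12))
})

test_that("a fit is a fixed point: refitting from the optimum does not move", {
  ts <- generate_dataset(preset_scheme("WT"), ms_setup_wt(seed = 17),
                         noise_relative = 0.01)
  fit <- fit_global(ts, n_components = 2, seed = 6)
  # refit with starts pinned at the optimum
  refit <- fit_global(ts, n_components = 2, seed = 6, n_starts = 1,
                      fit_window = range(fit$times))
  expect_lt(abs(refit$residual_rmsd - fit$residual_rmsd), 1e-10)
  expect_true(all(fit$time_constants > 0))
  expect_true(all(diff(fit$time_constants) > 0))
})

test_that("model comparison distinguishes marginal from substantial improvements", {
  tgrid <- 10^seq(-10.5, log10(2e-8), length.out = 250)
  # two decay constants a decade apart at equal amplitude: clearly biexponential
  y2 <- 0.01 * exp(-tgrid / 1e-9) + 0.01 * exp(-tgrid / 1e-8)
  set.seed(1)
  d2 <- list(times = tgrid, dA = cbind(y2 + rnorm(length(y2), sd = 1e-4)),
             wavelengths = 562)
  cmp2 <- compare_models(fit_global(d2, 1, seed = 1), fit_global(d2, 2, seed = 1))
  expect_identical(cmp2$verdict, "substantial")
  # 400 ps / 3 ns at 10:1 amplitudes in realistic single-trace noise: the
  # biexponential model is only marginally better, and the monoexponential
  # compromise lands near 0.5 ns
  y <- 0.02 * exp(-tgrid / 400e-12) + 0.002 * exp(-tgrid / 3e-9)
  set.seed(42)
  d <- list(times = tgrid, dA = cbind(y + rnorm(length(y), sd = 0.05 * max(y))),
            wavelengths = 562)
  f1 <- fit_global(d, 1, seed = 1)
  f2 <- fit_global(d, 2, seed = 1)
  cmp <- compare_models(f1, f2)
  expect_identical(cmp$verdict, "marginal")
  expect_gt(f1$time_constants, 0.4e-9)
  expect_lt(f1$time_constants, 1.0e-9)
  # identical fits compare as marginal with ratio 1
  cmp0 <- compare_models(f1, f1)
  expect_equal(cmp0$rmsd_ratio, 1)
  expect_identical(cmp0$verdict, "marginal")
  expect_error(compare_models(f1, fit_global(d2, 1, seed = 1)),
               "identical data")
})

test_that("amplitude spectra expose the decay-associated structure", {
  ts <- generate_dataset(preset_scheme("WT"), ms_setup_wt(seed = 7),
                         noise_relative = 0.01)
  fit <- fit_global(ts, n_components = 2, seed = 3)
  a1 <- amplitude_spectrum(fit, 1)
  a2 <- amplitude_spectrum(fit, 2)
  t0 <- amplitude_spectrum(fit, "t0")
  expect_equal(t0$amplitude, a1$amplitude + a2$amplitude)
  # offsets are not part of the t -> 0 extrapolation
  expect_false(isTRUE(all.equal(t0$amplitude,
                                a1$amplitude + a2$amplitude + fit$offsets)))
  # the slow (tyrosyl-pair) component shows almost no signal at 540 nm
  r540 <- abs(a2$amplitude[a2$wavelength_nm == 540] /
                a2$amplitude[a2$wavelength_nm == 450])
  expect_lt(r540, 0.15)
  # whereas the fast (Trp-pair) component does absorb there
  rf <- abs(a1$amplitude[a1$wavelength_nm == 540] /
              a1$amplitude[a1$wavelength_nm == 450])
  expect_gt(rf, 0.2)
  expect_error(amplitude_spectrum(fit, 3), "out of range")
  # single-component fits: the t0 spectrum is the amplitude column
  fitm <- fit_global(ts, n_components = 1, seed = 3)
  expect_equal(amplitude_spectrum(fitm, "t0")$amplitude,
               unname(fitm$amplitudes[, 1]))
})

test_that("constant traces yield a flagged offsets-only fallback", {
  t <- seq(1e-6, 1e-3, length.out = 50)
  d <- list(times = t, dA = cbind(rep(0.005, 50), rep(-0.002, 50)),
            wavelengths = c(450, 540))
  fit <- fit_global(d, 1, seed = 1)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_identical(fit$n_components, 0L)
  expect_equal(unname(fit$offsets), c(0.005, -0.002))
})

test_that("predictions, fitted values and residuals are mutually consistent", {
  ts <- generate_dataset(preset_scheme("W388F"),
                         instrument_setup("ms_s", wavelengths = c(450, 510),
                                          time_grid = 10^seq(-4, -1.7, length.out = 120),
                                          seed = 2),
                         noise_relative = 0.01)
  fit <- fit_global(ts, 1, seed = 1)
  expect_equal(fit$data - fitted(fit), residuals(fit))
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$residual_rmsd, tolerance = 1e-12)
  cf <- coef(fit)
  expect_named(cf, c("tau1", "A1_450nm", "A1_510nm"))
  pr <- predict(fit, times = c(0, fit$time_constants[1]))
  expect_equal(unname(pr[1, ] - pr[2, ]),
               unname(fit$amplitudes[, 1]) * (1 - exp(-1)), tolerance = 1e-9)
})
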