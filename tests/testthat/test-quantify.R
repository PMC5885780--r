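wt_actinometry <- function(...)
  actinometry_input(dA_sample = -0.023, dA_ref = -0.097,
                    delta_eps_sample = -3525, eps_exc_sample = 9460,
                    c_sample = 40e-6, ...)

test_that("relative actinometry reproduces both reported quantum yields", {
  # WT: the printed signal amplitudes carry two significant figures, so the
  # computed yield is checked against the reported 55.4% within the rounding
  # that those inputs can propagate
  qy_wt <- quantum_yield(wt_actinometry())
  expect_equal(100 * qy_wt$phi, 55.4, tolerance = 0.005)
  expect_true(qy_wt$plausible)
  # W388F: 3.7% at printed precision
  qy_w3 <- quantum_yield(actinometry_input(
    dA_sample = -0.002, dA_ref = -0.108, delta_eps_sample = -4315,
    eps_exc_sample = 9460, c_sample = 38.5e-6))
  expect_equal(round(100 * qy_w3$phi, 1), 3.7)
})

test_that("a sample identical to the reference returns the reference yield", {
  inp <- actinometry_input(dA_sample = -0.097, dA_ref = -0.097,
                           delta_eps_sample = -11000, delta_eps_ref = -11000,
                           eps_exc_sample = 10128, eps_exc_ref = 10128,
                           c_sample = 27.4e-6, c_ref = 27.4e-6, phi_ref = 1)
  expect_equal(quantum_yield(inp)$phi, 1)
})

test_that("the yield is invariant to a common rescaling of both amplitudes", {
  base <- quantum_yield(wt_actinometry())$phi
  for (f in c(0.1, 3, 117)) {
    scaled <- actinometry_input(dA_sample = -0.023 * f, dA_ref = -0.097 * f,
                                delta_eps_sample = -3525,
                                eps_exc_sample = 9460, c_sample = 40e-6)
    expect_equal(quantum_yield(scaled)$phi, base, tolerance = 1e-12)
  }
})

test_that("absorbed fraction follows 1 - 10^(-eps c d)", {
  expect_equal(absorbed_fraction(10128, 27.4e-6, 0.2),
               1 - 10^(-10128 * 27.4e-6 * 0.2))
  expect_equal(absorbed_fraction(10128, 27.4e-6, 0.2), 0.1200, tolerance = 1e-3)
  expect_equal(absorbed_fraction(0, 1, 1), 0)
  expect_equal(absorbed_fraction(1e6, 1, 1), 1)
  expect_error(absorbed_fraction(-1, 1, 1), "non-negative")
})

test_that("thin-sample limit reduces to the absorbance-normalized amplitude ratio", {
  # as eps*c*d -> 0 the absorbed fraction tends to ln(10)*eps*c*d, so the
  # yield tends to the amplitude ratio normalized by excitation absorbance
  shrink <- 1e-4
  inp <- actinometry_input(dA_sample = -0.023, dA_ref = -0.097,
                           delta_eps_sample = -3525, eps_exc_sample = 9460,
                           c_sample = 40e-6 * shrink, c_ref = 27.4e-6 * shrink)
  limit <- ((-0.023) / (-3525) / (9460 * 40e-6)) /
    ((-0.097) / (-11000) / (10128 * 27.4e-6))
  expect_equal(quantum_yield(inp)$phi, limit, tolerance = 1e-3)
  # with equal excitation absorptivities this is the concentration-normalized
  # amplitude ratio
  inp2 <- actinometry_input(dA_sample = -0.023, dA_ref = -0.097,
                            delta_eps_sample = -3525,
                            eps_exc_sample = 10128, eps_exc_ref = 10128,
                            c_sample = 40e-6 * shrink, c_ref = 27.4e-6 * shrink)
  limit2 <- ((-0.023) / (-3525) / (40e-6)) / ((-0.097) / (-11000) / (27.4e-6))
  expect_equal(quantum_yield(inp2)$phi, limit2, tolerance = 1e-3)
})

test_that("implausible yields are flagged with a warning", {
  inp <- actinometry_input(dA_sample = -0.23, dA_ref = -0.097,
                           delta_eps_sample = -3525, eps_exc_sample = 9460,
                           c_sample = 40e-6)
  expect_warning(qy <- quantum_yield(inp), "outside")
  expect_false(qy$plausible)
  expect_error(actinometry_input(dA_sample = -0.023, dA_ref = -0.097,
                                 delta_eps_sample = 0, eps_exc_sample = 9460,
                                 c_sample = 40e-6), "nonzero")
})

test_that("decomposition recovers an exact member of the candidate set", {
  reg <- the_registry()
  cands <- pair_candidates(reg)
  wl <- c(380, 408, 450, 457, 510, 540, 562, 594, 630)
  cd <- 6.5e-6  # concentration times path
  amp <- data.frame(wavelength_nm = wl,
                    amplitude = cd * eval_spectrum(cands[[2]], wl))
  dec <- decompose_amplitudes(amp, cands, registry = reg)
  expect_identical(dec$best_candidate, "FAD_radanion+Trp_rad")
  best <- dec$ranking[1, ]
  expect_equal(best$coefficient, cd, tolerance = 1e-10)
  expect_lt(best$rmsd, 1e-12 * max(abs(amp$amplitude)))
})

test_that("synthetic wild-type amplitudes are assigned to the deprotonated pair", {
  reg <- the_registry()
  wl <- c(380, 408, 450, 457, 510, 540, 562, 594, 630)
  st <- instrument_setup("ns_us", wavelengths = wl, seed = 2)
  ts <- generate_dataset(preset_scheme("WT"), st, registry = reg,
                         noise_relative = 0.01)
  fit <- fit_global(ts, n_components = 1, seed = 3)
  dec <- decompose_amplitudes(amplitude_spectrum(fit, "t0"), pair_candidates(reg),
                              registry = reg)
  expect_identical(dec$best_candidate, "FAD_radanion+Trp_rad")
  rk <- dec$ranking
  expect_lt(rk$rmsd[rk$candidate == "FAD_radanion+Trp_rad"],
            rk$rmsd[rk$candidate == "FAD_radanion+TrpH_cat"])
})

test_that("synthetic W388F plateau amplitudes are assigned to the tyrosyl pair", {
  reg <- the_registry()
  wl <- c(380, 408, 450, 457, 510, 540, 562, 594, 630)
  st <- instrument_setup("ms_s", wavelengths = wl,
                         time_grid = 10^seq(-4, log10(0.02), length.out = 200),
                         seed = 6)
  ts <- generate_dataset(preset_scheme("W388F"), st, registry = reg,
                         noise_relative = 0.01)
  fit <- fit_global(ts, n_components = 1, seed = 2)
  dec <- decompose_amplitudes(amplitude_spectrum(fit, 1), pair_candidates(reg),
                              registry = reg)
  expect_identical(dec$best_candidate, "FAD_radanion+Tyr_rad")
})

test_that("a 7% hydrated-electron admixture is quantified by the joint fit", {
  reg <- the_registry()
  # freshly formed pair (protonated Trp) with the UV-excitation artifact
  sc <- kinetic_scheme(
    states = c("pair", "ground"),
    species = list(pair = c("FAD_radanion", "TrpH_cat"), ground = "FAD_ox"),
    transitions = data.frame(from = "pair", to = "ground", rate = 1 / 350e-12),
    initial = c(pair = 1), ground = "ground", id = "fresh_pair")
  wl <- c(380, 408, 457, 510, 540, 562, 594, 630, 680, 720)
  st <- instrument_setup("ps_ns", wavelengths = wl,
                         time_grid = c(1e-13, 2e-13), seed = 1)
  ts <- generate_dataset(sc, st, registry = reg, convolve_irf = FALSE,
                         eaq_fraction = 0.07)
  amp <- data.frame(wavelength_nm = wl, amplitude = ts$dA[1, ])
  dec <- decompose_amplitudes(
    amp, pair_candidates(reg)["FAD_radanion+TrpH_cat"],
    include_eaq = TRUE, registry = reg)
  ratio <- dec$coefficients[["e_aq"]] / dec$coefficients[[1]]
  expect_equal(ratio, 0.07, tolerance = 0.01)
})

test_that("enlarging the candidate set never worsens the joint residual", {
  reg <- the_registry()
  cands <- pair_candidates(reg)
  wl <- c(380, 408, 450, 457, 510, 540, 562, 594, 630)
  set.seed(3)
  amp <- data.frame(wavelength_nm = wl,
                    amplitude = 5e-6 * eval_spectrum(cands[[2]], wl) +
                      rnorm(length(wl), sd = 1e-3))
  r1 <- decompose_amplitudes(amp, cands[2], registry = reg)$joint_rmsd
  r2 <- decompose_amplitudes(amp, cands[c(2, 3)], registry = reg)$joint_rmsd
  r3 <- decompose_amplitudes(amp, cands, registry = reg)$joint_rmsd
  expect_lte(r2, r1 + 1e-15)
  expect_lte(r3, r2 + 1e-15)
})

test_that("decomposition flags collinear designs and honors non-negativity", {
  reg <- the_registry()
  cands <- pair_candidates(reg)
  wl <- c(450, 457)  # two wavelengths, three near-collinear candidates
  amp <- data.frame(wavelength_nm = wl,
                    amplitude = 6e-6 * eval_spectrum(cands[[2]], wl))
  expect_warning(dec <- decompose_amplitudes(amp, cands, registry = reg),
                 "collinear")
  expect_true(dec$conditioning_warning)
  wl9 <- c(380, 408, 450, 457, 510, 540, 562, 594, 630)
  ampn <- data.frame(wavelength_nm = wl9,
                     amplitude = -6e-6 * eval_spectrum(cands[[2]], wl9))
  dn <- decompose_amplitudes(ampn, cands[2], nonneg = TRUE, registry = reg)
  expect_gte(dn$coefficients[[1]], 0)
  expect_error(decompose_amplitudes(ampn[1, , drop = FALSE], cands),
               "at least two")
})
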