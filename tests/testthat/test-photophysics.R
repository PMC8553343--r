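test_that("Forster-Hoffmann fit reproduces an exact log-log line", {
  s <- emission_series(c(1, 10, 100), c(10, 100, 1000), "viscosity")
  fit <- fit_forster_hoffmann(s)
  expect_equal(fit$slope_x, 1)
  expect_equal(fit$intercept_c, 1)
  expect_equal(fit$pearson_r, 1)
  expect_identical(fit$n, 3L)
})

test_that("Forster-Hoffmann fit matches a normal-equations oracle on noisy data", {
  cfg <- spectra_config(rel_noise = 0.01, seed = 1L)
  s <- gen_viscosity_series(cfg)
  fit <- fit_forster_hoffmann(s)
  oracle <- ols_oracle(log10(s$condition), log10(s$intensity))
  expect_equal(fit$intercept_c, oracle[1], tolerance = 1e-10)
  expect_equal(fit$slope_x, oracle[2], tolerance = 1e-10)
  expect_equal(fit$pearson_r,
               pearson_oracle(log10(s$condition), log10(s$intensity)),
               tolerance = 1e-12)
  # slope recovered within +/- 0.02 of the configured value at 1% noise
  expect_lt(abs(fit$slope_x - cfg$slope_x), 0.02)
})

test_that("fit on noise-free generated data recovers generator parameters", {
  cfg <- spectra_config(rel_noise = 0, slope_x = 0.55, intercept_c = 1.7)
  fit <- fit_forster_hoffmann(gen_viscosity_series(cfg))
  expect_equal(fit$slope_x, 0.55, tolerance = 1e-9)
  expect_equal(fit$intercept_c, 1.7, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
})

test_that("Forster-Hoffmann fit rejects degenerate and invalid input", {
  expect_error(fit_forster_hoffmann(emission_series(5, 10, "viscosity")),
               "2 points")
  expect_error(
    fit_forster_hoffmann(emission_series(c(5, 5), c(1, 2), "viscosity")),
    "degenerate")
  expect_error(emission_series(c(-1, 2), c(1, 2), "viscosity"), "positive")
  expect_error(
    fit_forster_hoffmann(emission_series(c(1, 2), c(0, 2), "viscosity")),
    "positive")
})

test_that("viscosity inversion is the exact inverse of prediction", {
  fit <- structure(list(slope_x = 1, intercept_c = 1), class = "fh_fit")
  expect_equal(invert_viscosity(fit, 100), 10)
  expect_equal(invert_viscosity(fit, 10^1), 1)  # intercept point: eta = 1
  # round trip on random viscosities under a nontrivial fit
  fit2 <- fit_forster_hoffmann(gen_viscosity_series(spectra_config()))
  withr::with_seed(7, {
    eta <- 10^runif(100, -0.5, 3.5)
    expect_equal(invert_viscosity(fit2, predict_intensity(fit2, eta)), eta,
                 tolerance = 1e-9)
  })
  fit0 <- structure(list(slope_x = 0, intercept_c = 1), class = "fh_fit")
  expect_error(invert_viscosity(fit0, 10), "non-invertible")
  expect_error(invert_viscosity(fit, -1), "positive")
})

test_that("titration fit recovers the calibration slope", {
  s <- emission_series(0:9, 11166.424 * (0:9), "titration")
  fit <- fit_titration(s)
  expect_equal(fit$slope_k, 11166.424, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  # two points: exact interpolating line
  fit2 <- fit_titration(emission_series(c(1, 3), c(10, 30), "titration"))
  expect_equal(fit2$slope_k, 10)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  # noisy generated series: within 2% of configured k, equals OLS oracle
  cfg <- spectra_config(seed = 2L)
  gen <- gen_ntr_titration(cfg)
  fit3 <- fit_titration(gen$series)
  oracle <- ols_oracle(gen$series$condition, gen$series$intensity)
  expect_equal(fit3$slope_k, oracle[2], tolerance = 1e-10)
  expect_equal(fit3$intercept, oracle[1], tolerance = 1e-10)
  expect_lt(abs(fit3$slope_k - cfg$titration_slope_k) / cfg$titration_slope_k, 0.02)
  expect_error(
    fit_titration(emission_series(c(2, 2), c(1, 5), "titration")),
    "degenerate")
})

test_that("blank_sigma is the n-1 sample standard deviation", {
  expect_equal(blank_sigma(rep(4.2, 5)), 0)
  expect_equal(blank_sigma(c(1, 2, 3)), 1)
  withr::with_seed(11, {
    draws <- rnorm(1000, 0, 77.883)
    expect_lt(abs(blank_sigma(draws) - 77.883) / 77.883, 0.05)
  })
  expect_error(blank_sigma(5), "2")
})

test_that("LOD follows the 3-sigma/k rule and its unit identities", {
  lod <- compute_lod(11166.424, 77.883)
  expect_equal(lod$lod_ug_per_ml, 3 * 77.883 / 11166.424)
  expect_equal(lod$lod_ng_per_ml, 1000 * lod$lod_ug_per_ml)
  expect_equal(compute_lod(3, 1)$lod_ug_per_ml, 1)
  expect_equal(compute_lod(5, 0)$lod_ug_per_ml, 0)
  expect_error(compute_lod(0, 1), ">")
  # homogeneity: scaling sigma and k together leaves the LOD unchanged
  for (f in c(0.1, 3, 1e4))
    expect_equal(compute_lod(11166.424 * f, 77.883 * f)$lod_ng_per_ml,
                 lod$lod_ng_per_ml, tolerance = 1e-12)
})

test_that("fold enhancement compares the viscosity extremes", {
  s <- emission_series(c(1, 10, 100), c(5, 5, 5), "viscosity")
  expect_equal(fold_enhancement(s), 1)
  # order of points must not matter
  s2 <- emission_series(c(100, 1, 10), c(50, 5, 20), "viscosity")
  expect_equal(fold_enhancement(s2), 10)
  expect_error(fold_enhancement(emission_series(3, 4, "viscosity")), "2 points")
})

test_that("emission series round-trips through its CSV format", {
  s <- emission_series(c(1.2, 10, 945), c(101.5, 300.25, 1827), "viscosity",
                       wavelength_nm = 610)
  path <- withr::local_tempfile(fileext = ".csv")
  write_emission_series(s, path)
  s2 <- read_emission_series(path)
  expect_equal(s2$condition, s$condition)
  expect_equal(s2$intensity, s$intensity)
  expect_identical(attr(s2, "kind"), "viscosity")
  expect_equal(attr(s2, "wavelength_nm"), 610)
})
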