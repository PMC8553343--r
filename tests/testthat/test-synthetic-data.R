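test_that("noise-free viscosity series lies exactly on the configured line", {
  cfg <- spectra_config(viscosities = c(1, 10, 100), slope_x = 1,
                        intercept_c = 1, rel_noise = 0)
  s <- gen_viscosity_series(cfg)
  expect_equal(s$intensity, c(10, 100, 1000))
  expect_equal(fit_forster_hoffmann(s)$pearson_r, 1, tolerance = 1e-12)
})

test_that("default slope is anchored to the 18-fold ethanol-glycerol ratio", {
  expect_equal(default_fh_slope(), log10(18) / log10(945 / 1.2))
  s <- gen_viscosity_series(spectra_config(rel_noise = 0))
  expect_equal(fold_enhancement(s), 18, tolerance = 1e-9)
})

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- spectra_config(rel_noise = 0.05, seed = 123L)
  expect_identical(gen_viscosity_series(cfg), gen_viscosity_series(cfg))
  expect_identical(gen_ntr_titration(cfg), gen_ntr_titration(cfg))
  ic <- image_config(seed = 5L)
  expect_identical(gen_tissue_image(ic), gen_tissue_image(ic))
  cc <- cohort_config(seed = 9L)
  expect_identical(gen_margin_cohort(cc), gen_margin_cohort(cc))
  # and different seeds actually differ
  cfg2 <- spectra_config(rel_noise = 0.05, seed = 124L)
  expect_false(identical(gen_viscosity_series(cfg)$intensity,
                         gen_viscosity_series(cfg2)$intensity))
})

test_that("titration generator matches its configured line and blank noise", {
  cfg <- spectra_config(blank_sd = 0, titration_slope_k = 11166.424,
                        titration_intercept = 0, titration_concs = 1)
  gen <- gen_ntr_titration(cfg)
  expect_equal(gen$series$intensity, 11166.424)
  expect_equal(gen$blanks, rep(0, cfg$n_blanks))
  # empty concentration list: empty series, blanks still produced
  cfg2 <- spectra_config(titration_concs = numeric(0), n_blanks = 5)
  gen2 <- gen_ntr_titration(cfg2)
  expect_equal(nrow(gen2$series), 0L)
  expect_length(gen2$blanks, 5L)
  # Monte-Carlo: blank SD converges to the configured sigma
  cfg3 <- spectra_config(blank_sd = 77.883, n_blanks = 1000L, seed = 4L)
  expect_lt(abs(blank_sigma(gen_ntr_titration(cfg3)$blanks) - 77.883) / 77.883,
            0.05)
})

test_that("spectra config rejects invalid parameters", {
  expect_error(spectra_config(viscosities = c(1, -2)), "positive")
  expect_error(spectra_config(titration_concs = c(-1, 2)), "non-negative")
  expect_error(spectra_config(titration_concs = c(1, 9.5)), "0-9.0")
  expect_error(spectra_config(rel_noise = 1), "< 1")
  expect_error(spectra_config(n_blanks = 1), "n_blanks")
})

test_that("tissue images carry truth tables consistent with the pixels", {
  cfg <- image_config(n_samples = 4L, seed = 8L)
  img <- gen_tissue_image(cfg)
  expect_true(all(img$ntr >= 0 & img$ntr <= 255))
  expect_true(all(img$vis >= 0 & img$vis <= 255))
  expect_identical(dim(img$ntr), c(cfg$height, cfg$width))
  expect_identical(nrow(img$truth), 4L)
  for (i in seq_len(nrow(img$truth))) {
    m <- img$labels == img$truth$blob_id[i]
    expect_identical(sum(m), img$truth$area[i])
    expect_identical(max(img$ntr[m]), img$truth$max_ntr[i])
    expect_identical(max(img$vis[m]), img$truth$max_vis[i])
  }
  # zero samples: background only
  img0 <- gen_tissue_image(image_config(n_samples = 0L))
  expect_identical(nrow(img0$truth), 0L)
  expect_identical(max(img0$labels), 0L)
  # constant blobs hit the class mean exactly
  imgc <- gen_tissue_image(image_config(
    n_samples = 3L, class_sd = 0,
    class_means = list(pos = c(200, 200)), seed = 2L))
  expect_true(all(imgc$truth$max_ntr == 200))
  expect_true(all(imgc$truth$max_vis == 200))
})

test_that("blob placement failure is reported with the blob index", {
  cfg <- image_config(width = 40L, height = 40L, n_samples = 30L,
                      blob_radius_range = c(10, 12), seed = 1L)
  expect_error(gen_tissue_image(cfg), "blob \\d+")
})

test_that("margin cohorts honor the study design", {
  cfg <- cohort_config(n_train_pairs = 9L, n_test_pos = 9L, n_test_neg = 26L,
                       seed = 1L)
  ch <- gen_margin_cohort(cfg)
  expect_identical(nrow(ch$training), 18L)            # 9 pairs
  expect_identical(nrow(ch$test), 35L)                # 35-piece margin set
  expect_identical(sum(ch$test$he_label == "P"), 9L)
  expect_identical(sum(ch$test$he_label == "N"), 26L)
  expect_true(all(table(ch$training$pair) == 2L))
  expect_setequal(unique(ch$training$class), c("cancerous", "noncancerous"))
  expect_true(all(ch$test$i_ntr %in% 0:255 & ch$test$i_vis %in% 0:255))
  # sd = 0: all rows of a class equal the class mean
  ch0 <- gen_margin_cohort(cohort_config(sd = 0, pos_mean = c(200, 190),
                                         neg_mean = c(110, 120)))
  expect_true(all(ch0$test$i_ntr[ch0$test$he_label == "P"] == 200))
  expect_true(all(ch0$test$i_vis[ch0$test$he_label == "N"] == 120))
})

test_that("cohort intensities converge to configured moments", {
  cfg <- cohort_config(n_test_pos = 10000L, n_test_neg = 0L,
                       pos_mean = c(150, 170), sd = 12, seed = 3L)
  ch <- gen_margin_cohort(cfg)
  n <- nrow(ch$test)
  se_mean <- 12 / sqrt(n)
  expect_lt(abs(mean(ch$test$i_ntr) - 150), 3 * se_mean)
  expect_lt(abs(mean(ch$test$i_vis) - 170), 3 * se_mean)
  # SD standard error ~ sd / sqrt(2 (n - 1)); quantization adds ~1/12 variance
  se_sd <- 12 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(ch$test$i_ntr) - sqrt(12^2 + 1 / 12)), 3 * se_sd + 0.01)
})
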