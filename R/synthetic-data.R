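## Synthetic-data generators: spectra, two-channel tissue images and
## margin cohorts with the statistical structure the analysis assumes,
## so every downstream stage is testable with known ground truth.

## Solvent viscosities at ~20 C used to anchor defaults: ethanol 1.2 cP,
## glycerol 945 cP (CRC Handbook values; implementation constants, not
## measured quantities -- override via `viscosities`).
ETHANOL_CP  <- 1.2
GLYCEROL_CP <- 945

#' Default Forster-Hoffmann slope
#'
#' Slope x solving `I(945 cP) / I(1.2 cP) = 18` under
#' `log10 I = c + x log10 eta`, i.e. `x = log10(18) / log10(945/1.2)`,
#' so the noise-free default series reproduces the rotor's ~18-fold
#' ethanol-to-glycerol enhancement by construction.
#'
#' @param fold the enhancement ratio to anchor to (default 18).
#' @param eta_lo,eta_hi the endpoint viscosities in cP.
#' @return the slope (dimensionless), about 0.4334 for the defaults.
#' @export
default_fh_slope <- function(fold = 18, eta_lo = ETHANOL_CP, eta_hi = GLYCEROL_CP) {
  log10(fold) / log10(eta_hi / eta_lo)
}

#' Spectra generator configuration
#'
#' Parameters for [gen_viscosity_series()] and [gen_ntr_titration()].
#' Defaults reproduce the probe's printed calibration: an 18-fold
#' ethanol-to-glycerol enhancement over 1.2-945 cP, and a titration with
#' slope 11166.424 intensity units per ug/mL and blank SD 77.883 over
#' the 0-9.0 ug/mL working range.
#'
#' @param viscosities viscosity grid in cP, strictly positive; default 8
#'   log-spaced points from ethanol (1.2 cP) to glycerol (945 cP).
#' @param slope_x Forster-Hoffmann slope; default [default_fh_slope()].
#' @param intercept_c Forster-Hoffmann intercept (log10 intensity).
#' @param rel_noise fractional (relative) intensity noise, in [0, 1).
#' @param titration_concs enzyme concentrations in ug/mL, within 0-9.0.
#' @param titration_slope_k titration slope (intensity per ug/mL).
#' @param titration_intercept titration intercept (intensity units).
#' @param blank_sd additive Gaussian noise SD for titration and blanks.
#' @param n_blanks number of blank replicates (>= 2).
#' @param seed integer RNG seed; generators are bit-reproducible given it.
#' @return A list of class `"spectra_config"`.
#' @export
spectra_config <- function(viscosities = 10^seq(log10(ETHANOL_CP), log10(GLYCEROL_CP),
                                                length.out = 8),
                           slope_x = default_fh_slope(),
                           intercept_c = 2,
                           rel_noise = 0,
                           titration_concs = seq(0, 9, by = 1),
                           titration_slope_k = 11166.424,
                           titration_intercept = 500,
                           blank_sd = 77.883,
                           n_blanks = 11,
                           seed = 1L) {
  if (!is.numeric(viscosities) || length(viscosities) == 0 || any(viscosities <= 0))
    stopf("`viscosities` must be strictly positive")
  if (any(titration_concs < 0))
    stopf("`titration_concs` must be non-negative")
  if (any(titration_concs > 9))
    stopf("`titration_concs` must lie within the 0-9.0 ug/mL working range")
  assert_scalar_num(rel_noise, "rel_noise", lower = 0)
  if (rel_noise >= 1) stopf("`rel_noise` must be < 1")
  assert_scalar_num(blank_sd, "blank_sd", lower = 0)
  n_blanks <- assert_count(n_blanks, "n_blanks", min = 2L)
  structure(list(viscosities = as.numeric(viscosities),
                 slope_x = slope_x, intercept_c = intercept_c,
                 rel_noise = rel_noise,
                 titration_concs = as.numeric(titration_concs),
                 titration_slope_k = titration_slope_k,
                 titration_intercept = titration_intercept,
                 blank_sd = blank_sd, n_blanks = n_blanks,
                 seed = as.integer(seed)),
            class = "spectra_config")
}

#' Generate a viscosity emission series
#'
#' Intensities follow the Forster-Hoffmann law with multiplicative
#' Gaussian noise: `I = 10^(c + x log10 eta) * (1 + e)`,
#' `e ~ Normal(0, rel_noise)`, clipped to stay positive. Spectra remain
#' real-valued (quantization to 8-bit integers happens only at the
#' image/cohort level).
#'
#' @param cfg a [spectra_config()].
#' @return an [emission_series()] of kind `"viscosity"` at 610 nm.
#' @export
gen_viscosity_series <- function(cfg) {
  stopifnot(inherits(cfg, "spectra_config"))
  ideal <- 10^(cfg$intercept_c + cfg$slope_x * log10(cfg$viscosities))
  noisy <- with_seed(cfg$seed, {
    eps <- if (cfg$rel_noise > 0)
      stats::rnorm(length(ideal), 0, cfg$rel_noise) else 0
    ideal * (1 + eps)
  })
  noisy <- pmax(noisy, .Machine$double.xmin)
  emission_series(cfg$viscosities, noisy, kind = "viscosity",
                  wavelength_nm = 610)
}

#' Generate a nitroreductase titration and blank replicates
#'
#' Intensities follow `I = k * conc + intercept + Normal(0, blank_sd)`;
#' blank replicates are drawn from `Normal(intercept, blank_sd)`.
#'
#' @param cfg a [spectra_config()].
#' @return a list with `series` (an [emission_series()] of kind
#'   `"titration"` at 520 nm; empty if `titration_concs` is empty) and
#'   `blanks` (numeric vector of length `n_blanks`).
#' @export
gen_ntr_titration <- function(cfg) {
  stopifnot(inherits(cfg, "spectra_config"))
  concs <- cfg$titration_concs
  out <- with_seed(cfg$seed, {
    noise <- if (cfg$blank_sd > 0 && length(concs))
      stats::rnorm(length(concs), 0, cfg$blank_sd) else rep(0, length(concs))
    i <- cfg$titration_slope_k * concs + cfg$titration_intercept + noise
    blanks <- cfg$titration_intercept +
      if (cfg$blank_sd > 0) stats::rnorm(cfg$n_blanks, 0, cfg$blank_sd)
      else rep(0, cfg$n_blanks)
    list(intensity = i, blanks = blanks)
  })
  list(series = emission_series(concs, out$intensity, kind = "titration",
                                wavelength_nm = 520),
       blanks = out$blanks)
}

#' Tissue-image generator configuration
#'
#' Parameters for [gen_tissue_image()], which emulates an imaged tray of
#' specimens: a Gaussian background with non-overlapping elliptical
#' specimen blobs whose pixels are drawn around per-class mean gray
#' levels in each channel.
#'
#' @param width,height image size in pixels.
#' @param n_samples number of specimen blobs (>= 0).
#' @param blob_radius_range min/max semi-axis length in pixels.
#' @param class_means named list mapping class (`pos`, `neg`,
#'   `one_high`, ...) to a `c(ntr, vis)` pair of mean gray levels.
#' @param class_sd per-pixel SD within a blob (gray levels).
#' @param background_mean,background_sd background Gaussian parameters.
#' @param seed integer RNG seed.
#' @return A list of class `"image_config"`.
#' @export
image_config <- function(width = 192L, height = 192L, n_samples = 5L,
                         blob_radius_range = c(8, 16),
                         class_means = list(pos = c(200, 200),
                                            neg = c(120, 120),
                                            one_high = c(200, 120)),
                         class_sd = 8,
                         background_mean = 10, background_sd = 4,
                         seed = 1L) {
  width <- assert_count(width, "width", 1L)
  height <- assert_count(height, "height", 1L)
  n_samples <- assert_count(n_samples, "n_samples", 0L)
  if (length(blob_radius_range) != 2L || any(blob_radius_range <= 0) ||
      blob_radius_range[1] > blob_radius_range[2])
    stopf("`blob_radius_range` must be an increasing positive pair")
  if (!length(class_means) || is.null(names(class_means)))
    stopf("`class_means` must be a named list of (ntr, vis) pairs")
  for (nm in names(class_means)) {
    mu <- class_means[[nm]]
    if (length(mu) != 2L || any(mu < 0) || any(mu > 255))
      stopf("class mean for '%s' must be a pair within [0, 255]", nm)
  }
  assert_scalar_num(class_sd, "class_sd", lower = 0)
  assert_scalar_num(background_sd, "background_sd", lower = 0)
  structure(list(width = width, height = height, n_samples = n_samples,
                 blob_radius_range = as.numeric(blob_radius_range),
                 class_means = class_means, class_sd = class_sd,
                 background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "image_config")
}

#' Generate a paired two-channel tissue image with ground truth
#'
#' Produces 8-bit nitroreductase- and viscosity-channel images of the
#' same field: Gaussian background plus `n_samples` non-overlapping
#' axis-aligned elliptical blobs. Blob classes cycle through
#' `names(class_means)`; every blob pixel is drawn from
#' `Normal(class mean, class_sd)` per channel, rounded and clipped to
#' [0, 255]. The truth table records each blob's class and planted
#' per-channel maximum, and `labels` is a label image (0 = background,
#' blob id elsewhere) usable as a segmentation ground-truth mask.
#'
#' @param cfg an [image_config()].
#' @return list with integer matrices `ntr` and `vis` (`height` x
#'   `width`, values in 0-255), data frame `truth` (`blob_id`, `class`,
#'   `center_row`, `center_col`, `a`, `b`, `area`, `max_ntr`,
#'   `max_vis`), and integer matrix `labels`.
#' @export
gen_tissue_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_config"))
  h <- cfg$height; w <- cfg$width
  with_seed(cfg$seed, {
    ntr <- matrix(stats::rnorm(h * w, cfg$background_mean, cfg$background_sd), h, w)
    vis <- matrix(stats::rnorm(h * w, cfg$background_mean, cfg$background_sd), h, w)
    labels <- matrix(0L, h, w)
    classes <- rep_len(names(cfg$class_means), max(cfg$n_samples, 1L))
    placed <- list()
    truth <- data.frame(blob_id = integer(), class = character(),
                        center_row = numeric(), center_col = numeric(),
                        a = numeric(), b = numeric(), area = integer(),
                        max_ntr = integer(), max_vis = integer())
    if (cfg$n_samples > 0) {
      rr <- cfg$blob_radius_range
      for (i in seq_len(cfg$n_samples)) {
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          a <- stats::runif(1, rr[1], rr[2])   # semi-axis, rows
          b <- stats::runif(1, rr[1], rr[2])   # semi-axis, cols
          rad <- max(a, b)
          if (2 * rad + 4 > min(h, w)) next
          cy <- stats::runif(1, rad + 2, h - rad - 1)
          cx <- stats::runif(1, rad + 2, w - rad - 1)
          # non-overlap by construction: bounding circles + 2 px gap
          clash <- FALSE
          for (p in placed)
            if (sqrt((cy - p[1])^2 + (cx - p[2])^2) < rad + p[3] + 2) {
              clash <- TRUE; break
            }
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok)
          stopf("could not place blob %d without overlap in 1000 attempts", i)
        placed[[length(placed) + 1L]] <- c(cy, cx, max(a, b))
        rows <- max(1L, floor(cy - a)):min(h, ceiling(cy + a))
        cols <- max(1L, floor(cx - b)):min(w, ceiling(cx + b))
        grid <- expand.grid(r = rows, cl = cols)
        inside <- ((grid$r - cy) / a)^2 + ((grid$cl - cx) / b)^2 <= 1
        px <- grid[inside, , drop = FALSE]
        mu <- cfg$class_means[[classes[i]]]
        idx <- cbind(px$r, px$cl)
        ntr[idx] <- stats::rnorm(nrow(px), mu[1], cfg$class_sd)
        vis[idx] <- stats::rnorm(nrow(px), mu[2], cfg$class_sd)
        labels[idx] <- i
        truth <- rbind(truth, data.frame(
          blob_id = i, class = classes[i], center_row = cy, center_col = cx,
          a = a, b = b, area = nrow(px), max_ntr = NA_integer_,
          max_vis = NA_integer_))
      }
    }
    ntr <- clip8(ntr); vis <- clip8(vis)
    storage.mode(ntr) <- "integer"; storage.mode(vis) <- "integer"
    # planted maxima are read off the final quantized images
    for (i in seq_len(nrow(truth))) {
      m <- labels == truth$blob_id[i]
      truth$max_ntr[i] <- max(ntr[m]); truth$max_vis[i] <- max(vis[m])
    }
    list(ntr = ntr, vis = vis, truth = truth, labels = labels)
  })
}

#' Margin-cohort generator configuration
#'
#' Parameters for [gen_margin_cohort()], which emulates the study design
#' of the ex vivo margin experiments: paired cancerous/noncancerous
#' training specimens and an H&E-labeled test set of resection margins.
#' Defaults mirror the hepatocellular cohort: 9 training pairs and a
#' 35-piece test set (9 tumor-involved, 26 tumor-free).
#'
#' @param n_train_pairs number of cancerous/noncancerous training pairs.
#' @param n_test_pos,n_test_neg test specimens with H&E label P / N.
#' @param pos_mean,neg_mean `c(ntr, vis)` mean max gray levels per class,
#'   within [0, 255].
#' @param sd per-specimen SD (gray levels), shared across classes.
#' @param seed integer RNG seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_train_pairs = 9L, n_test_pos = 9L, n_test_neg = 26L,
                          pos_mean = c(200, 200), neg_mean = c(120, 120),
                          sd = 10, seed = 1L) {
  n_train_pairs <- assert_count(n_train_pairs, "n_train_pairs", 1L)
  n_test_pos <- assert_count(n_test_pos, "n_test_pos", 0L)
  n_test_neg <- assert_count(n_test_neg, "n_test_neg", 0L)
  for (nm in c("pos_mean", "neg_mean")) {
    mu <- get(nm)
    if (length(mu) != 2L || any(mu < 0) || any(mu > 255))
      stopf("`%s` must be a pair within [0, 255]", nm)
  }
  assert_scalar_num(sd, "sd", lower = 0)
  structure(list(n_train_pairs = n_train_pairs, n_test_pos = n_test_pos,
                 n_test_neg = n_test_neg, pos_mean = as.numeric(pos_mean),
                 neg_mean = as.numeric(neg_mean), sd = sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

draw_class <- function(n, mu, sd) {
  cbind(clip8(stats::rnorm(n, mu[1], sd)), clip8(stats::rnorm(n, mu[2], sd)))
}

#' Generate a synthetic margin cohort
#'
#' Draws per-specimen maximal gray-scale intensities for both channels:
#' a training table of cancerous/noncancerous pairs (class tags) and a
#' test table with H&E labels `P`/`N`. Intensities are rounded to
#' integers and clipped to [0, 255], mirroring 8-bit imaging.
#'
#' @param cfg a [cohort_config()].
#' @return list with data frames `training` (`sample_id`, `pair`,
#'   `class`, `i_ntr`, `i_vis`) and `test` (`sample_id`, `i_ntr`,
#'   `i_vis`, `he_label`).
#' @export
gen_margin_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    np <- cfg$n_train_pairs
    ca <- draw_class(np, cfg$pos_mean, cfg$sd)
    nc <- draw_class(np, cfg$neg_mean, cfg$sd)
    training <- data.frame(
      sample_id = sprintf("train_%02d_%s", rep(seq_len(np), each = 2),
                          rep(c("ca", "nc"), np)),
      pair = rep(seq_len(np), each = 2),
      class = rep(c("cancerous", "noncancerous"), np),
      i_ntr = as.integer(t(cbind(ca[, 1], nc[, 1]))),
      i_vis = as.integer(t(cbind(ca[, 2], nc[, 2]))))
    pos <- draw_class(cfg$n_test_pos, cfg$pos_mean, cfg$sd)
    neg <- draw_class(cfg$n_test_neg, cfg$neg_mean, cfg$sd)
    n_test <- cfg$n_test_pos + cfg$n_test_neg
    test <- data.frame(
      sample_id = sprintf("test_%02d", seq_len(n_test)),
      i_ntr = as.integer(c(pos[, 1], neg[, 1])),
      i_vis = as.integer(c(pos[, 2], neg[, 2])),
      he_label = rep(c("P", "N"), c(cfg$n_test_pos, cfg$n_test_neg)))
    if (n_test == 0) test <- test[0, ]
    list(training = training, test = test)
  })
}
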