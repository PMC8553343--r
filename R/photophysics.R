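## Photophysical calibration of the dual-activatable molecular rotor:
## the Forster-Hoffmann viscosity law, the linear nitroreductase
## titration, and the 3*sigma/k limit of detection.

#' Construct an emission series
#'
#' An emission series holds condition -> intensity pairs read off a
#' fluorescence spectrometer at a fixed emission wavelength: either a
#' viscosity series (condition in cP, red channel, typically 610 nm) or a
#' nitroreductase titration (condition in ug/mL, green channel, typically
#' 520 nm).
#'
#' @param condition numeric vector; solvent viscosity (cP, strictly
#'   positive) for `kind = "viscosity"`, or enzyme concentration (ug/mL,
#'   non-negative) for `kind = "titration"`.
#' @param intensity numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `condition`.
#' @param kind `"viscosity"` or `"titration"`.
#' @param wavelength_nm emission wavelength the intensities were read at.
#' @return A data frame of class `"emission_series"` with columns
#'   `condition` and `intensity` and attributes `kind` and `wavelength_nm`.
#' @examples
#' emission_series(c(1, 10, 100), c(10, 100, 1000), "viscosity", 610)
#' @export
emission_series <- function(condition, intensity,
                            kind = c("viscosity", "titration"),
                            wavelength_nm = NA_real_) {
  kind <- match.arg(kind)
  if (!is.numeric(condition) || !is.numeric(intensity))
    stopf("`condition` and `intensity` must be numeric")
  if (length(condition) != length(intensity))
    stopf("`condition` and `intensity` must have equal length")
  if (anyNA(condition) || anyNA(intensity))
    stopf("emission series must not contain missing values")
  if (kind == "viscosity" && length(condition) && any(condition <= 0))
    stopf("viscosities must be strictly positive")
  if (kind == "titration" && length(condition) && any(condition < 0))
    stopf("concentrations must be non-negative")
  out <- data.frame(condition = as.numeric(condition),
                    intensity = as.numeric(intensity))
  structure(out, kind = kind, wavelength_nm = as.numeric(wavelength_nm),
            class = c("emission_series", "data.frame"))
}

#' Read / write an emission series as CSV
#'
#' The file is a two-column headered CSV (`condition,intensity`) preceded
#' by one metadata comment line `# kind=<kind> wavelength_nm=<nm>`.
#'
#' @param path file path.
#' @return `read_emission_series()` returns an [emission_series()];
#'   `write_emission_series()` returns `path` invisibly.
#' @export
read_emission_series <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- "viscosity"; wl <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("kind=(\\w+)", first))[[1]]
    if (length(m) == 2L) kind <- m[2]
    m <- regmatches(first, regexec("wavelength_nm=([0-9.eE+-]+|NA)", first))[[1]]
    if (length(m) == 2L && m[2] != "NA") wl <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  emission_series(df$condition, df$intensity, kind = kind, wavelength_nm = wl)
}

#' @rdname read_emission_series
#' @param x an [emission_series()].
#' @export
write_emission_series <- function(x, path) {
  stopifnot(inherits(x, "emission_series"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# kind=%s wavelength_nm=%s", attr(x, "kind"),
                     format(attr(x, "wavelength_nm"))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Fit the Forster-Hoffmann viscosity law
#'
#' Molecular rotors obey the empirical power law
#' \deqn{\log_{10} I_f = c + x \log_{10} \eta}
#' relating fluorescence intensity \eqn{I_f} to solvent viscosity
#' \eqn{\eta}. The fit is ordinary least squares of `log10(intensity)` on
#' `log10(condition)`; base-10 logs throughout.
#'
#' @param series an [emission_series()] of kind `"viscosity"` with at
#'   least 2 points, all conditions and intensities strictly positive.
#' @return A list of class `"fh_fit"` with elements `slope_x`,
#'   `intercept_c`, `pearson_r` (Pearson correlation of the log-log
#'   pairs), and `n`.
#' @seealso [invert_viscosity()], [predict_intensity()]
#' @examples
#' s <- emission_series(c(1, 10, 100), c(10, 100, 1000), "viscosity")
#' fit_forster_hoffmann(s)  # slope 1, intercept 1, r 1
#' @export
fit_forster_hoffmann <- function(series) {
  stopifnot(inherits(series, "emission_series"))
  if (attr(series, "kind") != "viscosity")
    stopf("fit_forster_hoffmann() needs a viscosity series")
  if (nrow(series) < 2L)
    stopf("at least 2 points are required to fit")
  if (any(series$condition <= 0) || any(series$intensity <= 0))
    stopf("viscosities and intensities must be strictly positive")
  lx <- log10(series$condition); ly <- log10(series$intensity)
  if (stats::var(lx) == 0)
    stopf("degenerate fit: zero variance in log10(viscosity)")
  co <- stats::coef(stats::lm(ly ~ lx))
  structure(list(slope_x = unname(co[2L]), intercept_c = unname(co[1L]),
                 pearson_r = stats::cor(lx, ly), n = nrow(series)),
            class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  cat(sprintf("Forster-Hoffmann fit: log10(I) = %.4f + %.4f log10(eta)  (r = %.4f, n = %d)\n",
              x$intercept_c, x$slope_x, x$pearson_r, x$n))
  invisible(x)
}

#' Predict intensity from viscosity under a fitted law
#'
#' @param fit an `"fh_fit"` from [fit_forster_hoffmann()].
#' @param eta viscosity in cP (> 0), vectorized.
#' @return predicted intensity, `10^(c + x * log10(eta))`.
#' @export
predict_intensity <- function(fit, eta) {
  stopifnot(inherits(fit, "fh_fit"))
  if (any(eta <= 0)) stopf("viscosity must be strictly positive")
  10^(fit$intercept_c + fit$slope_x * log10(eta))
}

#' Invert the Forster-Hoffmann law: intensity to viscosity
#'
#' @param fit an `"fh_fit"`; `slope_x` must be nonzero.
#' @param intensity fluorescence intensity (> 0), vectorized.
#' @return estimated viscosity in cP, `10^((log10(I) - c) / x)`.
#' @export
invert_viscosity <- function(fit, intensity) {
  stopifnot(inherits(fit, "fh_fit"))
  if (fit$slope_x == 0) stopf("fit is non-invertible: slope is zero")
  if (any(intensity <= 0)) stopf("intensity must be strictly positive")
  10^((log10(intensity) - fit$intercept_c) / fit$slope_x)
}

#' Fit the linear nitroreductase titration
#'
#' Probe intensity is linearly proportional to nitroreductase
#' concentration over the working range (0-9.0 ug/mL); the fit is plain
#' OLS of intensity on concentration on the linear scale.
#'
#' @param series an [emission_series()] of kind `"titration"` with >= 2
#'   points.
#' @return A list of class `"titration_fit"` with `slope_k` (intensity
#'   per ug/mL), `intercept`, `pearson_r`, `n`.
#' @export
fit_titration <- function(series) {
  stopifnot(inherits(series, "emission_series"))
  if (attr(series, "kind") != "titration")
    stopf("fit_titration() needs a titration series")
  if (nrow(series) < 2L)
    stopf("at least 2 points are required to fit")
  if (stats::var(series$condition) == 0)
    stopf("degenerate fit: zero variance in concentration")
  co <- stats::coef(stats::lm(intensity ~ condition, data = series))
  structure(list(slope_k = unname(co[2L]), intercept = unname(co[1L]),
                 pearson_r = stats::cor(series$condition, series$intensity),
                 n = nrow(series)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit: I = %.3f + %.3f * conc  (r = %.4f, n = %d)\n",
              x$intercept, x$slope_k, x$pearson_r, x$n))
  invisible(x)
}

#' Standard deviation of blank measurements
#'
#' Sample standard deviation (n - 1 denominator) of replicate blank
#' intensities, the sigma of the 3*sigma/k detection-limit rule.
#'
#' @param blanks numeric vector of >= 2 blank intensities.
#' @return the sample standard deviation.
#' @export
blank_sigma <- function(blanks) {
  if (!is.numeric(blanks) || length(blanks) < 2L || anyNA(blanks))
    stopf("at least 2 non-missing blank values are required")
  stats::sd(blanks)
}

#' Limit of detection by the 3-sigma/k rule
#'
#' LOD = 3 * sigma / k, where sigma is the blank standard deviation and k
#' the slope of the titration line. With k in intensity per ug/mL the LOD
#' is in ug/mL; the ng/mL view is 1000x. Values are stored at full
#' precision and rounded (1 decimal in ng/mL) only at display time.
#'
#' @param slope_k titration slope (intensity per ug/mL), > 0.
#' @param sigma blank standard deviation (intensity units), >= 0.
#' @return A list of class `"lod_result"` with `sigma`, `slope_k`,
#'   `lod_ug_per_ml`, `lod_ng_per_ml`.
#' @examples
#' compute_lod(11166.424, 77.883)  # prints 20.9 ng/mL
#' @export
compute_lod <- function(slope_k, sigma) {
  assert_scalar_num(slope_k, "slope_k", lower = 0, strict_lower = TRUE)
  assert_scalar_num(sigma, "sigma", lower = 0)
  lod <- 3 * sigma / slope_k
  structure(list(sigma = sigma, slope_k = slope_k,
                 lod_ug_per_ml = lod, lod_ng_per_ml = 1000 * lod),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD = 3 * %.3f / %.3f = %s ng/mL\n",
              x$sigma, x$slope_k, format_lod(x)))
  invisible(x)
}

#' @rdname compute_lod
#' @param x an `"lod_result"`.
#' @return `format_lod()` returns the ng/mL value formatted to 1 decimal.
#' @export
format_lod <- function(x) {
  stopifnot(inherits(x, "lod_result"))
  sprintf("%.1f", x$lod_ng_per_ml)
}

#' Fold enhancement across a viscosity series
#'
#' Intensity at the most viscous condition divided by intensity at the
#' least viscous one (e.g. glycerol vs ethanol); the rotor shows roughly
#' an 18-fold enhancement from ethanol (~1.2 cP) to glycerol (~945 cP).
#'
#' @param series an [emission_series()] with >= 2 points.
#' @return the max-condition / min-condition intensity ratio.
#' @export
fold_enhancement <- function(series) {
  stopifnot(inherits(series, "emission_series"))
  if (nrow(series) < 2L) stopf("at least 2 points are required")
  lo <- series$intensity[which.min(series$condition)]
  hi <- series$intensity[which.max(series$condition)]
  if (lo == 0) stopf("zero intensity at the minimum condition")
  hi / lo
}
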