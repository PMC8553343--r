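## Quantification of two-channel specimen images: segmentation of
## specimen regions and per-specimen maximal gray-scale intensity in the
## nitroreductase (green, 480-530 nm) and viscosity (red, 580-630 nm)
## detection channels; pixelwise Pearson colocalization.

check_channel <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stopf("`%s` must hold gray-scale values in [0, 255]", name)
  invisible(x)
}

## Connected-component labeling of a logical mask by breadth-first flood
## fill. EBImage::bwlabel offers only 4-connectivity, whereas diagonal
## specimen pixels must belong together here, so labeling is done
## in-package with configurable connectivity.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stopf("`connectivity` must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  off <- if (connectivity == 8L)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  fg <- which(mask)
  nlab <- 0L
  queue <- integer(length(fg))
  for (start in fg) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    lab[start] <- nlab
    queue[1L] <- start; qlen <- 1L
    while (qlen > 0L) {
      cur <- queue[qlen]; qlen <- qlen - 1L
      r <- ((cur - 1L) %% h) + 1L
      cl <- ((cur - 1L) %/% h) + 1L
      for (k in seq_len(nrow(off))) {
        nr <- r + off[k, 1L]; nc <- cl + off[k, 2L]
        if (nr < 1L || nr > h || nc < 1L || nc > w) next
        ni <- (nc - 1L) * h + nr
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- nlab
          qlen <- qlen + 1L; queue[qlen] <- ni
        }
      }
    }
  }
  lab
}

#' Segment specimen regions in a paired two-channel image
#'
#' Foreground is every pixel whose per-pixel maximum across the two
#' channels exceeds `bg_threshold` (so a specimen bright in only one
#' channel -- a prospective "+" call -- is still detected). Foreground is
#' split into connected components (8-connectivity by default),
#' components smaller than `min_area` pixels are discarded, and the
#' surviving regions are ordered by the (min_row, min_col) corner of
#' their bounding box and numbered from 1.
#'
#' @param ntr,vis numeric matrices of identical shape with gray-scale
#'   values in [0, 255] (nitroreductase and viscosity channels).
#' @param bg_threshold background threshold in gray levels (0-255).
#' @param min_area minimum region area in pixels.
#' @param connectivity 8 (default) or 4.
#' @return A list of `"sample_region"` objects, each with `region_id`,
#'   `pixels` (2-column row/col matrix), `area`, and `bbox`
#'   `(min_row, min_col, max_row, max_col)`.
#' @export
segment_samples <- function(ntr, vis, bg_threshold = 30L, min_area = 50L,
                            connectivity = 8L) {
  check_channel(ntr, "ntr"); check_channel(vis, "vis")
  if (!identical(dim(ntr), dim(vis)))
    stopf("channel images must have identical dimensions")
  assert_scalar_num(bg_threshold, "bg_threshold", lower = 0, upper = 255)
  lab <- label_components(pmax(ntr, vis) > bg_threshold, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  regions <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    regions[[length(regions) + 1L]] <- list(
      pixels = unname(idx), area = nrow(idx),
      bbox = c(min_row = min(idx[, 1]), min_col = min(idx[, 2]),
               max_row = max(idx[, 1]), max_col = max(idx[, 2])))
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$bbox[1], 0),
               vapply(regions, function(r) r$bbox[2], 0))
  regions <- regions[ord]
  for (i in seq_along(regions)) {
    regions[[i]]$region_id <- i
    class(regions[[i]]) <- "sample_region"
  }
  regions
}

#' Measure a specimen's maximal gray-scale intensity per channel
#'
#' Records the maximum pixel value over the region in each channel --
#' the per-specimen statistic the triage rule operates on. The maximum
#' is taken as-is, with no background subtraction.
#'
#' @param region a `"sample_region"` from [segment_samples()].
#' @param ntr,vis the channel images the region was segmented from.
#' @param sample_id optional id; defaults to `sample_<region_id>`.
#' @return A one-row data frame with `sample_id`, `i_ntr`, `i_vis`.
#' @export
measure_sample <- function(region, ntr, vis, sample_id = NULL) {
  stopifnot(inherits(region, "sample_region"))
  check_channel(ntr, "ntr"); check_channel(vis, "vis")
  px <- region$pixels
  if (is.null(px) || nrow(px) == 0L) stopf("region is empty")
  if (any(px[, 1] < 1 | px[, 1] > nrow(ntr) | px[, 2] < 1 | px[, 2] > ncol(ntr)))
    stopf("region pixels fall outside the image")
  if (is.null(sample_id)) sample_id <- sprintf("sample_%d", region$region_id)
  data.frame(sample_id = sample_id,
             i_ntr = max(ntr[px]), i_vis = max(vis[px]))
}

#' Measure every segmented specimen
#'
#' @param regions list of `"sample_region"` objects.
#' @param ntr,vis the channel images.
#' @return data frame with one row per region (`sample_id`, `i_ntr`,
#'   `i_vis`), in region order.
#' @export
measure_samples <- function(regions, ntr, vis) {
  rows <- lapply(regions, measure_sample, ntr = ntr, vis = vis)
  if (!length(rows))
    return(data.frame(sample_id = character(), i_ntr = numeric(),
                      i_vis = numeric()))
  do.call(rbind, rows)
}

#' Pearson colocalization coefficient of two channels
#'
#' Pixelwise Pearson correlation of two channel images over an optional
#' mask (whole image if absent); the standard colocalization statistic
#' for dual-stain overlap.
#'
#' @param a,b numeric matrices of identical shape.
#' @param mask optional logical matrix of the same shape selecting the
#'   pixels to correlate.
#' @return Pearson correlation in [-1, 1].
#' @export
pearson_colocalization <- function(a, b, mask = NULL) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b)))
    stopf("`a` and `b` must be matrices of identical shape")
  if (is.null(mask)) {
    x <- as.numeric(a); y <- as.numeric(b)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(a)))
      stopf("`mask` must be a logical matrix matching the images")
    x <- a[mask]; y <- b[mask]
  }
  if (length(x) < 2L) stopf("at least 2 masked pixels are required")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("degenerate input: a channel is constant over the mask")
  stats::cor(x, y)
}

#' Read / write an 8-bit grayscale channel TIFF
#'
#' One single-channel file per detection channel; pixel values are
#' stored as 8-bit gray levels. Multi-sample or RGB TIFFs are reduced to
#' the first plane / channel mean on read.
#'
#' @param path file path.
#' @return `read_channel_tiff()` returns an integer matrix in [0, 255];
#'   `write_channel_tiff()` returns `path` invisibly.
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (is.list(img)) img <- img[[1L]]
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  out <- clip8(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_channel_tiff
#' @param x numeric matrix with values in [0, 255].
#' @export
write_channel_tiff <- function(x, path) {
  check_channel(x, "x")
  tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
  invisible(path)
}
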