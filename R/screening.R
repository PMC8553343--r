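## Threshold derivation and three-group triage classification. The
## dual-channel decision point is the K-means centroid of the training
## scatter of per-specimen maximal gray-scale intensities; specimens are
## then triaged by which channels exceed it.

#' Lloyd's K-means with k-means++ seeding
#'
#' Deterministic given `seed`: centroids are initialized k-means++ style
#' (first uniformly, subsequent ones with probability proportional to
#' squared distance from the nearest chosen centroid), then refined by
#' Lloyd iterations until the largest centroid shift falls below `tol`
#' or `max_iter` is reached. A cluster that empties is re-seeded to the
#' point farthest from its assigned centroid.
#'
#' @param points numeric matrix with one row per point (2 columns for
#'   the dual-channel scatter; any dimension is accepted).
#' @param k number of clusters, `1 <= k <= nrow(points)`.
#' @param seed integer RNG seed for the initialization.
#' @param tol convergence tolerance on the centroid shift.
#' @param max_iter iteration cap.
#' @return A list of class `"kmeans_result"`: `k`, `centroids` (k x d
#'   matrix), `assignments` (1-based cluster index per point),
#'   `inertia` (total within-cluster sum of squares), `iterations`, and
#'   `inertia_trace` (inertia after each Lloyd assignment step).
#' @export
lloyd_kmeans <- function(points, k, seed = 1L, tol = 1e-8, max_iter = 100L) {
  points <- as.matrix(points)
  if (!is.numeric(points) || anyNA(points) || any(!is.finite(points)))
    stopf("`points` must be a finite numeric matrix")
  n <- nrow(points)
  if (k < 1L || k > n)
    stopf("`k` must satisfy 1 <= k <= number of points (%d)", n)
  sqdist_to <- function(centers) {
    # n x k matrix of squared Euclidean distances
    d2 <- matrix(0, n, nrow(centers))
    for (j in seq_len(nrow(centers)))
      d2[, j] <- rowSums(sweep(points, 2, centers[j, ], "-")^2)
    d2
  }
  centers <- with_seed(seed, {
    ctr <- points[sample.int(n, 1L), , drop = FALSE]
    while (nrow(ctr) < k) {
      d2 <- apply(sqdist_to(ctr), 1, min)
      nxt <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      ctr <- rbind(ctr, points[nxt, , drop = FALSE])
    }
    ctr
  })
  trace <- numeric(0)
  assign <- rep(1L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sqdist_to(centers)
    assign <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign)]))
    newc <- centers
    for (j in seq_len(k)) {
      mem <- assign == j
      if (any(mem)) {
        newc[j, ] <- colMeans(points[mem, , drop = FALSE])
      } else {
        # empty cluster: re-seed to the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), assign)])
        newc[j, ] <- points[far, ]
      }
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol || iter >= max_iter) break
  }
  d2 <- sqdist_to(centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  structure(list(k = as.integer(k), centroids = unname(centers),
                 assignments = assign, inertia = inertia,
                 iterations = iter, inertia_trace = c(trace, inertia)),
            class = "kmeans_result")
}

#' Construct a dual-channel threshold
#'
#' @param t_ntr,t_vis threshold gray levels for the nitroreductase (x)
#'   and viscosity (y) channels, in [0, 255].
#' @return A list of class `"threshold"`.
#' @export
threshold <- function(t_ntr, t_vis) {
  assert_scalar_num(t_ntr, "t_ntr", lower = 0, upper = 255)
  assert_scalar_num(t_vis, "t_vis", lower = 0, upper = 255)
  structure(list(t_ntr = t_ntr, t_vis = t_vis), class = "threshold")
}

#' @export
print.threshold <- function(x, ...) {
  cat(sprintf("Dual-channel threshold (ntr, vis) = (%.1f, %.1f)\n",
              x$t_ntr, x$t_vis))
  invisible(x)
}

#' Derive the triage threshold from a training scatter
#'
#' The maximal gray-scale intensities of all training specimens of one
#' cancer type -- cancerous and noncancerous together -- form a scatter
#' in the (ntr, vis) plane; its K-means centroid with k = 1 (the grand
#' componentwise mean) is the threshold point. Thresholds are
#' cancer-type- and instrument-specific, so they are always derived from
#' (or supplied with) the data, never hard-coded. Reported to 1 decimal.
#'
#' @param training data frame with columns `i_ntr` and `i_vis`, one row
#'   per training specimen (>= 2 rows).
#' @param k number of clusters; with the default `k = 1` the centroid is
#'   the grand mean. Larger k is available for sensitivity analysis, in
#'   which case the centroid mean is returned.
#' @param seed seed passed to [lloyd_kmeans()].
#' @return A [threshold()].
#' @export
derive_threshold <- function(training, k = 1L, seed = 1L) {
  if (!is.data.frame(training) || !all(c("i_ntr", "i_vis") %in% names(training)))
    stopf("`training` must have columns `i_ntr` and `i_vis`")
  if (nrow(training) < 2L)
    stopf("at least 2 training records are required")
  km <- lloyd_kmeans(cbind(training$i_ntr, training$i_vis), k = k, seed = seed)
  ctr <- colMeans(km$centroids)
  threshold(round(ctr[1], 1), round(ctr[2], 1))
}

#' Three-group triage classification
#'
#' A specimen is "high" in a channel when its maximal intensity is at or
#' above the threshold for that channel (ties count as high: the
#' pre-screen errs toward a positive call). Both channels high gives
#' definitely positive `"++"`, exactly one gives suspiciously positive
#' `"+"`, neither gives negative `"-"`.
#'
#' @param i_ntr,i_vis numeric vectors of maximal gray-scale intensities
#'   in [0, 255] (recycled to a common length).
#' @param thr a [threshold()].
#' @return character vector of calls in `c("++", "+", "-")`.
#' @examples
#' thr <- threshold(160.3, 164.3)
#' triage_classify(c(200, 200, 100), c(200, 100, 100), thr)  # "++" "+" "-"
#' @export
triage_classify <- function(i_ntr, i_vis, thr) {
  stopifnot(inherits(thr, "threshold"))
  if (anyNA(i_ntr) || anyNA(i_vis) ||
      any(i_ntr < 0 | i_ntr > 255) || any(i_vis < 0 | i_vis > 255))
    stopf("intensities must lie in [0, 255]")
  high_ntr <- i_ntr >= thr$t_ntr
  high_vis <- i_vis >= thr$t_vis
  ifelse(high_ntr & high_vis, "++", ifelse(high_ntr | high_vis, "+", "-"))
}

#' Classify a cohort of specimen records
#'
#' Order-preserving: fills (or refreshes) the `call` column of a sample
#' table with the triage call of each record.
#'
#' @param records data frame with columns `i_ntr` and `i_vis`.
#' @param thr a [threshold()].
#' @return `records` with a character `call` column.
#' @export
classify_cohort <- function(records, thr) {
  if (!is.data.frame(records) || !all(c("i_ntr", "i_vis") %in% names(records)))
    stopf("`records` must have columns `i_ntr` and `i_vis`")
  records$call <- if (nrow(records))
    triage_classify(records$i_ntr, records$i_vis, thr) else character(0)
  records
}
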