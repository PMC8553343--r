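# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: direct normal equations, direct formulas, and
# exhaustive enumeration at tiny n.

# OLS via the normal equations; returns c(intercept, slope)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Quadrant truth table for the triage rule, built by counting high
# channels rather than by boolean branching.
quadrant_oracle <- function(i_ntr, i_vis, t_ntr, t_vis) {
  n_high <- (i_ntr >= t_ntr) + (i_vis >= t_vis)
  c("-", "+", "++")[n_high + 1L]
}

# Exhaustive best 2-partition of a small point set: minimal total
# within-cluster sum of squares over all assignments into two non-empty
# clusters. Only usable for tiny n.
best_two_partition <- function(points) {
  n <- nrow(points)
  stopifnot(n <= 12)
  best <- list(sse = Inf)
  for (code in 1:(2^(n - 1) - 1)) {      # point 1 fixed in cluster 1
    memb <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    sse <- 0
    cents <- matrix(NA_real_, 2, ncol(points))
    for (g in 1:2) {
      pts <- points[memb == g, , drop = FALSE]
      cents[g, ] <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, cents[g, ], "-")^2)
    }
    if (sse < best$sse) best <- list(sse = sse, membership = memb, centroids = cents)
  }
  best
}

# Random labeled cohort for fuzzing the evaluation module.
random_labeled_cohort <- function(n) {
  data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    i_ntr = sample(0:255, n, replace = TRUE),
    i_vis = sample(0:255, n, replace = TRUE),
    call = sample(c("++", "+", "-"), n, replace = TRUE),
    he_label = sample(c("P", "N"), n, replace = TRUE))
}
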