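# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures live in the repository.

# A trace map with a single marked pixel.
single_px_map <- function(n, row, col) {
  m <- matrix(0L, n, n)
  m[row, col] <- 1L
  trace_map(m)
}

# Random sparse binary map, seeded.
rand_trace <- function(n, density = 0.05, seed = 1) {
  withr::with_seed(seed, trace_map(matrix(runif(n * n) < density, n, n)))
}

# Independent scoring oracle: exhaustive pairwise-distance classification.
# O(n^4) but exact; only used on small maps.
brute_score <- function(gt, resp, r, miss_rule = "dilated_response") {
  gt <- unclass(gt) > 0; resp <- unclass(resp) > 0
  n <- nrow(gt)
  gt_idx <- which(gt, arr.ind = TRUE)
  rp_idx <- which(resp, arr.ind = TRUE)
  near <- function(p, pts) {
    nrow(pts) > 0 &&
      any((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 <= r^2)
  }
  hits <- 0; fa <- 0
  for (i in seq_len(nrow(rp_idx)))
    if (near(rp_idx[i, ], gt_idx)) hits <- hits + 1 else fa <- fa + 1
  misses <- 0
  for (i in seq_len(nrow(gt_idx))) {
    p <- gt_idx[i, ]
    if (miss_rule == "dilated_response") {
      if (!near(p, rp_idx)) misses <- misses + 1
    } else {
      if (!resp[p[1], p[2]]) misses <- misses + 1
    }
  }
  list(hits = hits, misses = misses, fa = fa,
       cr = n * n - hits - fa - misses, n_pixels = n * n)
}

# Independent z oracle: invert the standard-normal CDF numerically.
z_oracle <- function(p) {
  uniroot(function(z) pnorm(z) - p, c(-10, 10), tol = 1e-12)$root
}

# Count 8-connected components of a binary matrix (BFS).
count_components <- function(mask) {
  mask <- mask > 0
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  comps <- 0
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    if (seen[i0, j0]) next
    comps <- comps + 1
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= n && j >= 1 && j <= m &&
            mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  comps
}

# Flat-field luminance image.
flat_image <- function(n, value = 100, ppd = 44) {
  luminance_image(matrix(value, n, n), ppd)
}
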