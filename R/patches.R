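#' Consensus heatmap from stacked ground-truth maps
#'
#' Per-pixel count of how many observers traced each pixel in the
#' noise-free session. The heatmap drives patch sampling by edge-consensus
#' category.
#'
#' @param maps list of [trace_map()]s of equal size, one per observer.
#' @return An object of class `consensus_heatmap`: an integer count matrix
#'   with attribute `n_observers`.
#' @export
stack_ground_truths <- function(maps) {
  if (length(maps) < 1) stop("need at least one map")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims != dims[, 1])) stop("maps have different sizes")
  counts <- Reduce(`+`, lapply(maps, function(m) {
    v <- unclass(m); attributes(v) <- list(dim = dim(m)); v
  }))
  structure(counts,
            n_observers = length(maps),
            class = c("consensus_heatmap", "matrix", "array"))
}

#' @export
print.consensus_heatmap <- function(x, ...) {
  cat(sprintf("<consensus_heatmap> %dx%d px, %d observers, max count %d\n",
              nrow(x), ncol(x), attr(x, "n_observers"), max(x)))
  invisible(x)
}

#' Eligibility mask for a consensus category
#'
#' Categories follow the consensus thresholds: `salient` pixels were traced
#' by at least `ceil(salient_frac * n)` observers (0.95 reproduces "at least
#' 19 of 20"), `some` by between `some_lo * n` and `some_hi * n` observers
#' (25%-75%, i.e. 5-15 of 20), `none` by nobody.
#'
#' @param heatmap a [stack_ground_truths()] result.
#' @param category `"salient"`, `"some"`, or `"none"`.
#' @param salient_frac,some_lo,some_hi category thresholds as fractions of
#'   the observer count.
#' @return Logical matrix of eligible center pixels.
#' @export
consensus_category <- function(heatmap, category = c("salient", "some", "none"),
                               salient_frac = 0.95,
                               some_lo = 0.25, some_hi = 0.75) {
  stopifnot(inherits(heatmap, "consensus_heatmap"))
  category <- match.arg(category)
  n <- attr(heatmap, "n_observers")
  cnt <- unclass(heatmap); attributes(cnt) <- list(dim = dim(heatmap))
  switch(category,
         salient = cnt >= ceiling(salient_frac * n),
         some = cnt >= some_lo * n & cnt <= some_hi * n & cnt > 0,
         none = cnt == 0)
}

#' Sample image patches by edge-consensus category
#'
#' Draws up to `k` seeded random patch centers whose center pixel satisfies
#' the category rule, keeping centers at least `min_spacing` pixels apart
#' (Euclidean) and patches fully inside the image.
#'
#' @param heatmap a [stack_ground_truths()] result.
#' @param scene a [luminance_image()] of the same size (the *noise-free*
#'   scene the patches are cut from).
#' @param category `"salient"`, `"some"`, or `"none"`.
#' @param k number of patches requested.
#' @param seed integer seed.
#' @param patch_px odd patch side length (default 51).
#' @param min_spacing minimum center-to-center distance; default one patch
#'   width, so patches never overlap more than marginally.
#' @param ... category thresholds passed to [consensus_category()].
#' @return An object of class `patch_set`: list with `centers` (data.frame
#'   `row`, `col`, `category`) and `patches` (list of patch matrices).
#'   If fewer than `k` centers are eligible, all eligible ones are returned
#'   with a warning.
#' @export
sample_patches <- function(heatmap, scene, category, k, seed = 1L,
                           patch_px = 51, min_spacing = patch_px, ...) {
  stopifnot(inherits(heatmap, "consensus_heatmap"), is_luminance_image(scene))
  if (!all(dim(heatmap) == dim(scene)))
    stop("heatmap and scene sizes differ")
  if (patch_px %% 2 == 0) stop("`patch_px` must be odd")
  n <- nrow(scene)
  half <- (patch_px - 1) / 2
  eligible <- consensus_category(heatmap, category, ...)
  interior <- matrix(FALSE, n, n)
  if (n >= patch_px)
    interior[(half + 1):(n - half), (half + 1):(n - half)] <- TRUE
  idx <- which(eligible & interior, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no eligible patch centers for category '", category, "'")
    return(structure(list(centers = data.frame(row = integer(), col = integer(),
                                               category = character()),
                          patches = list(), patch_px = patch_px,
                          ppd = attr(scene, "ppd")),
                     class = "patch_set"))
  }
  ord <- withr::with_seed(seed, sample.int(nrow(idx)))
  chosen <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    p <- idx[i, ]
    if (nrow(chosen) == 0 ||
        all((chosen[, 1] - p[1])^2 + (chosen[, 2] - p[2])^2 >=
              min_spacing^2)) {
      chosen <- rbind(chosen, p)
      if (nrow(chosen) == k) break
    }
  }
  if (nrow(chosen) < k)
    warning(sprintf("only %d of %d requested '%s' patches available",
                    nrow(chosen), k, category))
  patches <- lapply(seq_len(nrow(chosen)), function(i) {
    r <- chosen[i, 1]; c <- chosen[i, 2]
    m <- unclass(scene)[(r - half):(r + half), (c - half):(c + half)]
    attributes(m) <- list(dim = c(patch_px, patch_px))
    m
  })
  structure(list(centers = data.frame(row = chosen[, 1], col = chosen[, 2],
                                      category = category,
                                      row.names = NULL),
                 patches = patches, patch_px = patch_px,
                 ppd = attr(scene, "ppd")),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%dx%d px)%s\n",
              length(x$patches), x$patch_px, x$patch_px,
              if (nrow(x$centers)) paste0(", category ",
                                          unique(x$centers$category)) else ""))
  invisible(x)
}

#' Luminance and contrast features of a patch
#'
#' @param p a numeric patch matrix (or a [luminance_image()]).
#' @return A list with `mean_luminance` and `rms_contrast` (population sd /
#'   mean).
#' @export
patch_features <- function(p) {
  v <- as.numeric(p)
  if (length(v) == 0) stop("empty patch")
  m <- mean(v)
  if (m <= 0) stop("patch mean luminance must be positive")
  list(mean_luminance = m, rms_contrast = sqrt(mean((v - m)^2)) / m)
}

#' Directional power spectrum of a patch
#'
#' Mean-subtracted 2D FFT power, aggregated over frequency annuli restricted
#' to an angular wedge around the chosen frequency axis. The "vertical"
#' direction means energy along the vertical frequency axis, i.e. produced
#' by horizontally oriented luminance structure, and vice versa. A Hann
#' window limits spectral leakage by default; with `window = "none"` the
#' total power over all bins equals the patch's population variance
#' (Parseval), exposed as attribute `total_power`.
#'
#' @param p numeric patch matrix.
#' @param direction `"vertical"` or `"horizontal"` (frequency-axis wedge).
#' @param ppd pixels per degree of the source image.
#' @param wedge_deg full angular width of the wedge in degrees (default 30).
#' @param window `"hann"` (default) or `"none"`.
#' @param normalize divide by the maximum power (the per-graph normalization
#'   used for plotting). Default FALSE.
#' @return data.frame with columns `sf` (cpd) and `power`, with attributes
#'   `direction` and `total_power`.
#' @export
directional_power <- function(p, direction = c("vertical", "horizontal"),
                              ppd, wedge_deg = 30,
                              window = c("hann", "none"),
                              normalize = FALSE) {
  direction <- match.arg(direction)
  window <- match.arg(window)
  x <- as.matrix(p)
  n <- nrow(x)
  if (ncol(x) != n) stop("patch must be square")
  x <- x - mean(x)
  if (window == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    x <- x * outer(h, h)
    x <- x - mean(x)
  }
  pw <- Mod(stats::fft(x))^2 / n^4 # sums to the (windowed) variance
  f <- fft_freq(n) * ppd
  fy <- matrix(f, n, n)        # row frequency varies down rows
  fx <- matrix(f, n, n, byrow = TRUE)
  fr <- sqrt(fx^2 + fy^2)
  theta <- atan2(fy, fx) * 180 / pi # orientation of the frequency vector
  theta <- theta %% 180
  half <- wedge_deg / 2
  in_wedge <- if (direction == "vertical") {
    abs(theta - 90) <= half
  } else {
    theta <= half | theta >= 180 - half
  }
  df <- ppd / n
  bin <- as.integer(round(fr / df))
  keep <- in_wedge & bin > 0
  pow <- tapply(pw[keep], bin[keep], mean)
  out <- data.frame(sf = as.integer(names(pow)) * df,
                    power = as.numeric(pow))
  if (normalize && nrow(out) && max(out$power) > 0)
    out$power <- out$power / max(out$power)
  attr(out, "direction") <- direction
  attr(out, "total_power") <- sum(pw)
  out
}
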