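#' Luminance image
#'
#' A square grid of luminance values (cd/m^2) together with the display
#' resolution in pixels per degree of visual angle. This is the common
#' currency of the stimulus, patch and simulation functions: all contrast
#' and spatial-frequency computations are referenced to physical luminance
#' and visual angle, not raw pixel values.
#'
#' @param values numeric matrix of luminance values; must be square with
#'   side length >= 2.
#' @param ppd pixels per degree of visual angle (> 0).
#' @return An object of class `luminance_image`: the value matrix with
#'   attributes `ppd` and `size_px`.
#' @examples
#' img <- luminance_image(matrix(100, 32, 32), ppd = 44)
#' rms_contrast(img)
#' @export
luminance_image <- function(values, ppd) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("luminance images must be square; got ",
         nrow(values), "x", ncol(values))
  if (nrow(values) < 2)
    stop("luminance images must be at least 2x2")
  if (anyNA(values))
    stop("`values` contains NA")
  if (!is.numeric(ppd) || length(ppd) != 1L || ppd <= 0)
    stop("`ppd` must be a single positive number")
  structure(values,
            ppd = as.numeric(ppd),
            size_px = nrow(values),
            class = c("luminance_image", "matrix", "array"))
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf(
    "<luminance_image> %dx%d px, %.3g ppd (%.2f deg), mean %.4g cd/m2, RMS contrast %.4g\n",
    nrow(x), ncol(x), attr(x, "ppd"),
    angular_size(nrow(x), attr(x, "ppd")),
    mean(x), rms_contrast(x)))
  invisible(x)
}

is_luminance_image <- function(x) inherits(x, "luminance_image")

#' Root-mean-squared contrast
#'
#' RMS contrast is the population standard deviation of luminance divided by
#' the mean luminance (dimensionless). The population (n) convention, not the
#' sample (n-1) convention, is used: the image is the whole population of
#' pixels, and normalization targets must round-trip exactly.
#'
#' @param img a [luminance_image()] or a plain numeric matrix.
#' @return RMS contrast (scalar >= 0).
#' @export
rms_contrast <- function(img) {
  v <- as.numeric(img)
  if (length(v) < 2) stop("need at least 2 pixels to define contrast")
  m <- mean(v)
  if (m <= 0) stop("mean luminance must be positive, got ", format(m))
  sqrt(mean((v - m)^2)) / m
}

#' Affinely renormalize an image to a target contrast and mean
#'
#' Applies the affine map `a * x + b` that gives the output exactly the
#' target mean luminance and target RMS contrast. Used to set scene contrast
#' before compositing and to calibrate noise fields.
#'
#' @param img a [luminance_image()].
#' @param target_rms target RMS contrast (>= 0); 0 yields a constant image.
#' @param target_mean target mean luminance in cd/m^2 (> 0).
#' @return A [luminance_image()] with the same shape and ppd.
#' @export
normalize_to <- function(img, target_rms, target_mean) {
  stopifnot(is_luminance_image(img))
  if (target_mean <= 0) stop("`target_mean` must be positive")
  if (target_rms < 0) stop("`target_rms` must be non-negative")
  v <- unclass(img)
  attributes(v) <- list(dim = dim(img))
  if (target_rms == 0) {
    out <- matrix(target_mean, nrow(v), ncol(v))
    return(luminance_image(out, attr(img, "ppd")))
  }
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0)
    stop("cannot normalize a constant image to a positive RMS contrast")
  a <- target_rms * target_mean / s
  out <- a * (v - mean(v)) + target_mean
  luminance_image(out, attr(img, "ppd"))
}

#' Angular size of a square stimulus
#'
#' @param size_px side length in pixels.
#' @param ppd pixels per degree (> 0).
#' @return Size in degrees of visual angle.
#' @examples
#' angular_size(512, 44) # ~11.6 deg
#' @export
angular_size <- function(size_px, ppd) {
  if (ppd <= 0) stop("`ppd` must be positive")
  size_px / ppd
}
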