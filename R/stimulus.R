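#' Stimulus specification
#'
#' The recipe for one trial's stimulus: the RMS contrast at which the scene
#' is shown, the mean luminance of the display, and optionally a noise mask.
#' The scene and the noise combine additively in the contrast domain,
#' `L = Lbar * (1 + c_scene * s + n)`, so the mask's contrast energy is
#' independent of the image contrast.
#'
#' @param image_contrast RMS contrast of the scene component (>= 0).
#' @param mean_luminance mean luminance in cd/m^2 (> 0). Default 100.
#' @param noise a [noise_spec()], a [luminance_image()] noise mask, or NULL
#'   for a noise-free stimulus.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(image_contrast, mean_luminance = 100, noise = NULL) {
  if (image_contrast < 0) stop("`image_contrast` must be non-negative")
  if (mean_luminance <= 0) stop("`mean_luminance` must be positive")
  if (!is.null(noise) && !inherits(noise, "noise_spec") &&
      !is_luminance_image(noise))
    stop("`noise` must be a noise_spec, a luminance_image, or NULL")
  structure(list(image_contrast = image_contrast,
                 mean_luminance = mean_luminance,
                 noise = noise),
            class = "stimulus_spec")
}

#' Compose a noisy stimulus from a scene and a stimulus spec
#'
#' The scene is affinely renormalized to `(image_contrast, mean_luminance)`;
#' the noise mask (generated from the spec, or supplied as an image) is
#' converted to a zero-mean contrast modulation and added; negative
#' luminances are clamped to zero. The clipped pixel fraction is attached as
#' attribute `clip_fraction` and a warning is raised when it exceeds 1%.
#'
#' @param scene a [luminance_image()].
#' @param spec a [stimulus_spec()].
#' @return A [luminance_image()] with attribute `clip_fraction`.
#' @export
compose_stimulus <- function(scene, spec) {
  stopifnot(is_luminance_image(scene), inherits(spec, "stimulus_spec"))
  ppd <- attr(scene, "ppd")
  n <- nrow(scene)
  base <- normalize_to(scene, spec$image_contrast, spec$mean_luminance)
  out <- unclass(base); attributes(out) <- list(dim = dim(base))

  if (!is.null(spec$noise)) {
    mask <- spec$noise
    if (inherits(mask, "noise_spec"))
      mask <- make_noise(mask, n, ppd, spec$mean_luminance)
    if (nrow(mask) != n)
      stop("scene and noise mask sizes differ: ", n, " vs ", nrow(mask))
    if (!isTRUE(all.equal(attr(mask, "ppd"), ppd)))
      stop("scene and noise mask ppd differ")
    # zero-mean contrast modulation of the mask, scaled by the mean luminance
    nc <- as.numeric(mask) / mean(mask) - 1
    out <- out + spec$mean_luminance * nc
  }

  clipped <- out < 0
  clip_fraction <- mean(clipped)
  if (any(clipped)) out[clipped] <- 0
  if (clip_fraction > 0.01)
    warning(sprintf("%.2f%% of pixels clipped at 0 cd/m2", 100 * clip_fraction))
  res <- luminance_image(out, ppd)
  attr(res, "clip_fraction") <- clip_fraction
  res
}
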