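#' Noise mask specification
#'
#' Describes one of the four noise families used for masking: broadband
#' white, pink (power ~ 1/f) and brown (power ~ 1/f^2) noise, and
#' spatial-frequency narrowband noise with a log-Gaussian amplitude envelope
#' centered on `center_sf`. The exponents name the POWER spectrum; the
#' amplitude weights applied in the frequency domain are their square roots
#' (white f^0, pink f^-1/2, brown f^-1).
#'
#' @param family one of `"white"`, `"pink"`, `"brown"`, `"narrowband"`.
#' @param rms_contrast RMS contrast of the mask (std / mean luminance, > 0).
#'   Default 0.1, the fixed mask contrast of the experimental design.
#' @param center_sf center spatial frequency in cycles/degree; required for
#'   narrowband (the experiment used 0.5, 3 and 9 cpd).
#' @param bandwidth_octaves full width at half height of the narrowband
#'   amplitude envelope, in octaves. Default 1.
#' @param seed integer seed; the generated field is a deterministic function
#'   of the spec (including the seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("white", "pink", "brown", "narrowband"),
                       rms_contrast = 0.1,
                       center_sf = NULL,
                       bandwidth_octaves = 1,
                       seed = 1L) {
  family <- match.arg(family)
  if (rms_contrast <= 0) stop("`rms_contrast` must be positive")
  if (family == "narrowband") {
    if (is.null(center_sf) || center_sf <= 0)
      stop("narrowband noise requires a positive `center_sf` (cycles/degree)")
    if (bandwidth_octaves <= 0) stop("`bandwidth_octaves` must be positive")
  } else if (!is.null(center_sf)) {
    stop("`center_sf` only applies to narrowband noise")
  }
  structure(list(family = family,
                 rms_contrast = rms_contrast,
                 center_sf = if (is.null(center_sf)) NA_real_ else center_sf,
                 bandwidth_octaves = bandwidth_octaves,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s, RMS %.3g%s, seed %d\n",
              x$family, x$rms_contrast,
              if (x$family == "narrowband")
                sprintf(", %.3g cpd (%.3g oct FWHH)",
                        x$center_sf, x$bandwidth_octaves) else "",
              x$seed))
  invisible(x)
}

# Frequencies of an n-point DFT in cycles per sample, numpy fftfreq layout:
# 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1, all divided by n.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / n
}

# Radial frequency grid in cycles/degree for an n x n image at `ppd`.
radial_freq_grid <- function(n, ppd) {
  f <- fft_freq(n) * ppd
  sqrt(outer(f^2, f^2, "+"))
}

#' Generate a calibrated noise mask
#'
#' Spectrally filters a seeded Gaussian white-noise field: the FFT of the
#' field is multiplied by the family's amplitude weight (f^0, f^-1/2, f^-1,
#' or an isotropic log-Gaussian band around `center_sf`), the DC component is
#' zeroed, and the inverse transform is affinely renormalized to the
#' requested RMS contrast about `mean_luminance`.
#'
#' @param spec a [noise_spec()].
#' @param size_px side length in pixels.
#' @param ppd pixels per degree; sets the cycles/degree frequency grid.
#' @param mean_luminance mean luminance of the returned mask (cd/m^2).
#' @return A [luminance_image()] with mean `mean_luminance` and RMS contrast
#'   `spec$rms_contrast` (both exact to floating point).
#' @export
make_noise <- function(spec, size_px, ppd, mean_luminance = 100) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- as.integer(size_px)
  if (n < 2) stop("`size_px` must be >= 2")
  nyquist <- ppd / 2
  if (spec$family == "narrowband" && spec$center_sf > nyquist)
    stop(sprintf("center_sf %.3g cpd exceeds the Nyquist frequency %.3g cpd",
                 spec$center_sf, nyquist))

  fr <- radial_freq_grid(n, ppd)
  w <- switch(spec$family,
    white = matrix(1, n, n),
    pink  = ifelse(fr > 0, fr^(-0.5), 0),
    brown = ifelse(fr > 0, fr^(-1), 0),
    narrowband = {
      # log-Gaussian amplitude envelope; FWHH in octaves -> sd in log2 units
      s <- spec$bandwidth_octaves / (2 * sqrt(2 * log(2)))
      ifelse(fr > 0, exp(-(log2(fr / spec$center_sf))^2 / (2 * s^2)), 0)
    })
  w[fr == 0] <- 0 # no DC: the mask is a zero-mean contrast modulation

  field <- withr::with_seed(spec$seed, matrix(stats::rnorm(n * n), n, n))
  filtered <- Re(stats::fft(stats::fft(field) * w, inverse = TRUE)) / n^2
  s <- sqrt(mean((filtered - mean(filtered))^2))
  if (s == 0) stop("degenerate noise field (zero variance after filtering)")
  values <- (filtered - mean(filtered)) / s *
    (spec$rms_contrast * mean_luminance) + mean_luminance
  out <- luminance_image(values, ppd)
  attr(out, "noise_spec") <- spec
  out
}

#' Radially averaged power spectrum
#'
#' Computes the 2D FFT power of the mean-subtracted image and averages it in
#' annuli of one frequency-pixel width (`ppd / size_px` cycles/degree).
#' Power is scaled so that the total over all non-DC bins equals the
#' population variance of the image (Parseval).
#'
#' @param img a [luminance_image()].
#' @return A data.frame with columns `sf` (cycles/degree, annulus center)
#'   and `power` (mean power per frequency cell in the annulus).
#' @export
radial_power_spectrum <- function(img) {
  stopifnot(is_luminance_image(img))
  n <- nrow(img)
  ppd <- attr(img, "ppd")
  x <- unclass(img); attributes(x) <- list(dim = dim(img))
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^4 # sum(p) == population variance
  fr <- radial_freq_grid(n, ppd)
  df <- ppd / n
  bin <- as.integer(round(fr / df))
  keep <- bin > 0
  pw <- tapply(p[keep], bin[keep], mean)
  data.frame(sf = as.integer(names(pw)) * df,
             power = as.numeric(pw))
}

#' Log-log slope of a radial power spectrum
#'
#' Least-squares slope of log10(power) against log10(sf) over a mid-band
#' frequency range, the standard diagnostic for 1/f-family noise (white 0,
#' pink -1, brown -2 on the radially averaged power).
#'
#' @param spectrum data.frame from [radial_power_spectrum()].
#' @param sf_range length-2 numeric, frequency band (cpd) used for the fit;
#'   default drops the lowest and highest octave to avoid DC leakage and
#'   corner anisotropy.
#' @return The fitted slope (scalar).
#' @export
spectral_slope <- function(spectrum, sf_range = NULL) {
  s <- spectrum[spectrum$sf > 0 & spectrum$power > 0, ]
  if (is.null(sf_range)) {
    lo <- min(s$sf) * 4
    hi <- max(s$sf) / 2
    sf_range <- c(lo, hi)
  }
  s <- s[s$sf >= sf_range[1] & s$sf <= sf_range[2], ]
  if (nrow(s) < 3) stop("too few frequency bins in `sf_range`")
  stats::coef(stats::lm(log10(power) ~ log10(sf), data = s))[[2]]
}

#' Peak frequency of a radial power spectrum
#'
#' @param spectrum data.frame from [radial_power_spectrum()].
#' @return Spatial frequency (cpd) of the annulus with maximal mean power.
#' @export
spectral_peak <- function(spectrum) {
  spectrum$sf[which.max(spectrum$power)]
}
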