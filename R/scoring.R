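#' Scoring configuration
#'
#' Settings for pixelwise SDT scoring of a response trace against a ground
#' truth. The error margin absorbs drawing inaccuracy: a response pixel
#' within a Euclidean disk of radius `margin_px` of any ground-truth pixel
#' counts as a hit. The margin can be given in pixels or as a fraction of
#' the image side; 2.5% of a 512 px image gives the canonical 13 px.
#'
#' @param margin_px integer pixel radius (>= 0). Give exactly one of
#'   `margin_px` / `margin_fraction`.
#' @param margin_fraction margin as a fraction of the image side; resolved
#'   per image as `round(margin_fraction * size_px)`.
#' @param rate_correction how hit/FA rates of exactly 0 or 1 are handled
#'   before the z-transform: `"loglinear"` (add 0.5 to each cell of the
#'   affected pair) or `"clamp"` (clamp to 1/(2N) from the boundary).
#' @param include_cr_in_pc include correct rejections in proportion correct
#'   (the appendix variant). Default FALSE.
#' @param miss_rule `"dilated_response"` (default): a ground-truth pixel is
#'   a miss only if no response pixel lies within the margin of it;
#'   `"strict"`: a ground-truth pixel is a miss unless it is itself a
#'   response pixel.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(margin_px = NULL,
                           margin_fraction = NULL,
                           rate_correction = c("loglinear", "clamp"),
                           include_cr_in_pc = FALSE,
                           miss_rule = c("dilated_response", "strict")) {
  if (is.null(margin_px) && is.null(margin_fraction))
    margin_fraction <- 0.025
  if (!is.null(margin_px) && !is.null(margin_fraction))
    stop("give exactly one of `margin_px` / `margin_fraction`")
  if (!is.null(margin_px) &&
      (margin_px < 0 || margin_px != round(margin_px)))
    stop("`margin_px` must be a non-negative integer")
  if (!is.null(margin_fraction) &&
      (margin_fraction < 0 || margin_fraction >= 1))
    stop("`margin_fraction` must be in [0, 1)")
  structure(list(margin_px = margin_px,
                 margin_fraction = margin_fraction,
                 rate_correction = match.arg(rate_correction),
                 include_cr_in_pc = isTRUE(include_cr_in_pc),
                 miss_rule = match.arg(miss_rule)),
            class = "scoring_config")
}

resolve_margin <- function(cfg, size_px) {
  if (!is.null(cfg$margin_px)) as.integer(cfg$margin_px)
  else as.integer(round(cfg$margin_fraction * size_px))
}

#' Dilate a binary mask with a Euclidean disk
#'
#' Morphological dilation with the structuring element
#' `{(dx, dy) : dx^2 + dy^2 <= r^2}`, implemented by zero-padded FFT
#' convolution with the disk indicator (exact for binary inputs since the
#' convolution values are integers thresholded at 1/2).
#'
#' @param mask logical or 0/1 matrix.
#' @param r disk radius in pixels (integer >= 0).
#' @return Logical matrix of the same shape.
#' @export
dilate_disk <- function(mask, r) {
  m <- if (is.logical(mask)) mask else mask > 0
  r <- as.integer(r)
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # pad so the circular convolution cannot wrap the disk around the borders
  mr <- stats::nextn(nr + 2L * r, c(2, 3, 5))
  mc <- stats::nextn(nc + 2L * r, c(2, 3, 5))
  big <- matrix(0, mr, mc)
  big[seq_len(nr), seq_len(nc)] <- m
  off <- -r:r
  disk <- outer(off^2, off^2, "+") <= r^2
  dx <- row(disk)[disk] - (r + 1L)
  dy <- col(disk)[disk] - (r + 1L)
  kern <- matrix(0, mr, mc)
  kern[cbind((dx %% mr) + 1L, (dy %% mc) + 1L)] <- 1
  conv <- Re(stats::fft(stats::fft(big) * stats::fft(kern), inverse = TRUE)) /
    (mr * mc)
  (conv[seq_len(nr), seq_len(nc)] >= 0.5)
}

#' Contingency counts from pixelwise classification
#'
#' Container for the four SDT categories of one scored (ground truth,
#' response) pair. The four counts always partition the pixel grid:
#' `hits + misses + fa + cr = n_pixels`.
#'
#' @param hits,misses,fa,cr non-negative integer counts.
#' @param n_pixels total number of pixels.
#' @return An object of class `contingency_counts`.
#' @export
contingency_counts <- function(hits, misses, fa, cr, n_pixels) {
  v <- c(hits = hits, misses = misses, fa = fa, cr = cr)
  if (any(v < 0)) stop("counts must be non-negative")
  if (sum(v) != n_pixels)
    stop("counts do not partition the grid: sum ", sum(v), " != ", n_pixels)
  structure(as.list(c(v, n_pixels = n_pixels)),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("<contingency_counts> H %d  M %d  FA %d  CR %d  (N = %d)\n",
              x$hits, x$misses, x$fa, x$cr, x$n_pixels))
  invisible(x)
}

#' Score a response trace map against a ground-truth trace map
#'
#' Every pixel is treated as one trial and assigned exactly one SDT
#' category. Response pixels within `margin_px` (Euclidean) of any
#' ground-truth pixel are hits; the remaining response pixels are false
#' alarms. Ground-truth pixels not explained by any response pixel within
#' the margin are misses (see `miss_rule` in [scoring_config()]); everything
#' else is a correct rejection. A ground-truth pixel that is itself a hit is
#' never also a miss.
#'
#' @param ground_truth,response [trace_map()]s of equal size.
#' @param cfg a [scoring_config()].
#' @return A [contingency_counts()] with attribute `margin_px` (the resolved
#'   margin).
#' @export
score_traces <- function(ground_truth, response, cfg = scoring_config()) {
  stopifnot(is_trace_map(ground_truth), is_trace_map(response))
  if (!all(dim(ground_truth) == dim(response)))
    stop("ground truth and response sizes differ: ",
         paste(dim(ground_truth), collapse = "x"), " vs ",
         paste(dim(response), collapse = "x"))
  gt <- as_binary_matrix(ground_truth)
  rp <- as_binary_matrix(response)
  r <- resolve_margin(cfg, nrow(gt))
  n <- length(gt)

  dil_gt <- dilate_disk(gt, r)
  hits <- sum(rp & dil_gt)
  fa <- sum(rp) - hits
  misses <- if (cfg$miss_rule == "dilated_response") {
    sum(gt & !dilate_disk(rp, r))
  } else {
    sum(gt & !rp)
  }
  out <- contingency_counts(hits, misses, fa, n - hits - fa - misses, n)
  attr(out, "margin_px") <- r
  out
}

#' Proportion correct
#'
#' Default definition `p = H / (H + M + FA)`: correct rejections are left
#' out because nearly all pixels of a trace map are untraced background, and
#' including them compresses p into a narrow band near 1. The
#' `include_cr` variant `p = (H + CR) / N` is the classical definition.
#'
#' @param counts a [contingency_counts()].
#' @param include_cr include correct rejections (default FALSE).
#' @return Proportion correct in \[0, 1\].
#' @export
proportion_correct <- function(counts, include_cr = FALSE) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (include_cr) {
    denom <- counts$n_pixels
    if (denom == 0) stop("proportion correct undefined: empty image")
    (counts$hits + counts$cr) / denom
  } else {
    denom <- counts$hits + counts$misses + counts$fa
    if (denom == 0)
      stop("proportion correct undefined: no traced pixels in either map")
    counts$hits / denom
  }
}

# Hit and FA rates with the configured boundary correction. The correction
# touches a pair (numerator, denominator) only when its rate is exactly 0 or
# 1, so interior rates are transformed untouched.
corrected_rates <- function(counts, correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$fa + counts$cr
  if (n_sig == 0) stop("hit rate undefined: no ground-truth pixels")
  if (n_noise == 0) stop("FA rate undefined: no noise pixels")
  fix <- function(k, n) {
    r <- k / n
    if (r > 0 && r < 1) return(r)
    if (correction == "loglinear") (k + 0.5) / (n + 1)
    else min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  c(hit = fix(counts$hits, n_sig), fa = fix(counts$fa, n_noise))
}

#' Sensitivity d-prime
#'
#' `d' = z(hit rate) - z(FA rate)` with z the standard-normal quantile
#' function; rates of exactly 0 or 1 are corrected first (see
#' [scoring_config()]).
#'
#' @param counts a [contingency_counts()].
#' @param correction `"loglinear"` or `"clamp"`.
#' @return d-prime (dimensionless).
#' @export
dprime <- function(counts, correction = c("loglinear", "clamp")) {
  r <- corrected_rates(counts, correction)
  stats::qnorm(r[["hit"]]) - stats::qnorm(r[["fa"]])
}

#' Response bias c
#'
#' `c = -(z(hit rate) + z(FA rate)) / 2`. Negative values indicate a bias
#' toward responding "edge present" (liberal tracing), positive values a
#' conservative bias.
#'
#' @inheritParams dprime
#' @return Bias c (dimensionless).
#' @export
response_bias <- function(counts, correction = c("loglinear", "clamp")) {
  r <- corrected_rates(counts, correction)
  -0.5 * (stats::qnorm(r[["hit"]]) + stats::qnorm(r[["fa"]]))
}

#' All SDT measures for one scored pair
#'
#' @inheritParams dprime
#' @param include_cr passed to [proportion_correct()].
#' @return A list with `p`, `dprime`, `c`.
#' @export
sdt_measures <- function(counts, correction = c("loglinear", "clamp"),
                         include_cr = FALSE) {
  list(p = proportion_correct(counts, include_cr = include_cr),
       dprime = dprime(counts, correction),
       c = response_bias(counts, correction))
}

#' Pairwise consistency of a set of trace maps
#'
#' Scores every ordered pair (signal, response) of maps of the same image
#' and summarizes proportion correct. Applied to the noise-free maps of all
#' observers it measures between-observer consistency; applied to one
#' observer's noise-free map versus their highest-contrast noisy maps it
#' measures within-observer consistency.
#'
#' @param maps list of >= 2 [trace_map()]s of equal size.
#' @param cfg a [scoring_config()].
#' @param include_cr passed to [proportion_correct()].
#' @return A list with `mean`, `sd`, `n_pairs`, and the per-pair `values`.
#' @export
pairwise_consistency <- function(maps, cfg = scoring_config(),
                                 include_cr = FALSE) {
  if (length(maps) < 2) stop("need at least 2 maps")
  idx <- which(outer(seq_along(maps), seq_along(maps), "!="), arr.ind = TRUE)
  vals <- apply(idx, 1, function(ij) {
    proportion_correct(score_traces(maps[[ij[1]]], maps[[ij[2]]], cfg),
                       include_cr = include_cr)
  })
  list(mean = mean(vals), sd = stats::sd(vals),
       n_pairs = length(vals), values = as.numeric(vals))
}
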