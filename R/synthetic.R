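#' Synthetic scene with known ground-truth edges
#'
#' Renders a scene of simple primitives (a horizon step plus rotated
#' ellipses) on a mid-gray ground, each with a known contrast amplitude, and
#' returns the exact 1-pixel boundary map. The generator exists so that
#' scoring, psychometric fitting and patch analysis can be validated
#' end-to-end against a known answer; it emulates scenes with unambiguous
#' object boundaries, not natural-image statistics.
#'
#' @param n_shapes number of ellipses (>= 0).
#' @param size_px side length in pixels (default 128 for fast simulation;
#'   use 512 for experiment-scale stimuli).
#' @param ppd pixels per degree.
#' @param contrast_range range of absolute contrast amplitudes for the
#'   primitives (relative to the mean luminance), default c(0.25, 0.6).
#' @param seed integer seed; the scene is deterministic given the seed.
#' @param blur_sd optional Gaussian blur sd in pixels applied to the
#'   rendered luminance AFTER edge extraction (edges stay exact).
#' @param mean_luminance exact mean luminance of the rendered scene
#'   (cd/m^2); the contrast field is mean-centered before rendering.
#' @param horizon add a horizon luminance step (default TRUE).
#' @param amplitude_scale global multiplier on all contrast amplitudes; the
#'   rendering is affine in this parameter, so the scene's RMS contrast
#'   scales linearly with it (up to blur).
#' @return An object of class `synthetic_scene`: list with `scene`
#'   ([luminance_image()]), `true_edges` ([trace_map()]), `catalog`
#'   (data.frame: `id`, `type`, `amplitude`, `minor`, `n_edge_px`),
#'   `edge_shape` (integer matrix assigning each edge pixel to a shape id),
#'   and `label` (region label matrix).
#' @export
make_scene <- function(n_shapes = 6, size_px = 128, ppd = 11,
                       contrast_range = c(0.25, 0.6), seed = 1L,
                       blur_sd = 0, mean_luminance = 100,
                       horizon = TRUE, amplitude_scale = 1) {
  n <- as.integer(size_px)
  stopifnot(n >= 2, n_shapes >= 0, contrast_range[1] > 0,
            contrast_range[2] >= contrast_range[1])
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)

  res <- withr::with_seed(seed, {
    label <- matrix(0L, n, n)
    amp <- numeric(0)
    type <- character(0)
    id <- 0L
    if (horizon) {
      id <- id + 1L
      h <- round(stats::runif(1, 0.3, 0.7) * n)
      label[rows > h] <- id
      amp <- c(amp, sample(c(-1, 1), 1) *
                 stats::runif(1, contrast_range[1], contrast_range[2]))
      type <- c(type, "horizon")
    }
    centers <- matrix(numeric(0), 0, 2)
    for (s in seq_len(n_shapes)) {
      id <- id + 1L
      # bias against overlap: retry centers that fall close to earlier ones
      for (try in 1:20) {
        cx <- stats::runif(1, 0.15 * n, 0.85 * n)
        cy <- stats::runif(1, 0.15 * n, 0.85 * n)
        if (nrow(centers) == 0 ||
            min((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
              (0.2 * n)^2) break
      }
      centers <- rbind(centers, c(cx, cy))
      a <- stats::runif(1, 0.06 * n, 0.18 * n)
      b <- stats::runif(1, 0.06 * n, 0.18 * n)
      th <- stats::runif(1, 0, pi)
      u <- (rows - cx) * cos(th) + (cols - cy) * sin(th)
      v <- -(rows - cx) * sin(th) + (cols - cy) * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      label[inside] <- id
      amp <- c(amp, sample(c(-1, 1), 1) *
                 stats::runif(1, contrast_range[1], contrast_range[2]))
      type <- c(type, "ellipse")
    }
    list(label = label, amp = amp, type = type)
  })
  label <- res$label; amp <- res$amp; type <- res$type

  # 1-px boundary: a pixel is an edge where the region label changes to its
  # right or downward neighbor; each edge pixel is attributed to the larger
  # of the two labels involved (later shapes occlude earlier ones)
  edge_shape <- matrix(0L, n, n)
  dright <- label[, -n] != label[, -1]
  mx <- pmax(label[, -n], label[, -1])
  sel <- which(dright)
  tmp <- edge_shape[, -n]; tmp[sel] <- pmax(tmp[sel], mx[sel])
  edge_shape[, -n] <- tmp
  ddown <- label[-n, ] != label[-1, ]
  mx <- pmax(label[-n, ], label[-1, ])
  sel <- which(ddown)
  tmp <- edge_shape[-n, ]; tmp[sel] <- pmax(tmp[sel], mx[sel])
  edge_shape[-n, ] <- tmp

  v <- matrix(0, n, n)
  for (i in seq_along(amp)) v[label == i] <- amp[i]
  # mean-centered contrast field: the scene mean is exactly mean_luminance
  # and RMS contrast is exactly linear in amplitude_scale
  v <- v - mean(v)
  values <- mean_luminance * (1 + amplitude_scale * v)
  if (blur_sd > 0) values <- gaussian_blur(values, blur_sd)

  n_edge <- vapply(seq_along(amp), function(i) sum(edge_shape == i),
                   integer(1))
  minor <- abs(amp) < contrast_range[1] + diff(contrast_range) / 3
  catalog <- data.frame(id = seq_along(amp), type = type,
                        amplitude = amp * amplitude_scale,
                        minor = minor, n_edge_px = n_edge)
  structure(list(scene = luminance_image(values, ppd),
                 true_edges = trace_map(edge_shape > 0),
                 catalog = catalog,
                 edge_shape = edge_shape,
                 label = label,
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d px, %d shapes, %d edge px, seed %d\n",
              nrow(x$scene), ncol(x$scene), nrow(x$catalog),
              sum(x$true_edges), x$seed))
  invisible(x)
}

# FFT Gaussian blur with periodic boundary; adequate for synthetic scenes.
gaussian_blur <- function(x, sd_px) {
  n <- nrow(x)
  f <- fft_freq(n) # cycles per pixel
  g <- exp(-2 * pi^2 * sd_px^2 * outer(f^2, f^2, "+"))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n^2
}

#' Synthetic observer model
#'
#' Parameters of the simulated drawing behavior: a cumulative-Gaussian
#' visibility link deciding whether each boundary segment is traced, smooth
#' spatial jitter of the drawn lines (emulating drawing inaccuracy, the
#' reason for the scoring error margin), spatially extended false traces
#' (noise mistaken for image structure), and a detail level attenuating the
#' probability of drawing minor (low-contrast) edges.
#'
#' @param jitter_sd standard deviation (px) of the smooth displacement field
#'   applied to drawn traces. Default 1.5 px, well inside the canonical
#'   13 px margin.
#' @param omission_mu,omission_sigma midpoint and slope (in effective RMS
#'   contrast units) of the visibility link
#'   `P(trace) = Phi((c_eff - omission_mu) / omission_sigma)`.
#' @param fa_rate expected number of false-trace pixels per image.
#' @param fa_contrast_dependent if TRUE, the false-trace rate shrinks as
#'   edges become more visible (observers stop mistaking noise for image
#'   structure at high contrast), which produces the decreasing-bias
#'   pattern.
#' @param detail_level probability multiplier for minor edges in \[0, 1\].
#' @param seed integer seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(jitter_sd = 1.5, omission_mu = 0.02,
                           omission_sigma = 0.01, fa_rate = 100,
                           fa_contrast_dependent = FALSE,
                           detail_level = 1, seed = 1L) {
  stopifnot(jitter_sd >= 0, omission_sigma > 0, fa_rate >= 0,
            detail_level >= 0, detail_level <= 1)
  structure(list(jitter_sd = jitter_sd, omission_mu = omission_mu,
                 omission_sigma = omission_sigma, fa_rate = fa_rate,
                 fa_contrast_dependent = isTRUE(fa_contrast_dependent),
                 detail_level = detail_level, seed = as.integer(seed)),
            class = "observer_model")
}

# Smooth random displacement field with pointwise sd `sd_px`.
smooth_field <- function(n, sd_px, corr_px = 8) {
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- fft_freq(n)
  g <- exp(-2 * pi^2 * corr_px^2 * outer(f^2, f^2, "+"))
  s <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n^2
  sd0 <- stats::sd(as.numeric(s))
  if (sd0 == 0) return(matrix(0, n, n))
  (s - mean(s)) / sd0 * sd_px
}

# One smooth false-alarm stroke: bounded-turning random walk.
fa_stroke <- function(n, max_len) {
  pos <- stats::runif(2, 2, n - 1)
  heading <- stats::runif(1, 0, 2 * pi)
  out <- matrix(0L, max_len, 2)
  k <- 0
  for (i in seq_len(max_len)) {
    pos <- pos + c(cos(heading), sin(heading))
    heading <- heading + stats::rnorm(1, 0, 0.25)
    ij <- round(pos)
    if (any(ij < 1) || any(ij > n)) break
    k <- k + 1
    out[k, ] <- as.integer(ij)
  }
  out[seq_len(k), , drop = FALSE]
}

#' Simulate one observer's trace of a stimulus
#'
#' Each boundary segment (one shape's edge) is drawn with probability given
#' by the visibility link evaluated at the segment's effective contrast
#' `image_contrast * |amplitude| / (1 + masking_strength)`; drawn segments
#' are displaced by a smooth random field with sd `jitter_sd`; false traces
#' are added as bounded-turning random-walk strokes totaling about
#' `fa_rate` pixels. With a saturated link, zero jitter and zero `fa_rate`
#' the output equals `scene$true_edges` exactly.
#'
#' @param scene a [make_scene()] result.
#' @param stim a [stimulus_spec()]; only `image_contrast` enters the
#'   visibility link (the mask's effect is summarized by
#'   `masking_strength`).
#' @param model an [observer_model()].
#' @param masking_strength non-negative attenuation parameter of the noise
#'   family in effect (0 = no noise). A single multiplicative parameter, not
#'   a mechanistic channel model.
#' @param observer_id,image_id,condition identifiers for the returned map.
#' @return A [trace_map()].
#' @export
simulate_observer <- function(scene, stim, model, masking_strength = 0,
                              observer_id = NA, image_id = NA,
                              condition = NA) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(stim, "stimulus_spec"),
            inherits(model, "observer_model"),
            masking_strength >= 0)
  n <- nrow(scene$scene)
  cat_ <- scene$catalog
  c_eff <- stim$image_contrast * abs(cat_$amplitude) / (1 + masking_strength)
  p_draw <- stats::pnorm((c_eff - model$omission_mu) / model$omission_sigma)
  p_draw[cat_$minor] <- p_draw[cat_$minor] * model$detail_level

  mask <- withr::with_seed(model$seed, {
    drawn <- stats::runif(nrow(cat_)) < p_draw
    m <- matrix(FALSE, n, n)
    if (any(drawn))
      m[scene$edge_shape %in% cat_$id[drawn]] <- TRUE
    if (model$jitter_sd > 0 && any(m)) {
      dy <- smooth_field(n, model$jitter_sd)
      dx <- smooth_field(n, model$jitter_sd)
      ij <- which(m, arr.ind = TRUE)
      ii <- pmin(pmax(ij[, 1] + round(dy[ij]), 1L), n)
      jj <- pmin(pmax(ij[, 2] + round(dx[ij]), 1L), n)
      m <- matrix(FALSE, n, n)
      m[cbind(ii, jj)] <- TRUE
    }
    rate <- model$fa_rate
    if (model$fa_contrast_dependent && nrow(cat_) > 0)
      rate <- rate * (1 - mean(p_draw))
    if (rate > 0) {
      n_fa <- stats::rpois(1, rate)
      placed <- 0
      while (placed < n_fa) {
        st <- fa_stroke(n, min(40, n_fa - placed))
        if (nrow(st)) {
          m[st] <- TRUE
          placed <- placed + nrow(st)
        } else placed <- placed + 1 # stroke left the image immediately
      }
    }
    m
  })
  trace_map(mask, observer_id = observer_id, image_id = image_id,
            condition = condition)
}

#' Generate a randomized trial design
#'
#' Per observer, every image identity appears exactly once and its condition
#' (noise family x contrast level) is drawn uniformly from the condition
#' grid, mirroring the two-session design in which a given condition falls
#' on different image identities across observers.
#'
#' @param n_images number of images per observer.
#' @param contrasts named list mapping each noise family to its vector of
#'   image-contrast levels (the per-condition levels are chosen in piloting
#'   and are configuration, not derived).
#' @param n_observers number of observers.
#' @param seed integer seed.
#' @return data.frame with columns `observer_id`, `trial`, `image_id`,
#'   `noise_family`, `level` (index into the family's contrast vector), and
#'   `image_contrast`.
#' @export
generate_design <- function(n_images = 30, contrasts, n_observers = 20,
                            seed = 1L) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1,
            !is.null(names(contrasts)))
  families <- names(contrasts)
  n_levels <- lengths(contrasts)
  cells <- data.frame(
    noise_family = rep(families, n_levels),
    level = unlist(lapply(n_levels, seq_len), use.names = FALSE))
  if (n_images < 1) stop("`n_images` must be >= 1")
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_observers), function(o) {
      imgs <- sample.int(n_images) # each image identity exactly once
      pick <- sample.int(nrow(cells), n_images, replace = TRUE)
      data.frame(observer_id = o, trial = seq_len(n_images),
                 image_id = imgs,
                 noise_family = cells$noise_family[pick],
                 level = cells$level[pick],
                 image_contrast = vapply(seq_len(n_images), function(t) {
                   contrasts[[cells$noise_family[pick[t]]]][cells$level[pick[t]]]
                 }, numeric(1)))
    }))
  })
}

#' Default per-family contrast levels for a simulated experiment
#'
#' Emulates the piloting step of the real design: levels are placed around
#' each family's expected visibility midpoint
#' `omission_mu * (1 + masking_strength) / E|amplitude|` so that every
#' psychometric function is sampled from floor to saturation.
#'
#' @param masking_strengths named numeric vector of per-family attenuation.
#' @param model an [observer_model()] (for the link midpoint).
#' @param mean_amplitude expected absolute contrast amplitude of scene
#'   primitives.
#' @param spread multipliers defining the 5 levels around the midpoint.
#' @return Named list of contrast vectors, one per family.
#' @export
pilot_contrasts <- function(masking_strengths, model = observer_model(),
                            mean_amplitude = 0.425,
                            spread = c(0.4, 0.7, 1.0, 1.5, 2.4)) {
  stats::setNames(lapply(names(masking_strengths), function(f) {
    mid <- model$omission_mu * (1 + masking_strengths[[f]]) / mean_amplitude
    mid * spread
  }), names(masking_strengths))
}

#' End-to-end recovery harness
#'
#' Simulates a complete experiment (scenes, per-observer ground-truth
#' session at high contrast without noise, noisy session from a randomized
#' design), scores every noisy trace against the same observer's
#' ground-truth map, fits a max-scaled cumulative Gaussian per noise family,
#' and reports whether the injected ordering of masking strengths is
#' recovered in the fitted thresholds.
#'
#' @param n_observers,n_images experiment size (defaults 20 x 30, the scale
#'   of the real design).
#' @param size_px,ppd scene geometry. The default 128 px / 11 ppd keeps the
#'   simulated field of view near 11.6 deg while keeping scoring fast; the
#'   error margin still resolves to 2.5% of the image side.
#' @param masking_strengths named numeric vector, one entry per simulated
#'   noise family; the *ordering* of these values is the recovery target.
#' @param gt_contrast contrast of the ground-truth session (default 0.16).
#' @param model base [observer_model()]; each observer/trial gets a derived
#'   seed.
#' @param scoring_cfg a [scoring_config()].
#' @param contrasts optional named list of per-family contrast levels;
#'   default [pilot_contrasts()].
#' @param seed master seed.
#' @return A list with `scores` (per-trial data.frame), `fits` (per-family
#'   [fit_cumulative_gaussian()] results), `thresholds` (named vector),
#'   `masking_strengths`, `ordering_recovered` (logical), and
#'   `midpoint_ratio` (fitted mu over the design-predicted midpoint, per
#'   family).
#' @export
end_to_end_recovery <- function(n_observers = 20, n_images = 30,
                                size_px = 128, ppd = 11,
                                masking_strengths = c(brown = 1, pink = 2,
                                                      white = 3),
                                gt_contrast = 0.16,
                                model = observer_model(),
                                scoring_cfg = scoring_config(),
                                contrasts = NULL,
                                seed = 1L) {
  if (is.null(contrasts))
    contrasts <- pilot_contrasts(masking_strengths, model)
  design <- generate_design(n_images, contrasts, n_observers,
                            seed = seed)
  scenes <- lapply(seq_len(n_images), function(i)
    make_scene(size_px = size_px, ppd = ppd, seed = seed * 1000L + i))

  trial_seed <- function(o, img, tag)
    (seed * 7L + o * 101L + img * 13L + tag) %% 2147483647L

  gt_maps <- lapply(seq_len(n_observers), function(o) {
    lapply(seq_len(n_images), function(i) {
      m <- model; m$seed <- trial_seed(o, i, 0L)
      simulate_observer(scenes[[i]], stimulus_spec(gt_contrast), m,
                        masking_strength = 0,
                        observer_id = o, image_id = i,
                        condition = "ground_truth")
    })
  })

  scores <- do.call(rbind, lapply(seq_len(nrow(design)), function(r) {
    d <- design[r, ]
    m <- model; m$seed <- trial_seed(d$observer_id, d$image_id, 1e6L)
    resp <- simulate_observer(
      scenes[[d$image_id]], stimulus_spec(d$image_contrast), m,
      masking_strength = masking_strengths[[d$noise_family]],
      observer_id = d$observer_id, image_id = d$image_id,
      condition = d$noise_family)
    cnt <- score_traces(gt_maps[[d$observer_id]][[d$image_id]], resp,
                        scoring_cfg)
    meas <- sdt_measures(cnt)
    cbind(d, p = meas$p, dprime = meas$dprime, c = meas$c,
          hits = cnt$hits, misses = cnt$misses, fa = cnt$fa, cr = cnt$cr)
  }))

  families <- names(masking_strengths)
  fits <- stats::setNames(lapply(families, function(f) {
    sub <- scores[scores$noise_family == f, ]
    agg <- stats::aggregate(p ~ level, data = sub, FUN = mean)
    nper <- stats::aggregate(p ~ level, data = sub, FUN = length)
    pd <- psychometric_data(contrasts[[f]][agg$level], agg$p,
                            weights = nper$p * 50) # effective counts knob
    fit_cumulative_gaussian(scale_by_max(pd))
  }), families)
  thresholds <- vapply(fits, function(f) f$threshold, numeric(1))

  mean_amp <- mean(vapply(scenes, function(s) mean(abs(s$catalog$amplitude)),
                          numeric(1)))
  predicted_mid <- vapply(families, function(f)
    model$omission_mu * (1 + masking_strengths[[f]]) / mean_amp, numeric(1))

  list(scores = scores,
       fits = fits,
       thresholds = thresholds,
       masking_strengths = masking_strengths,
       ordering_recovered = identical(order(thresholds),
                                      order(unlist(masking_strengths))),
       midpoint_ratio = vapply(fits, function(f) f$mu, numeric(1)) /
         predicted_mid)
}
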