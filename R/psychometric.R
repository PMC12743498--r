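#' Psychometric data: proportion correct versus image contrast
#'
#' @param contrasts strictly positive RMS contrast levels.
#' @param p_values proportion correct per level, in \[0, 1\].
#' @param weights effective trial counts per level. Pixel counts from trace
#'   scoring are not independent Bernoulli trials, so the weights should be
#'   an *effective* count (a config knob), not the raw pixel count; only
#'   relative weights matter for the fit. Default: equal weights.
#' @return An object of class `psychometric_data`, sorted by contrast.
#' @export
psychometric_data <- function(contrasts, p_values, weights = NULL) {
  if (length(contrasts) != length(p_values))
    stop("`contrasts` and `p_values` lengths differ")
  if (length(contrasts) == 0) stop("empty data")
  if (any(contrasts <= 0)) stop("contrasts must be strictly positive")
  if (any(p_values < 0 | p_values > 1)) stop("p_values must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(contrasts))
  if (any(weights <= 0)) stop("weights must be positive")
  o <- order(contrasts)
  structure(list(contrasts = as.numeric(contrasts[o]),
                 p_values = as.numeric(p_values[o]),
                 weights = as.numeric(weights[o]),
                 pmax = NA_real_),
            class = "psychometric_data")
}

#' Scale performance by its observed maximum
#'
#' Observers' maximum proportion correct stays well below 1 even at the
#' highest contrasts (their noisy traces never perfectly match their own
#' ground truths), so the psychometric function is fitted on data scaled by
#' the maximum performance `pmax`; `pmax` is carried in the returned object.
#'
#' @param data a [psychometric_data()].
#' @param pmax optional explicit maximum; default is the observed maximum.
#' @return A [psychometric_data()] with `p_values` divided by `pmax` and the
#'   `pmax` field set.
#' @export
scale_by_max <- function(data, pmax = NULL) {
  stopifnot(inherits(data, "psychometric_data"))
  if (is.null(pmax)) pmax <- max(data$p_values)
  if (pmax <= 0) stop("cannot scale: maximum performance is zero")
  if (stats::sd(data$p_values) == 0)
    warning("constant performance: scaled data are degenerate (all 1)")
  out <- data
  out$p_values <- pmin(data$p_values / pmax, 1)
  out$pmax <- pmax
  out
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Fits `p(x) = gamma + (1 - gamma - lambda) * Phi((x - mu) / sigma)` to
#' (scaled) proportion correct by penalized maximum likelihood with a
#' weighted binomial likelihood on effective counts. The guess rate `gamma`
#' is fixed (default 0, appropriate for proportion correct without correct
#' rejections); the lapse rate `lambda` is free within `[0, lapse_max]`
#' with a mild quadratic penalty toward 0. Optimization restarts from a
#' deterministic grid of start values, so the fit is a deterministic
#' function of the data.
#'
#' @param data a [psychometric_data()] (usually after [scale_by_max()]).
#' @param gamma fixed guess rate (default 0).
#' @param lapse_max upper bound for the lapse rate (default 0.05).
#' @param criterion performance criterion, as a fraction of the scaled
#'   range, at which the default threshold is read off (default 0.5, i.e.
#'   the curve midpoint `mu`).
#' @return An object of class `psychometric_fit` with fields `mu`, `sigma`,
#'   `lambda`, `gamma`, `pmax`, `threshold`, `gof` (residual deviance and a
#'   degeneracy flag), and `logLik`.
#' @export
fit_cumulative_gaussian <- function(data, gamma = 0, lapse_max = 0.05,
                                    criterion = 0.5) {
  stopifnot(inherits(data, "psychometric_data"))
  x <- data$contrasts; p <- data$p_values; w <- data$weights
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct contrast levels")
  wn <- w / sum(w) # uniform weight rescaling cannot change the fit
  rng <- diff(range(x))

  nll <- function(th) {
    mu <- th[1]; sigma <- exp(th[2]); lam <- th[3]
    ph <- gamma + (1 - gamma - lam) * stats::pnorm((x - mu) / sigma)
    ph <- pmin(pmax(ph, 1e-9), 1 - 1e-9)
    -sum(wn * (p * log(ph) + (1 - p) * log1p(-ph))) +
      1e-3 * (lam / lapse_max)^2
  }

  # deterministic multi-start: candidate midpoints from quantiles plus the
  # interpolated 50% crossing, three slope scales
  mu0 <- unique(c(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                  tryCatch(stats::approx(p, x, xout = 0.5, ties = mean)$y,
                           error = function(e) NA)))
  mu0 <- mu0[is.finite(mu0)]
  sig0 <- rng * c(0.1, 0.25, 0.5)
  starts <- expand.grid(mu = mu0, lsig = log(sig0))
  lower <- c(min(x) - 2 * rng, log(rng * 1e-3), 0)
  upper <- c(max(x) + 2 * rng, log(rng * 1e2), lapse_max)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- c(starts$mu[i], starts$lsig[i], min(0.01, lapse_max))
    fit <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop("optimization failed from every start value")

  mu <- best$par[1]; sigma <- exp(best$par[2]); lambda <- best$par[3]
  phat <- gamma + (1 - gamma - lambda) * stats::pnorm((x - mu) / sigma)
  phat <- pmin(pmax(phat, 1e-9), 1 - 1e-9)
  pobs <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  # residual deviance against the saturated model, on effective counts
  dev <- 2 * sum(w * (pobs * log(pobs / phat) +
                        (1 - pobs) * log((1 - pobs) / (1 - phat))))
  degenerate <- !any(diff(p) > 0) || sigma <= rng * 1.5e-3 ||
    mu < min(x) - rng || mu > max(x) + rng
  if (degenerate)
    warning("degenerate psychometric data: fit returned with gof flag")

  fit <- structure(list(mu = mu, sigma = sigma, lambda = lambda,
                        gamma = gamma, pmax = data$pmax,
                        gof = list(deviance = dev, df = length(x) - 3,
                                   degenerate = degenerate),
                        logLik = -best$value, data = data),
                   class = "psychometric_fit")
  fit$threshold <- threshold_at(fit, criterion)
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> mu %.4g  sigma %.4g  lambda %.3g%s  threshold %.4g%s\n",
    x$mu, x$sigma, x$lambda,
    if (is.na(x$pmax)) "" else sprintf("  pmax %.3g", x$pmax),
    x$threshold,
    if (x$gof$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Predicted (scaled) proportion correct
#'
#' @param object a `psychometric_fit`.
#' @param x contrast values.
#' @param ... unused.
#' @export
predict.psychometric_fit <- function(object, x, ...) {
  object$gamma + (1 - object$gamma - object$lambda) *
    stats::pnorm((x - object$mu) / object$sigma)
}

#' Contrast threshold at a performance criterion
#'
#' Inverts the fitted curve at a criterion expressed as a fraction of the
#' scaled range between the asymptotes; 0.5 gives the midpoint `mu`, and
#' `Phi(1) ~ 0.841` gives `mu + sigma`.
#'
#' @param fit a `psychometric_fit`.
#' @param criterion fraction of the scaled range, strictly in (0, 1).
#' @return Contrast at the criterion.
#' @export
threshold_at <- function(fit, criterion = 0.5) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (criterion <= 0 || criterion >= 1)
    stop("`criterion` must lie strictly between the asymptotes (0, 1)")
  fit$mu + fit$sigma * stats::qnorm(criterion)
}

#' Pearson correlation between two threshold patterns
#'
#' Compares a pattern of per-condition thresholds (e.g. the six noise
#' conditions) against a reference pattern from another experiment.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @export
correlate_patterns <- function(a, b) {
  if (length(a) != length(b)) stop("patterns have different lengths")
  if (length(a) < 3) stop("need at least 3 conditions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: a pattern has zero variance")
  stats::cor(a, b)
}

#' Bootstrap confidence interval for a fitted threshold
#'
#' Nonparametric bootstrap over observers: observers are resampled with
#' replacement, per-contrast performance is re-averaged, the scaled
#' cumulative Gaussian is refitted, and the threshold recomputed. Stands in
#' for credible intervals of a Bayesian fitter.
#'
#' @param df data.frame with columns `observer`, `contrast`, `p`, and
#'   optionally `weight`.
#' @param n_boot number of resamples (default 1000).
#' @param level interval coverage (default 0.68).
#' @param criterion threshold criterion, see [threshold_at()].
#' @param seed integer seed.
#' @return A list with `threshold` (point estimate), `lower`, `upper`, and
#'   the bootstrap `samples`.
#' @export
bootstrap_threshold_ci <- function(df, n_boot = 1000, level = 0.68,
                                   criterion = 0.5, seed = 1L) {
  stopifnot(all(c("observer", "contrast", "p") %in% names(df)))
  if (is.null(df$weight)) df$weight <- 1
  obs <- unique(df$observer)
  fit_from <- function(d) {
    agg <- stats::aggregate(cbind(p, weight) ~ contrast, data = d,
                            FUN = function(z) mean(z))
    pd <- scale_by_max(psychometric_data(agg$contrast, agg$p,
                                         agg$weight * nrow(d)))
    threshold_at(fit_cumulative_gaussian(pd), criterion)
  }
  point <- fit_from(df)
  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      pick <- sample(obs, length(obs), replace = TRUE)
      d <- do.call(rbind, lapply(pick, function(o) df[df$observer == o, ]))
      tryCatch(fit_from(d), error = function(e) NA_real_)
    }, numeric(1))
  })
  qs <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(threshold = point, lower = qs[1], upper = qs[2], samples = samples)
}
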