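test_that("stacking conserves trace mass and bounds counts", {
  maps <- lapply(1:20, function(i) rand_trace(32, density = 0.1, seed = i))
  hm <- stack_ground_truths(maps)
  expect_equal(sum(hm), sum(vapply(maps, sum, numeric(1))))
  expect_true(all(hm >= 0 & hm <= 20))
  expect_equal(attr(hm, "n_observers"), 20)

  same <- stack_ground_truths(rep(list(maps[[1]]), 20))
  expect_true(all(unique(as.numeric(same)) %in% c(0, 20)))
  expect_error(stack_ground_truths(list(rand_trace(16), rand_trace(24))),
               "different sizes")
})

test_that("stacked counts match the binomial expectation", {
  # each of 40 observers marks each pixel independently with prob 0.3
  n <- 48; prob <- 0.3; n_obs <- 40
  maps <- lapply(seq_len(n_obs), function(i)
    withr::with_seed(500 + i, trace_map(matrix(runif(n * n) < prob, n, n))))
  hm <- stack_ground_truths(maps)
  expect_equal(mean(hm), n_obs * prob, tolerance = 0.03)
  expect_equal(var(as.numeric(hm)), n_obs * prob * (1 - prob),
               tolerance = 0.1)
})

test_that("category rules reproduce the 20-observer thresholds", {
  n <- 60
  counts <- matrix(0L, n, n)
  counts[30, 30] <- 10L  # traced by 10 of 20
  counts[10, 10] <- 19L
  counts[15, 15] <- 4L
  hm <- structure(counts, n_observers = 20L,
                  class = c("consensus_heatmap", "matrix", "array"))
  sal <- consensus_category(hm, "salient") # >= ceil(0.95*20) = 19
  some <- consensus_category(hm, "some")   # 5..15
  none <- consensus_category(hm, "none")
  expect_true(sal[10, 10]); expect_false(sal[30, 30])
  expect_true(some[30, 30]); expect_false(some[10, 10])
  expect_false(some[15, 15]) # 4 < 0.25*20
  expect_false(none[30, 30]); expect_true(none[1, 1])
  # categories are disjoint by construction
  expect_false(any(sal & some) || any(sal & none) || any(some & none))
})

test_that("sample_patches respects interior, spacing, and category", {
  n <- 200
  maps <- lapply(1:20, function(i) rand_trace(n, density = 0.15, seed = i))
  hm <- stack_ground_truths(maps)
  scene <- make_scene(seed = 8, size_px = n)$scene
  ps <- sample_patches(hm, scene, "some", k = 10, seed = 3)
  expect_lte(nrow(ps$centers), 10)
  expect_gt(nrow(ps$centers), 0)
  half <- 25
  expect_true(all(ps$centers$row > half & ps$centers$row <= n - half))
  expect_true(all(ps$centers$col > half & ps$centers$col <= n - half))
  if (nrow(ps$centers) > 1) {
    d2 <- as.matrix(dist(ps$centers[, c("row", "col")]))^2
    expect_true(all(d2[upper.tri(d2)] >= 51^2))
  }
  # every returned patch is 51x51 and cut from the scene
  expect_true(all(vapply(ps$patches, function(p) all(dim(p) == 51),
                         logical(1))))
  i <- 1
  expect_equal(ps$patches[[i]][26, 26],
               unclass(scene)[ps$centers$row[i], ps$centers$col[i]])
  # deterministic given seed
  ps2 <- sample_patches(hm, scene, "some", k = 10, seed = 3)
  expect_identical(ps$centers, ps2$centers)
  # scarce categories warn and return what exists
  empty <- stack_ground_truths(lapply(1:20, function(i)
    trace_map(matrix(0L, n, n))))
  expect_warning(sp <- sample_patches(empty, scene, "some", k = 5, seed = 1),
                 "no eligible|available")
  expect_equal(length(sp$patches), 0)
})

test_that("patch features are mean and std/mean", {
  expect_equal(patch_features(matrix(100, 51, 51)),
               list(mean_luminance = 100, rms_contrast = 0))
  step <- cbind(matrix(50, 50, 25), matrix(150, 50, 25))
  f <- patch_features(step)
  expect_equal(f$mean_luminance, 100)
  expect_equal(f$rms_contrast, 0.5)
})

test_that("synthetic edge patches have higher contrast than flat patches", {
  sc <- make_scene(seed = 12, size_px = 200, n_shapes = 5)
  maps <- lapply(1:20, function(i) {
    m <- observer_model(jitter_sd = 0, omission_mu = -5, omission_sigma = 1,
                        fa_rate = 0, seed = 600 + i)
    simulate_observer(sc, stimulus_spec(0.16), m)
  })
  hm <- stack_ground_truths(maps)
  sal <- sample_patches(hm, sc$scene, "salient", k = 8, seed = 2)
  non <- sample_patches(hm, sc$scene, "none", k = 8, seed = 2)
  rms_of <- function(ps) vapply(ps$patches,
                                function(p) patch_features(p)$rms_contrast,
                                numeric(1))
  expect_gt(mean(rms_of(sal)), mean(rms_of(non)))
})

test_that("directional power separates edge orientations", {
  ppd <- 44; n <- 51
  # horizontal edge (luminance varies down the rows)
  edge <- rbind(matrix(60, 25, n), matrix(140, 26, n))
  dv <- directional_power(edge, "vertical", ppd)
  dh <- directional_power(edge, "horizontal", ppd)
  expect_gt(sum(dv$power), 10 * sum(dh$power))
  # pure vertical sinusoid: all power at f0 on the horizontal axis
  f0 <- 6
  patch <- matrix(100 + 20 * sin(2 * pi * f0 * (0:(n - 1)) / ppd),
                  n, n, byrow = TRUE)
  dh2 <- directional_power(patch, "horizontal", ppd, window = "none")
  expect_equal(dh2$sf[which.max(dh2$power)], f0, tolerance = ppd / n / f0)
  dv2 <- directional_power(patch, "vertical", ppd, window = "none")
  expect_lt(sum(dv2$power), 1e-10 * sum(dh2$power) + 1e-12)
})

test_that("white-noise patches are directionally isotropic", {
  tot <- vapply(1:20, function(s) {
    w <- withr::with_seed(s, matrix(rnorm(51^2), 51, 51))
    c(sum(directional_power(w, "vertical", 44, window = "none")$power),
      sum(directional_power(w, "horizontal", 44, window = "none")$power))
  }, numeric(2))
  expect_equal(mean(tot[1, ]), mean(tot[2, ]), tolerance = 0.05)
})

test_that("total FFT power equals the patch variance (Parseval)", {
  w <- withr::with_seed(77, matrix(rnorm(51^2, 100, 15), 51, 51))
  dp <- directional_power(w, "vertical", 44, wedge_deg = 180,
                          window = "none")
  expect_equal(attr(dp, "total_power"), mean((w - mean(w))^2),
               tolerance = 1e-8)
})

test_that("normalization divides by the maximum power", {
  w <- withr::with_seed(5, matrix(rnorm(51^2), 51, 51))
  dp <- directional_power(w, "vertical", 44, normalize = TRUE)
  expect_equal(max(dp$power), 1)
})
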