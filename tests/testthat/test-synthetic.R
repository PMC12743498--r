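test_that("make_scene handles the empty and single-shape cases", {
  empty <- make_scene(n_shapes = 0, horizon = FALSE, seed = 1)
  expect_true(all(empty$scene == 100))
  expect_equal(sum(empty$true_edges), 0)

  one <- make_scene(n_shapes = 1, horizon = FALSE, seed = 4, size_px = 96)
  # one ellipse -> its boundary is a single closed 8-connected curve
  expect_equal(count_components(unclass(one$true_edges)), 1)
  expect_gt(sum(one$true_edges), 0)
})

test_that("every true-edge pixel sits on a luminance discontinuity", {
  sc <- make_scene(seed = 9, size_px = 96)
  lab <- sc$label
  idx <- which(unclass(sc$true_edges) == 1L, arr.ind = TRUE)
  n <- nrow(lab)
  on_boundary <- apply(idx, 1, function(p) {
    i <- p[1]; j <- p[2]
    nb <- rbind(c(i + 1, j), c(i - 1, j), c(i, j + 1), c(i, j - 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n, ,
             drop = FALSE]
    any(lab[nb] != lab[i, j])
  })
  expect_true(all(on_boundary))
})

test_that("scene RMS contrast is linear in the amplitude scale", {
  r1 <- rms_contrast(make_scene(seed = 6, amplitude_scale = 0.5)$scene)
  r2 <- rms_contrast(make_scene(seed = 6, amplitude_scale = 1)$scene)
  r4 <- rms_contrast(make_scene(seed = 6, amplitude_scale = 2)$scene)
  expect_equal(r2 / r1, 2, tolerance = 1e-10)
  expect_equal(r4 / r2, 2, tolerance = 1e-10)
})

test_that("scenes and observers are deterministic given seeds", {
  a <- make_scene(seed = 31); b <- make_scene(seed = 31)
  expect_identical(unclass(a$scene), unclass(b$scene))
  m <- observer_model(seed = 7)
  t1 <- simulate_observer(a, stimulus_spec(0.1), m)
  t2 <- simulate_observer(b, stimulus_spec(0.1), m)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("a noiseless saturated observer reproduces the true edges", {
  sc <- make_scene(seed = 2)
  m <- observer_model(jitter_sd = 0, omission_mu = -10, omission_sigma = 0.1,
                      fa_rate = 0, detail_level = 1)
  tm <- simulate_observer(sc, stimulus_spec(0.16), m)
  expect_identical(unclass(tm), unclass(sc$true_edges))
})

test_that("uniform omission probability yields the expected hit rate", {
  # near-equal amplitudes + a link placed so P(draw) = q for every segment
  q <- 0.7
  c_img <- 0.16; amp <- 0.25; sigma <- 0.01
  mu <- c_img * amp - qnorm(q) * sigma
  hit_rates <- vapply(1:50, function(s) {
    sc <- make_scene(n_shapes = 12, horizon = FALSE, seed = 900 + s,
                     contrast_range = c(amp, amp + 1e-7))
    m <- observer_model(jitter_sd = 0, omission_mu = mu,
                        omission_sigma = sigma, fa_rate = 0, seed = s)
    tm <- simulate_observer(sc, stimulus_spec(c_img), m)
    cnt <- score_traces(sc$true_edges, tm, scoring_config(margin_px = 0))
    cnt$hits / (cnt$hits + cnt$misses)
  }, numeric(1))
  expect_equal(mean(hit_rates), q, tolerance = 0.05)
})

test_that("jitter hurts strict scoring but is absorbed by the margin", {
  sc <- make_scene(seed = 3, size_px = 128)
  m <- observer_model(jitter_sd = 3, omission_mu = -10, omission_sigma = 0.1,
                      fa_rate = 0, seed = 11)
  tm <- simulate_observer(sc, stimulus_spec(0.16), m)
  p0 <- proportion_correct(score_traces(sc$true_edges, tm,
                                        scoring_config(margin_px = 0)))
  p13 <- proportion_correct(score_traces(sc$true_edges, tm,
                                         scoring_config(margin_px = 13)))
  expect_gt(p13, p0)
  expect_gt(p13, 0.95) # 3 px jitter is far inside a 13 px margin
})

test_that("the visibility link gates drawing on contrast", {
  sc <- make_scene(seed = 13)
  m <- observer_model(jitter_sd = 0, omission_mu = 0.05,
                      omission_sigma = 0.005, fa_rate = 0)
  # far below the link midpoint: nothing is drawn
  lo <- simulate_observer(sc, stimulus_spec(0.01), m)
  expect_equal(sum(lo), 0)
  # far above: everything is drawn
  hi <- simulate_observer(sc, stimulus_spec(0.9), m)
  expect_identical(unclass(hi), unclass(sc$true_edges))
  # masking attenuates effective contrast
  masked <- simulate_observer(sc, stimulus_spec(0.9), m,
                              masking_strength = 50)
  expect_equal(sum(masked), 0)
})

test_that("false traces are spatially extended strokes at the target rate", {
  sc <- make_scene(n_shapes = 0, horizon = FALSE, seed = 1, size_px = 128)
  m <- observer_model(jitter_sd = 0, omission_mu = 10, omission_sigma = 0.1,
                      fa_rate = 200, seed = 21)
  counts <- vapply(1:20, function(s) {
    m$seed <- s
    sum(simulate_observer(sc, stimulus_spec(0.1), m))
  }, numeric(1))
  expect_equal(mean(counts), 200, tolerance = 0.1)
  # strokes are extended curves, not salt-and-pepper: far fewer connected
  # components than pixels
  m$seed <- 3
  tm <- simulate_observer(sc, stimulus_spec(0.1), m)
  expect_lt(count_components(unclass(tm)), sum(tm) / 5)
})

test_that("generate_design satisfies the design constraints", {
  contrasts <- list(white = 1:5 / 50, pink = 1:5 / 40, brown = 1:5 / 30,
                    nb05 = 1:5 / 25, nb3 = 1:5 / 20, nb9 = 1:5 / 15)
  d <- generate_design(30, contrasts, n_observers = 12, seed = 2)
  # 5 contrasts x 6 noises = 30 condition cells
  expect_equal(nrow(unique(do.call(rbind, lapply(names(contrasts), function(f)
    data.frame(f, seq_along(contrasts[[f]])))))), 30)
  for (o in unique(d$observer_id)) {
    sub <- d[d$observer_id == o, ]
    expect_equal(sort(sub$image_id), 1:30) # each image exactly once
    expect_true(all(sub$image_contrast ==
                      mapply(function(f, l) contrasts[[f]][l],
                             sub$noise_family, sub$level)))
  }
  expect_identical(d, generate_design(30, contrasts, n_observers = 12,
                                      seed = 2))
})

test_that("condition assignment is uniform over the grid", {
  contrasts <- list(a = 1:5 / 50, b = 1:5 / 40, c = 1:5 / 30)
  d <- generate_design(30, contrasts, n_observers = 60, seed = 5)
  tab <- table(paste(d$noise_family, d$level))
  expect_equal(length(tab), 15)
  cs <- suppressWarnings(chisq.test(tab))
  expect_gt(cs$p.value, 0.001)
})
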