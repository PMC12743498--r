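test_that("identity scoring is perfect at any margin", {
  m <- rand_trace(48, density = 0.1, seed = 21)
  for (r in c(0, 3, 13)) {
    cnt <- score_traces(m, m, scoring_config(margin_px = r))
    expect_equal(cnt$hits, sum(m))
    expect_equal(cnt$misses, 0)
    expect_equal(cnt$fa, 0)
    expect_equal(proportion_correct(cnt), 1)
  }
})

test_that("single-pixel pairs respect the Euclidean margin", {
  a <- single_px_map(64, 32, 10)
  b20 <- single_px_map(64, 32, 30) # distance 20 > 13
  b10 <- single_px_map(64, 32, 20) # distance 10 <= 13
  cfg <- scoring_config(margin_px = 13)
  c1 <- score_traces(a, b20, cfg)
  expect_equal(c(c1$hits, c1$fa, c1$misses), c(0, 1, 1))
  c2 <- score_traces(a, b10, cfg)
  expect_equal(c(c2$hits, c2$fa, c2$misses), c(1, 0, 0))
  # exactly on the rim: distance 13 counts, 13.04 does not
  c3 <- score_traces(a, single_px_map(64, 32, 23), cfg)   # dist 13
  expect_equal(c3$hits, 1)
  c4 <- score_traces(a, single_px_map(64, 37, 22), cfg)   # dist 13.0
  expect_equal(c4$hits, 1) # 5-12-13 triangle
})

test_that("margin_fraction resolves to round(frac * size)", {
  cfg <- scoring_config(margin_fraction = 0.025)
  a <- rand_trace(64, seed = 1); b <- rand_trace(64, seed = 2)
  expect_equal(attr(score_traces(a, b, cfg), "margin_px"), 2) # round(1.6)
  expect_error(scoring_config(margin_px = 3, margin_fraction = 0.1),
               "exactly one")
  expect_error(scoring_config(margin_px = -1), "non-negative")
})

test_that("dilation scorer matches the brute-force oracle on small maps", {
  for (seed in 1:6) {
    gt <- rand_trace(24, density = 0.08, seed = seed)
    rp <- rand_trace(24, density = 0.08, seed = seed + 100)
    for (r in c(0, 1, 2, 5)) {
      for (rule in c("dilated_response", "strict")) {
        got <- score_traces(gt, rp, scoring_config(margin_px = r,
                                                   miss_rule = rule))
        want <- brute_score(gt, rp, r, rule)
        expect_equal(got$hits, want$hits)
        expect_equal(got$misses, want$misses)
        expect_equal(got$fa, want$fa)
        expect_equal(got$cr, want$cr)
      }
    }
  }
})

test_that("counts partition the grid and respect count-domain bounds", {
  for (seed in 1:8) {
    gt <- rand_trace(40, density = 0.07, seed = seed)
    rp <- rand_trace(40, density = 0.07, seed = seed + 50)
    cnt <- score_traces(gt, rp, scoring_config(margin_px = 3))
    expect_equal(cnt$hits + cnt$misses + cnt$fa + cnt$cr, cnt$n_pixels)
    expect_equal(cnt$hits + cnt$fa, sum(rp))
    expect_lte(cnt$misses, sum(gt))
  }
})

test_that("hits grow and false alarms shrink with the margin", {
  gt <- rand_trace(48, density = 0.05, seed = 3)
  rp <- rand_trace(48, density = 0.05, seed = 4)
  prev_h <- -1; prev_fa <- Inf
  for (r in 0:8) {
    cnt <- score_traces(gt, rp, scoring_config(margin_px = r))
    expect_gte(cnt$hits, prev_h)
    expect_lte(cnt$fa, prev_fa)
    prev_h <- cnt$hits; prev_fa <- cnt$fa
  }
})

test_that("size and binarity violations are rejected", {
  expect_error(score_traces(rand_trace(16), rand_trace(24)), "sizes differ")
  expect_error(trace_map(matrix(c(0, 0.5, 1, 1), 2)), "binary")
})

test_that("proportion correct follows both definitions", {
  cnt <- contingency_counts(60, 20, 20, 900, 1000)
  expect_equal(proportion_correct(cnt), 0.6)
  cnt2 <- contingency_counts(10, 0, 0, 990, 1000)
  expect_equal(proportion_correct(cnt2), 1)
  expect_equal(proportion_correct(cnt2, include_cr = TRUE), 1)
  cnt3 <- contingency_counts(10, 10, 20, 960, 1000)
  expect_equal(proportion_correct(cnt3, include_cr = TRUE), 0.97)
  empty <- contingency_counts(0, 0, 0, 100, 100)
  expect_error(proportion_correct(empty), "undefined")
})

test_that("d-prime and bias match the quantile oracle", {
  # rates chosen to be exactly representable as count ratios
  cnt <- contingency_counts(69, 31, 31, 69, 200)
  expect_equal(dprime(cnt), 2 * z_oracle(0.69), tolerance = 1e-8)
  expect_equal(response_bias(cnt), 0, tolerance = 1e-12)
  cnt2 <- contingency_counts(50, 50, 50, 50, 200)
  expect_equal(dprime(cnt2), 0)
  expect_equal(response_bias(cnt2), 0)
  cnt3 <- contingency_counts(90, 10, 50, 50, 200)
  expect_equal(response_bias(cnt3), -0.5 * z_oracle(0.9), tolerance = 1e-8)
  expect_error(dprime(contingency_counts(0, 0, 3, 7, 10)), "hit rate")
})

test_that("boundary rates are corrected, interior rates untouched", {
  cnt <- contingency_counts(100, 0, 0, 100, 200) # rates 1 and 0
  d_ll <- dprime(cnt, "loglinear")
  expect_true(is.finite(d_ll))
  expect_equal(d_ll, qnorm(100.5 / 101) - qnorm(0.5 / 101))
  d_cl <- dprime(cnt, "clamp")
  expect_equal(d_cl, qnorm(1 - 1 / 200) - qnorm(1 / 200))
  # d' and c from the same corrected rates are mutually consistent
  for (seed in 1:5) {
    cnt <- withr::with_seed(seed, {
      h <- sample(0:50, 1); m <- sample(1:50, 1)
      f <- sample(0:50, 1); c0 <- sample(1:50, 1)
      contingency_counts(h, m, f, c0, h + m + f + c0)
    })
    d <- dprime(cnt); cc <- response_bias(cnt)
    r <- tracescore:::corrected_rates(cnt, "loglinear")
    expect_equal(r[["hit"]], pnorm(d / 2 - cc), tolerance = 1e-10)
    expect_equal(r[["fa"]], pnorm(-d / 2 - cc), tolerance = 1e-10)
  }
})

test_that("pairwise consistency summarizes ordered pairs", {
  m <- rand_trace(32, density = 0.1, seed = 5)
  pc <- pairwise_consistency(list(m, m))
  expect_equal(pc$mean, 1)
  expect_equal(pc$sd, 0)
  expect_equal(pc$n_pairs, 2)
  expect_error(pairwise_consistency(list(m)), "at least 2")
})

test_that("consistency under independent omissions matches the closed form", {
  # maps are independent thinnings (keep prob 1-q) of one edge set;
  # with margin 0, E[p] over a pair is about (1-q)/(1+q)
  n <- 64; q <- 0.3
  E <- withr::with_seed(42, matrix(runif(n * n) < 0.1, n, n))
  maps <- lapply(1:10, function(i)
    withr::with_seed(100 + i,
                     trace_map(E & matrix(runif(n * n) > q, n, n))))
  pc <- pairwise_consistency(maps, scoring_config(margin_px = 0))
  expect_equal(pc$mean, (1 - q) / (1 + q), tolerance = 0.05)
})
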