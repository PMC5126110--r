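test_that("Hilbert envelope recovers constant and slowly varying amplitudes", {
  fs <- 250
  t <- seq_len(60 * fs) / fs
  x <- 2.5 * sin(2 * pi * 10 * t)
  env <- hilbert_envelope(x, fs)$values
  central <- round(0.05 * length(x)):round(0.95 * length(x))
  expect_lt(max(abs(env[central] - 2.5)) / 2.5, 0.01)
  expect_equal(hilbert_envelope(numeric(100) + 0, fs)$values, numeric(100))
  m <- 1 + 0.5 * sin(2 * pi * 0.1 * t)          # raised slow AM
  env2 <- hilbert_envelope(m * sin(2 * pi * 10 * t), fs)$values
  expect_lt(sqrt(mean((env2[central] - m[central])^2)) / mean(m), 0.02)
  expect_error(hilbert_envelope(numeric(0), fs), "empty")
})

test_that("the cumulative profile is exactly detrended", {
  prof <- build_profile(rep(3.7, 1000))
  expect_lt(max(abs(prof)), 1e-9)               # cumsum of a constant is linear
  set.seed(7)
  prof2 <- build_profile(stats::rexp(2000))
  expect_lt(abs(mean(prof2)), 1e-9)
  expect_lt(abs(stats::cov(prof2, seq_along(prof2))), 1e-6)
})

test_that("profile of a white envelope grows like a detrended random walk", {
  set.seed(8)
  v <- stats::rexp(4000)
  prof <- build_profile(v)
  walk <- cumsum(v - mean(v))
  walk <- stats::lm.fit(cbind(1, seq_along(walk)), walk)$residuals
  expect_equal(prof, walk, tolerance = 1e-10)
})

test_that("cubic detrending annihilates cubic profiles and segments correctly", {
  t <- seq_len(900)
  cubic <- 2 + 0.01 * t - 1e-5 * t^2 + 1e-8 * t^3
  fl <- fluctuation_at_scale(cubic, 900L)
  expect_lt(fl$fluctuation, 1e-8)
  fl2 <- fluctuation_at_scale(stats::rnorm(1000), 300L)
  expect_equal(fl2$n_segments, 3L)              # 100 trailing samples discarded
  expect_error(fluctuation_at_scale(stats::rnorm(100), 300L), "exceeds")
})

test_that("fast fluctuation equals the naive per-segment polynomial oracle", {
  set.seed(9)
  for (n in c(1200L, 5000L)) {
    prof <- build_profile(abs(stats::rnorm(n)) + 0.2)
    for (scale in c(37L, 100L, 333L)) {
      fast <- fluctuation_at_scale(prof, scale)$fluctuation
      slow <- brute_fluctuation(prof, scale)
      expect_equal(fast, slow, tolerance = 1e-10,
                   label = sprintf("n=%d scale=%d", n, scale))
    }
  }
})

test_that("fluctuations of an fGn profile follow the scaling law", {
  ratios <- sapply(1:12, function(s) {
    prof <- build_profile(generate_fgn(2e4, 0.75, seed = s) + 10)
    f1 <- fluctuation_at_scale(prof, 250L)$fluctuation
    f2 <- fluctuation_at_scale(prof, 500L)$fluctuation
    f2 / f1
  })
  expect_equal(mean(ratios), 2^0.75, tolerance = 0.07)
})

test_that("the scale grid reproduces the printed band minima and the 22.5 s maximum", {
  fs <- 250; n <- 45000
  g <- make_scale_grid(default_bands()$theta, fs, n)
  expect_equal(g$min_scale, 4)                  # 8 * 125 / 250
  expect_equal(g$max_scale, 22.5)               # 180 s / 8
  mins <- vapply(default_bands(), function(b) {
    make_scale_grid(b, fs, n)$min_scale
  }, 0)
  expect_equal(round(unname(mins), 2), c(4, 2.02, 1.22, 0.99, 0.74))
  # the printed sigma minimum is 1.24 s; the stated 8x rule gives
  # 8 * 38 / 250 = 1.216 s - a documented 0.02 s discrepancy
  expect_equal(mins[["sigma"]], 1.216)
  expect_equal(length(g$scales), 20L)
  ratios <- diff(log(g$exact))
  expect_lt(diff(range(ratios)), 1e-10)         # constant before rounding
  expect_error(make_scale_grid(default_bands()$theta, fs, 5000), "too short")
})

test_that("DFA slope matches the Hurst exponent of exact fGn", {
  g <- make_scale_grid(default_bands()$alpha, 250, 45000)
  for (H in c(0.55, 0.7, 0.9)) {
    fits <- lapply(1:10, function(s) {
      estimate_hurst(generate_fgn(45000, H, seed = 100 + s) + 10, g)
    })
    hbar <- mean(vapply(fits, `[[`, 0, "hurst"))
    expect_lt(abs(hbar - H), 0.05, label = sprintf("H = %.2f bias", H))
    expect_gt(min(vapply(fits, `[[`, 0, "fit_r2")), 0.95)
  }
})

test_that("degenerate (constant) envelopes raise an informative error", {
  g <- make_scale_grid(default_bands()$alpha, 250, 45000)
  expect_error(estimate_hurst(rep(1, 45000), g), "degenerate")
})

test_that("grand and band medians aggregate the H plane correctly", {
  h <- array(0.7, dim = c(2, 3, 2),
             dimnames = list(c("a", "b"), c("E1", "E2", "E3"), c("theta", "alpha")))
  hm <- h_matrix(h)
  expect_equal(unname(grand_median_h(hm)), c(0.7, 0.7))
  h2 <- h
  h2[1, , 1] <- c(0.6, 0.9, 0.7)                # worked 3-electrode example
  hm2 <- h_matrix(h2)
  expect_equal(band_median_h(hm2)[1, "theta"], 0.7)
  plane <- c(0.6, 0.7, 0.8, 0.9)                # 2x2 plane median
  h3 <- array(plane, dim = c(1, 2, 2), dimnames = list("a", c("E1", "E2"), c("t", "al")))
  expect_equal(unname(grand_median_h(h_matrix(h3))), 0.75)
  perm <- h2[, c(2, 3, 1), ]                    # bin permutation invariance
  dimnames(perm)[[2]] <- c("E1", "E2", "E3")
  expect_equal(grand_median_h(h_matrix(perm)), grand_median_h(hm2))
})

test_that("compute_h_matrix has the right shape and channel equivariance", {
  bands <- two_bands()
  mk <- function(seed, labels) {
    set.seed(seed)
    dat <- do.call(rbind, lapply(seq_along(labels), function(e) {
      rowSums(sapply(bands, function(b) {
        as.numeric(generate_band_oscillation(b, 60, 250, envelope_hurst = 0.7,
                                             seed = seed * 10 + e)$data)
      }))
    }))
    recording(dat, fs = 250, labels = labels, condition = "EO")
  }
  recs <- list(S1 = mk(1, c("A", "B", "C")), S2 = mk(2, c("A", "B", "C")))
  hm <- compute_h_matrix(recs, bands)
  expect_equal(dim(hm), c(2L, 3L, 2L))
  expect_true(all(is.finite(hm)))
  # permuting channels permutes the result identically
  recs_p <- lapply(recs, function(r) {
    recording(r$data[c(2, 3, 1), ], fs = r$fs, labels = r$labels[c(2, 3, 1)],
              condition = r$condition)
  })
  hm_p <- compute_h_matrix(recs_p, bands)
  expect_equal(unclass(hm_p)[, c("A", "B", "C"), ], unclass(hm)[, c("A", "B", "C"), ],
               tolerance = 1e-12)
})
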