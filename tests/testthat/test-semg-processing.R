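test_that("median centering zeroes the median and is idempotent", {
  expect_equal(center_median(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_median(c(5, 5, 9, 5)), c(0, 0, 4, 0))
  x <- c(-2, 0, 0, 1, 3)
  expect_equal(center_median(center_median(x)), center_median(x))
  expect_error(center_median(numeric(0)), "empty")
})

test_that("Hampel filter replaces outliers and nothing else", {
  expect_equal(hampel_filter(c(1, 1, 10, 1, 1), window = 5, n_sigma = 3),
               rep(1, 5))
  # constant signal: MAD = 0 but deviation is also 0, so nothing changes
  expect_equal(hampel_filter(rep(2, 20)), rep(2, 20))
  # clean oscillation passes through untouched
  x <- sin(seq(0, 4 * pi, length.out = 100))
  expect_equal(hampel_filter(x, window = 11, n_sigma = 3), x)
  # brute-force oracle on a noisy spike train: recompute the definition
  # (truncated edge windows, scaled MAD, strict exceedance) independently
  withr::with_seed(5, {
    y <- rnorm(60)
    y[c(10, 35)] <- c(25, -30)
  })
  filt <- hampel_filter(y, window = 7, n_sigma = 3)
  oracle <- y
  for (i in seq_along(y)) {
    w <- y[max(1, i - 3):min(60, i + 3)]
    med <- median(w)
    if (abs(y[i] - med) > 3 * 1.4826 * median(abs(w - med)))
      oracle[i] <- med
  }
  expect_equal(filt, oracle)
  expect_true(all(filt[c(10, 35)] != y[c(10, 35)]))
  expect_error(hampel_filter(y, window = 6), "odd")
})

test_that("rectification is an elementwise absolute value", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  x <- abs(rnorm(10))
  expect_identical(rectify(x), x)
  # |sin| doubles the fundamental frequency: spectrum peak moves from
  # bin f0 to bin 2*f0
  n <- 1024
  s <- sin(2 * pi * 8 * seq(0, 1, length.out = n + 1)[-1])
  spec_raw <- Mod(stats::fft(s))[2:60]
  spec_rect <- Mod(stats::fft(rectify(s) - mean(rectify(s))))[2:60]
  expect_equal(which.max(spec_raw), 8)
  expect_equal(which.max(spec_rect), 16)
})

test_that("Butterworth low-pass matches its analytic magnitude response", {
  fs <- 2250
  cfg <- processing_config(sample_rate = fs)
  tt <- seq(0, 2, by = 1 / fs)
  # DC gain 1
  expect_equal(butter_lowpass(rep(2.5, length(tt)), cfg),
               rep(2.5, length(tt)), tolerance = 1e-6)
  # 100 Hz tone: squared 2nd-order response at 100/3 -> far below 2%
  x100 <- sin(2 * pi * 100 * tt)
  y100 <- butter_lowpass(x100, cfg)
  mid <- seq(length(tt) %/% 4, 3 * length(tt) %/% 4)
  expect_lt(max(abs(y100[mid])), 0.02)
  # 0.1 Hz tone passes within 1%
  tt2 <- seq(0, 30, by = 1 / fs)
  x01 <- sin(2 * pi * 0.1 * tt2)
  y01 <- butter_lowpass(x01, processing_config(sample_rate = fs))
  mid2 <- seq(length(tt2) %/% 4, 3 * length(tt2) %/% 4)
  expect_equal(max(abs(y01[mid2])), 1, tolerance = 0.01)
  # attenuation is monotone in frequency
  att <- vapply(c(5, 20, 80), function(f) {
    y <- butter_lowpass(sin(2 * pi * f * tt), cfg)
    max(abs(y[mid]))
  }, numeric(1))
  expect_true(all(diff(att) < 0))
  expect_error(processing_config(sample_rate = 4, butter_cutoff = 3),
               "Nyquist")
})

test_that("MVC normalization uses the maximum across trials", {
  one <- mvc_normalize(c(0.5, 2, 1))
  expect_equal(one$mvc, 2)
  expect_equal(max(one$signals), 1)
  two <- mvc_normalize(list(c(1, 2), c(4, 0.5)))
  expect_equal(two$mvc, 4)
  expect_equal(two$signals[[1]], c(0.25, 0.5))
  expect_equal(max(unlist(two$signals)), 1)
  # idempotent
  again <- mvc_normalize(two$signals)
  expect_equal(again$signals, two$signals)
  expect_equal(again$mvc, 1)
  expect_error(mvc_normalize(rep(0, 5)), "positive maximum")
})

test_that("full processing chain recovers the underlying activation", {
  # synthesize a raw sEMG-like signal whose envelope is a known excitation:
  # amplitude-modulated zero-mean carrier noise
  model <- verification_model()
  fs <- 1000
  cfg <- processing_config(sample_rate = fs)
  tt <- seq(0, 5, by = 1 / fs)
  env <- 0.2 + 0.5 * pmax(0, sin(2 * pi * 0.5 * tt))^2
  withr::with_seed(21, carrier <- rnorm(length(tt)))
  raw <- env * carrier
  out <- process_semg(raw, cfg, model$biceps)
  expect_true(all(out$activation >= 0 & out$activation <= 1))
  # the recovered excitation tracks the true envelope up to the MVC scale;
  # the residual is the demodulation noise of smoothing |carrier| at 3 Hz
  ex <- out$excitation / max(out$excitation)
  truth <- env / max(env)
  mid <- seq(500, length(tt) - 500)
  expect_lt(sqrt(mean((ex[mid] - truth[mid])^2)), 0.1)
  expect_gt(stats::cor(ex[mid], truth[mid]), 0.98)
  # a perfectly constant raw signal has no AC content: after median
  # centering it is identically zero and the MVC is undefined
  expect_error(process_semg(rep(1, 1000), cfg, model$biceps),
               "MVC undefined")
})

test_that("chain stages are order-sensitive", {
  # rectify-then-filter differs from filter-then-rectify on a zero-mean
  # signal: the chain's order is part of its definition
  fs <- 200
  cfg <- processing_config(sample_rate = fs, butter_cutoff = 3)
  withr::with_seed(9, x <- rnorm(400) * sin(2 * pi * 5 * seq_len(400) / fs))
  a <- butter_lowpass(rectify(x), cfg)
  b <- rectify(butter_lowpass(x, cfg))
  expect_gt(mean(abs(a - b)), 0.01)
})

test_that("elbow angle from markers reports flexion from vertical arm", {
  # straight arm: shoulder above elbow, wrist below -> q = 0
  expect_equal(elbow_angle_from_markers(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1)),
               0, tolerance = 1e-12)
  # right angle at the elbow -> q = pi/2
  expect_equal(elbow_angle_from_markers(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)),
               pi / 2, tolerance = 1e-12)
  # fully folded -> q = pi
  expect_equal(elbow_angle_from_markers(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1)),
               pi, tolerance = 1e-12)
  # vectorized over frames
  sh <- rbind(c(0, 0, 1), c(0, 0, 1))
  el <- rbind(c(0, 0, 0), c(0, 0, 0))
  wr <- rbind(c(0, 0, -1), c(1, 0, 0))
  expect_equal(elbow_angle_from_markers(sh, el, wr), c(0, pi / 2),
               tolerance = 1e-12)
})
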