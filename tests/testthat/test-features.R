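# Sliding-window segmentation and the 43-dim feature vector.

test_that("segmentation emits full uniformly-labelled windows at the stride", {
  r <- makeRecording(600)
  w <- segmentWindows(r)
  expect_length(w, 3)                     # offsets 0, 150, 300
  expect_identical(w[[1]]$data, recordingSamples(r)[1:300, ])
  expect_identical(w[[3]]$data, recordingSamples(r)[301:600, ])

  expect_length(segmentWindows(makeRecording(300)), 1)
  expect_length(segmentWindows(makeRecording(299)), 0)

  # closed form for the count
  for (n in c(300, 450, 900, 1234)) {
    expect_length(segmentWindows(makeRecording(n)),
                  floor((n - 300) / 150) + 1)
  }
})

test_that("mixed-label windows are dropped", {
  samples <- matrix(rnorm(1800), ncol = 3)
  labels <- rep(c("W", "R"), each = 300)
  r <- AccelRecording("s1", samples, labels)
  w <- segmentWindows(r)
  # offsets 0 and 300 are pure; offset 150 straddles the bout boundary
  expect_length(w, 2)
  expect_identical(vapply(w, `[[`, "", "label"), c("W", "R"))
})

test_that("time features match order statistics and the SMA definition", {
  const <- matrix(2.5, 300, 3)
  f <- timeFeatures(const)
  expect_equal(unname(f[c("x_mean", "y_mean", "z_mean")]), rep(2.5, 3))
  expect_equal(unname(f[c("x_sd", "x_mad", "x_iqr")]), rep(0, 3))
  expect_equal(unname(f["sma"]), 7.5)

  ones <- matrix(1, 300, 3)
  expect_equal(unname(timeFeatures(ones)["sma"]), 3)

  # {1,2,3,4} tiled: brute-force order statistics
  v <- rep(1:4, length.out = 300)
  w <- cbind(v, v, v)
  f <- timeFeatures(w)
  expect_equal(unname(f["x_mad"]), median(abs(v - median(v))))
  expect_equal(unname(f["x_iqr"]),
               unname(quantile(v, 0.75) - quantile(v, 0.25)))
  expect_equal(unname(f["x_max"]), 4)
  expect_equal(unname(f["x_min"]), 1)
})

test_that("AR coefficients recover simulated processes", {
  expect_length(arCoefficients(makeWindow()), 9)

  # AR(1) with phi = 0.5, long series
  withr::with_seed(7, {
    x <- as.numeric(arima.sim(list(ar = 0.5), 1e4))
    w <- cbind(x, x, x)
  })
  cf <- arCoefficients(w)
  expect_lt(abs(cf[["x_ar1"]] - 0.5), 0.05)

  # white noise: coefficients are zero in expectation; at n = 300 each
  # estimate has sampling SD ~ 1/sqrt(n), so check the mean magnitude
  # across seeds plus a generous per-coefficient bound
  wnmag <- sapply(1:20, function(s) {
    withr::with_seed(s, wn <- matrix(rnorm(900), ncol = 3))
    cf <- arCoefficients(wn)
    expect_true(all(abs(cf) < 0.25))
    mean(abs(cf))
  })
  expect_lt(mean(wnmag), 0.1)

  # parameter recovery across seeds for a planted AR(3)
  phi <- c(0.4, -0.2, 0.1)
  err <- sapply(1:20, function(s) {
    withr::with_seed(s, x <- as.numeric(arima.sim(list(ar = phi), 5000)))
    max(abs(arCoefficients(cbind(x, x, x), order = 3)[1:3] - phi))
  })
  expect_lt(mean(err), 0.05)
})

test_that("zero-variance axis yields zero AR coefficients with a message", {
  w <- cbind(rep(1, 300), rnorm(300), rnorm(300))
  expect_message(cf <- arCoefficients(w), "zero-variance")
  expect_equal(unname(cf[1:3]), c(0, 0, 0))
})

test_that("spectral features behave at the degenerate and flat limits", {
  n <- 300
  t <- (0:(n - 1)) / n
  # pure sinusoid at an exact bin: all power in one bin -> entropy 0
  s <- sin(2 * pi * 10 * t)
  f <- frequencyFeatures(cbind(s, s, s))
  expect_lt(f[["x_fentropy"]], 1e-10)

  # white noise: entropy near log(#bins), within 10%
  withr::with_seed(3, wn <- matrix(rnorm(3 * n), ncol = 3))
  f <- frequencyFeatures(wn)
  expect_lt(abs(f[["x_fentropy"]] - log(n / 2)), 0.1 * log(n / 2))

  # Parseval: energy equals time-domain mean square of the detrended signal
  withr::with_seed(4, w <- matrix(rnorm(3 * n), ncol = 3))
  f <- frequencyFeatures(w)
  for (j in 1:3) {
    v <- w[, j] - mean(w[, j])
    expect_equal(unname(f[[paste0(c("x", "y", "z")[j], "_fenergy")]]),
                 mean(v^2), tolerance = 1e-12)
  }

  # zero signal is flagged and yields zeros
  z <- cbind(rep(0, n), rnorm(n), rnorm(n))
  expect_message(fz <- frequencyFeatures(z), "zero signal")
  expect_equal(unname(fz[1:5]), rep(0, 5))
})

test_that("spectral entropy is scale-invariant and the mean scales linearly", {
  w <- makeWindow(seed = 9)
  f1 <- windowFeatures(w)
  f2 <- windowFeatures(3 * w)
  expect_equal(f1[["x_fentropy"]], f2[["x_fentropy"]], tolerance = 1e-12)
  expect_equal(3 * f1[["x_mean"]], f2[["x_mean"]], tolerance = 1e-12)
})

test_that("extractFeatures stacks aligned 43-column rows in input order", {
  r1 <- makeRecording(600, label = "W", subject = "a", seed = 1)
  r2 <- makeRecording(300, label = "R", subject = "b", seed = 2)
  fe <- extractFeatures(list(r1, r2))
  expect_equal(dim(fe$features), c(4, 43))
  expect_identical(colnames(fe$features), featureNames())
  expect_identical(fe$labels, c("W", "W", "W", "R"))
  expect_identical(fe$subjects, c("a", "a", "a", "b"))
  expect_true(all(is.finite(fe$features)))

  # permutation-equivariant over recordings; deterministic
  fe2 <- extractFeatures(list(r2, r1))
  expect_identical(fe2$features[1, ], fe$features[4, ])
  expect_identical(extractFeatures(list(r1, r2)), fe)

  expect_error(extractFeatures(list(makeRecording(100))), "no usable windows")
})
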