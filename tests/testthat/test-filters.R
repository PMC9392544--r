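fs <- 500
tt <- seq(1 / fs, 10, by = 1 / fs)
mid <- function(x) x[(length(x) %/% 4):(3 * length(x) %/% 4)]
rms <- function(x) sqrt(mean(x^2))

test_that("the 50 Hz notch removes a pure 50 Hz tone almost completely", {
  x <- sin(2 * pi * 50 * tt)
  y <- apply_filter(x, filter_spec("notch", center_hz = 50), fs = fs)
  expect_lt(rms(mid(y)) / rms(mid(x)), 0.01)
})

test_that("the elliptic band-pass keeps 10 Hz within ripple and kills DC", {
  bp <- filter_spec("elliptic_bandpass", low_hz = 0.1, high_hz = 60)
  x10 <- sin(2 * pi * 10 * tt)
  y10 <- apply_filter(x10, bp, fs = fs)
  ratio <- rms(mid(y10)) / rms(mid(x10))
  # zero-phase application doubles the 1 dB design ripple
  expect_gt(ratio, 10^(-2.2 / 20))
  expect_lt(ratio, 1.02)

  ydc <- apply_filter(rep(1, 30000), bp, fs = fs)
  expect_lt(max(abs(mid(ydc))), 0.05)

  y80 <- apply_filter(sin(2 * pi * 80 * tt), bp, fs = fs)
  expect_lt(rms(mid(y80)) / rms(mid(sin(2 * pi * 80 * tt))), 0.01)
})

test_that("the Chebyshev type-II band-pass alternative behaves comparably", {
  bp <- filter_spec("chebyshev2_bandpass", low_hz = 0.1, high_hz = 60)
  x10 <- sin(2 * pi * 10 * tt)
  ratio <- rms(mid(apply_filter(x10, bp, fs = fs))) / rms(mid(x10))
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.02)
  y80 <- apply_filter(sin(2 * pi * 80 * tt), bp, fs = fs)
  expect_lt(rms(mid(y80)), 0.05)
})

test_that("filtering is linear and zero-phase", {
  set.seed(4)
  x <- rnorm(2000)
  y <- rnorm(2000)
  # well-conditioned design: linearity holds to near machine precision
  nt <- filter_spec("notch", center_hz = 50)
  lhs_n <- apply_filter(2.5 * x - 1.25 * y, nt, fs = fs)
  rhs_n <- 2.5 * apply_filter(x, nt, fs = fs) -
    1.25 * apply_filter(y, nt, fs = fs)
  expect_lt(max(abs(lhs_n - rhs_n)) / max(abs(lhs_n)), 1e-8)

  # the 0.1 Hz elliptic edge has poles ~1e-4 inside the unit circle, so
  # the IIR recursion amplifies roundoff; linearity holds to ~1e-4
  bp <- filter_spec("elliptic_bandpass", low_hz = 0.1, high_hz = 60)
  lhs <- apply_filter(2.5 * x - 1.25 * y, bp, fs = fs)
  rhs <- 2.5 * apply_filter(x, bp, fs = fs) -
    1.25 * apply_filter(y, bp, fs = fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-4)

  # zero-phase: cross-correlation of a band-limited tone peaks at lag 0
  x10 <- sin(2 * pi * 10 * tt)
  y10 <- apply_filter(x10, bp, fs = fs)
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    i <- 500:4500
    stats::cor(x10[i], y10[i + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("recordings filter channel-wise with shape preserved", {
  rec <- tiny_recording(seed = 5, duration = 2,
                        artifacts = artifact_spec(blink_rate = 0,
                                                  line_noise_amp = 10,
                                                  muscle_burst_rate = 0,
                                                  drift_amp = 0))
  out <- apply_filter(rec, filter_spec("notch", center_hz = 50))
  expect_equal(dim(out$data), dim(rec$data))
  before <- band_power(rec$data[10, ], 500, 49.5, 50.5)
  after <- band_power(out$data[10, ], 500, 49.5, 50.5)
  expect_lt(after, before / 100)
})

test_that("invalid designs are refused", {
  expect_error(design_filter(filter_spec("elliptic_bandpass", low_hz = 0.1,
                                         high_hz = 300), fs = 500),
               "Nyquist")
  expect_error(filter_spec("elliptic_bandpass", low_hz = 60, high_hz = 0.1),
               "low_hz < high_hz")
  expect_error(filter_spec("notch", order = 0), "order")
})
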