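test_that("trace extraction equals the brute-force ROI mean", {
  set.seed(21)
  arr <- array(runif(6 * 7 * 5), c(6, 7, 5))
  mov <- reentry_movie(arr, 100, 10)
  roi <- rbind(c(1L, 2L), c(3L, 4L), c(5L, 0L))          # 0-based (row, col)
  tr <- extract_trace(mov, roi)
  manual <- vapply(1:5, function(f) {
    mean(c(arr[2, 3, f], arr[4, 5, f], arr[6, 1, f]))
  }, 0)
  expect_equal(as.numeric(tr), manual)
  # single pixel and uniform frames
  one <- extract_trace(mov, rbind(c(0L, 0L)))
  expect_equal(as.numeric(one), arr[1, 1, ])
  flat <- reentry_movie(array(rep(1:5 / 10, each = 42), c(6, 7, 5)), 100, 10)
  expect_equal(as.numeric(extract_trace(flat, roi)), 1:5 / 10)
  expect_error(extract_trace(mov, matrix(numeric(0), 0, 2)), "empty roi")
  expect_error(extract_trace(mov, rbind(c(10L, 1L))), "outside")
})

test_that("normalization is idempotent and flags constant traces", {
  x <- rotormap:::new_trace(seq(0, 1, length.out = 50), 100)
  norm <- detrend_normalize(x)
  expect_equal(as.numeric(detrend_normalize(norm)), as.numeric(norm),
               tolerance = 1e-12)
  flat <- detrend_normalize(rotormap:::new_trace(rep(0.4, 50), 100))
  expect_true(attr(flat, "silent"))
  expect_equal(as.numeric(flat), rep(0, 50))
})

test_that("bleach correction restores event-peak heights", {
  tr0 <- kernel_train_trace(1, duration_s = 20)
  t_s <- (seq_along(tr0) - 1L) / 100
  bleached <- rotormap:::new_trace((0.2 + as.numeric(tr0)) * exp(-t_s / 8), 100)
  fixed <- detrend_normalize(bleached, bleach_correction = TRUE)
  ev <- detect_activations(fixed)
  peaks <- vapply(as.numeric(ev), function(t) {
    i <- round(t / 10) + 1L
    max(as.numeric(fixed)[i:min(length(fixed), i + 30L)])
  }, 0)
  expect_gt(length(peaks), 15)
  expect_lt(diff(range(peaks)) / max(peaks), 0.05)
})

test_that("steepest upstroke lands on the sigmoid midpoint and ramps break ties early", {
  t <- 0:100
  sig <- rotormap:::new_trace(1 / (1 + exp(-(t - 50) / 3)), 100)
  ev <- detect_activations(sig)
  expect_length(ev, 1L)
  expect_equal(as.numeric(ev), 500)          # frame 50 at 100 fps
  ramp <- rotormap:::new_trace(seq(0, 1, length.out = 80), 100)
  evr <- detect_activations(ramp, reentry_config(smooth_window = 1L))
  expect_length(evr, 1L)
  expect_equal(as.numeric(evr), 0)           # earliest frame of the run
})

test_that("detection recovers phantom ground truth and honours invariants", {
  ph <- small_rotor(seed = 13L, duration_s = 10, dim = c(64L, 64L))
  px <- c(16L, 48L)
  truth <- truth_events(ph$truth, px)
  tr <- extract_trace(ph$movie, matrix(px, 1))
  ev <- detect_activations(tr, cfg_rotor())
  expect_equal(length(ev), 29L)
  expect_equal(length(truth), 29L)
  expect_true(all(abs(as.numeric(ev) - truth) <= 20))   # within 2 frames
  # affine invariance
  aff <- rotormap:::new_trace(3.2 * as.numeric(tr) + 7, 100)
  plain <- rotormap:::new_trace(as.numeric(tr), 100)
  expect_equal(as.numeric(detect_activations(aff, cfg_rotor())),
               as.numeric(detect_activations(plain, cfg_rotor())))
  # event count on noise-free periodic traces is floor(T/P) +- 1
  for (f0 in c(1.5, 2.4, 3.3)) {
    n <- length(detect_activations(kernel_train_trace(f0), cfg_rotor()))
    expect_lte(abs(n - floor(10 * f0)), 1)
  }
  # strictly increasing with refractory-respecting gaps
  expect_true(all(diff(as.numeric(ev)) >= cfg_rotor()$refractory_ms))
})

test_that("dominant frequency meets the printed precision", {
  t_s <- (0:999) / 100
  pure <- rotormap:::new_trace(sin(2 * pi * 2.9 * t_s), 100)
  est <- dominant_frequency(pure)
  expect_lt(abs(est$frequency - 2.9), 0.1)
  expect_equal(est$resolution, 0.1)
  train <- kernel_train_trace(4)                     # 250 ms pulse train
  expect_lt(abs(dominant_frequency(train)$frequency - 4), 0.1)
  # noise-free error is within 1/duration across the band
  for (f0 in c(1.4, 2.2, 2.9)) {
    est <- dominant_frequency(kernel_train_trace(f0))
    expect_lt(abs(est$frequency - f0), est$resolution)
  }
  silent <- rotormap:::new_trace(rep(0.3, 1000), 100, silent = TRUE)
  expect_true(dominant_frequency(silent)$undefined)
  expect_error(dominant_frequency(pure, band = c(0.05, 10)), "too short")
})

test_that("channel lag is recovered for shifted copies over the search range", {
  tr <- kernel_train_trace(2.5, duration_s = 8)
  same <- estimate_channel_lag(tr, tr)
  expect_equal(same$lag, 0L)
  shift_by <- function(x, k) {
    n <- length(x)
    s <- if (k >= 0) c(rep(x[1], k), x[seq_len(n - k)]) else
      c(x[(-k + 1):n], rep(x[n], -k))
    rotormap:::new_trace(s, 100)
  }
  for (k in c(-20L, -7L, 3L, 20L)) {
    est <- estimate_channel_lag(tr, shift_by(as.numeric(tr), k))
    expect_equal(est$lag, k)
  }
  quiet <- rotormap:::new_trace(rep(0.2, length(tr)), 100)
  expect_true(estimate_channel_lag(tr, quiet)$undefined)
})
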