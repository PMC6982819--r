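test_that("detector finds crafted apex and heel-strike features", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  step <- 1.0                      # one "gait cycle" per second
  # slow wave: apex minima at t = 0.5, 1.5, 2.5 (negative there)
  ay <- -2.5 * cos(2 * pi * (t - 0.5) / step)
  # crest then sharp notch shortly after each apex: heel strikes at x.62
  for (c0 in c(0.62, 1.62, 2.62)) {
    ay <- ay + 3.0 * exp(-((t - (c0 - 0.07)) / 0.025)^2)   # local max at x.55
    ay <- ay - 6.0 * exp(-((t - c0) / 0.02)^2)             # HS notch
  }
  # horizontal braking trough at x.75
  ax <- sin(2 * pi * t / step)
  for (c0 in c(0.75, 1.75, 2.75)) ax <- ax - 3 * exp(-((t - c0) / 0.03)^2)
  trial <- list(t = t, ax = ax, ay = ay, fs = fs)

  ev <- detect_gait_events(trial)
  expect_gte(nrow(ev), 2L)
  # oracle: brute-force extrema scan of the constructed low-passed signals
  ay10 <- lowpass_filter(ay, fs, 10)
  apex_oracle <- t[brute_minima(ay10)[ay10[brute_minima(ay10)] < -1]]
  expect_lt(min(abs(ev$apex_t[1] - apex_oracle)), 0.03)
  expect_lt(abs(ev$apex_t[1] - 0.5), 0.03)
  expect_lt(abs(ev$hs_t[1] - 0.62), 0.03)
  expect_lt(abs(ev$to_t[1] - 0.75), 0.03)
  expect_true(all(ev$hs_i < ev$to_i))
})

test_that("heel strike is re-identified when it would follow toe off", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  ay <- -2.5 * cos(2 * pi * (t - 0.55) / 1)   # ay10 minimum near 0.55
  for (c0 in c(0.62, 1.62, 2.62)) {
    # genuine notch at c0 - 0.1 (= 0.52, before the late ay10 minimum) and a
    # spurious late candidate after the toe-off trough
    ay <- ay - 4.0 * exp(-((t - (c0 - 0.10)) / 0.02)^2)
    ay <- ay + 2.5 * exp(-((t - (c0 + 0.06)) / 0.03)^2)
    ay <- ay - 5.0 * exp(-((t - (c0 + 0.22)) / 0.02)^2)
  }
  ax <- sin(2 * pi * t / 1)
  for (c0 in c(0.75, 1.75, 2.75)) ax <- ax - 3 * exp(-((t - c0) / 0.03)^2)
  trial <- list(t = t, ax = ax, ay = ay, fs = fs)
  ev <- suppressWarnings(detect_gait_events(trial))
  expect_gte(nrow(ev), 1L)
  # the final HS must precede the TO of its cycle
  expect_true(all(ev$hs_t < ev$to_t))
})

test_that("segmentation pairs heel strikes with the right toe-offs", {
  tr <- tiny_trial()
  segs <- segment_trial(tr, tr$truth$events)
  expect_length(segs, nrow(tr$truth$events))
  Ts <- vapply(segs, `[[`, 0, "T")
  expect_true(all(Ts > 0.3 & Ts < 0.9))
  # segments cover [hs, to] exactly, no sample reuse inside a window
  s <- segs[[4]]
  expect_true(all(diff(s$t) > 0))
  expect_lte(s$t[1] - s$hs_t, 1 / tr$fs)
  expect_lte(s$to_t - s$t[length(s$t)], 1 / tr$fs)
  # constant-acceleration magnitude contract
  fake <- tr
  fake$ax <- rep(-1.3, length(tr$t)); fake$ay <- rep(0, length(tr$t))
  s2 <- segment_trial(fake, tr$truth$events)[[2]]
  expect_equal(s2$A, 1.3, tolerance = 1e-9)
  # stride-based gait frequency: inverse time between ipsilateral heel strikes
  hs <- sort(tr$truth$events$hs_t)
  expect_equal(segs[[1]]$f_gait, 1 / (hs[3] - hs[1]), tolerance = 1e-9)
})

test_that("drift-removed integration satisfies its closed forms", {
  fs <- 100
  n <- 101
  T <- (n - 1) / fs

  # constant bias integrates to identically zero velocity
  v <- integrate_drift_removed(rep(0.7, n), T, fs)
  expect_equal(v, rep(0, n), tolerance = 1e-12)

  # zero-net-impulse acceleration passes through unchanged
  a <- sin(2 * pi * seq(0, 1, length.out = n))    # integral 0 over the window
  v2 <- integrate_drift_removed(a, T, fs)
  t <- seq(0, T, by = 1 / fs)
  expect_equal(v2, cumtrapz(t, a), tolerance = 1e-9)

  # analytic oracle at 1 kHz: a = sin(2*pi*t/T) has v = T/(2*pi)*(1-cos(2*pi*t/T)),
  # whose net change is zero, so the ramp correction vanishes
  fs2 <- 1000; n2 <- fs2 + 1; T2 <- 1
  t2 <- seq(0, T2, length.out = n2)
  v3 <- integrate_drift_removed(sin(2 * pi * t2 / T2), T2, fs2)
  # trapezoid error bound for sin: ~ h^2 * 2*pi/6 = 1.05e-6 at h = 1e-3
  expect_lt(max(abs(v3 - T2 / (2 * pi) * (1 - cos(2 * pi * t2 / T2)))), 1.1e-6)

  # property: the endpoint equality holds to machine precision for any input
  set.seed(8)
  for (i in 1:25) {
    a <- rnorm(50 + i)
    v <- integrate_drift_removed(a, (length(a) - 1) / fs, fs)
    expect_lt(abs(v[length(v)] - v[1]), 1e-12 * max(1, max(abs(v))))
  }
  expect_error(integrate_drift_removed(a, 0, fs), "positive")
})

test_that("speed-offset regression recovers exact coefficients and scales", {
  set.seed(10)
  n <- 40
  A <- runif(n, 1, 3); f <- runif(n, 0.7, 1.1); h <- runif(n, 1.5, 1.9)
  a0 <- 0.04; b0 <- 0.3; c0 <- -0.05
  v <- (a0 * A + b0 * f + c0) * sqrt(h * 9.81)
  om <- fit_speed_offset_model(A, v, f = f, h = h)
  expect_equal(c(om$a, om$b, om$c), c(a0, b0, c0), tolerance = 1e-10)

  seg <- structure(list(A = 2, f_gait = 0.9, h = 1.7), class = "stance_segment")
  expect_equal(apply_speed_offset(om, seg),
               (a0 * 2 + b0 * 0.9 + c0) * sqrt(1.7 * 9.81), tolerance = 1e-10)

  # a = b = 0 model: pure height scaling, doubling h multiplies v0 by sqrt(2)
  om0 <- om; om0$a <- 0; om0$b <- 0
  seg2 <- seg; seg2$h <- 3.4
  expect_equal(apply_speed_offset(om0, seg2) / apply_speed_offset(om0, seg),
               sqrt(2), tolerance = 1e-12)

  # rank-deficient design
  expect_error(fit_speed_offset_model(rep(1, 5), v[1:5], f = rep(1, 5), h = h[1:5]),
               "rank-deficient")
  expect_error(fit_speed_offset_model(A[1:2], v[1:2], f = f[1:2], h = h[1:2]),
               "at least 3")

  # Monte-Carlo: coefficient RMSE shrinks roughly as 1/sqrt(n)
  rmse_at <- function(n, reps = 40) {
    errs <- replicate(reps, {
      A <- runif(n, 1, 3); f <- runif(n, 0.7, 1.1); h <- runif(n, 1.5, 1.9)
      v <- (a0 * A + b0 * f + c0) * sqrt(h * 9.81) + rnorm(n, 0, 0.1)
      om <- fit_speed_offset_model(A, v, f = f, h = h)
      sqrt(mean((c(om$a, om$b, om$c) - c(a0, b0, c0))^2))
    })
    mean(errs)
  }
  set.seed(12)
  r30 <- rmse_at(30); r120 <- rmse_at(120); r480 <- rmse_at(480)
  expect_lt(r120 / r30, 0.75)       # ~ 1/2 expected
  expect_lt(r480 / r120, 0.75)
})

test_that("feature assembly meets the resampling and reset contracts", {
  tr <- tiny_trial()
  segs <- segment_trial(tr, tr$truth$events)
  s <- segs[[5]]
  fb <- assemble_features(s, leg_length = tr$params$l0, v0 = 1.2,
                          labels = tr$truth$stances[[5]])
  expect_equal(dim(fb), c(7L, 200L))
  expect_identical(rownames(fb), c("t", "x", "y", "vx", "vy", "ax", "ay"))
  expect_equal(fb["t", ], seq(0, 1, length.out = 200))
  expect_equal(unname(fb["x", 1]), 0)                # HS reset
  expect_equal(unname(fb["y", 1]), tr$params$l0)     # leg-length offset
  lab <- attr(fb, "labels")
  expect_equal(dim(lab), c(11L, 200L))

  # min-max normalization against frozen extrema; degenerate channel -> 0.5
  st <- compute_norm_stats(list(fb))
  nb <- apply_norm(fb, st)
  expect_true(all(nb >= -1e-12 & nb <= 1 + 1e-12))
  expect_equal(invert_norm(nb, st), unclass(fb), tolerance = 1e-12,
               ignore_attr = TRUE)
  degen <- fb; degen["ay", ] <- 5
  st2 <- compute_norm_stats(list(degen))
  expect_warning(nd <- apply_norm(degen, st2), "degenerate")
  expect_true(all(nd["ay", ] == 0.5))
})
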