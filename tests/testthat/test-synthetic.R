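test_that("trial generation is deterministic and keeps its promises", {
  p <- default_params()
  tr1 <- generate_walking_trial(p, 1.25, 10, seed = 123)
  tr2 <- generate_walking_trial(p, 1.25, 10, seed = 123)
  expect_identical(tr1, tr2)
  tr3 <- generate_walking_trial(p, 1.25, 10, seed = 124)
  expect_false(identical(tr1$ay, tr3$ay))

  # exactly n_steps (hs, to) pairs, strictly ordered within each row
  ev <- tr1$truth$events
  expect_equal(nrow(ev), 10L)
  expect_true(all(ev$apex_t < ev$hs_t))
  expect_true(all(ev$hs_t < ev$to_t))
  expect_equal(length(tr1$truth$stances), 10L)
  expect_true(all(vapply(tr1$truth$stances, ncol, 0L) == 12L))

  # mean forward speed of the noise-free CoM within 2% of the request
  com <- tr1$truth$com
  v_meas <- (com$x[nrow(com)] - com$x[1]) / (com$t[nrow(com)] - com$t[1])
  expect_lt(abs(v_meas / 1.25 - 1), 0.02)

  expect_error(generate_walking_trial(p, 1.25, 1, seed = 1), "at least 2")
})

test_that("IMU corruption is additive, seeded, and exactly reversible at zero", {
  tr <- tiny_trial()
  zero <- noise_model(accel_noise_sd = 0, bias = 0, bias_drift_rate = 0, seed = 9)
  same <- corrupt_to_imu(tr, zero)
  expect_equal(same$ax, tr$ax)
  expect_equal(same$ay, tr$ay)
  expect_identical(same$truth, tr$truth)

  # pure constant bias b: integrated velocity error grows exactly as b*t
  b <- 0.2
  biased <- corrupt_to_imu(tr, noise_model(0, bias = b, 0, seed = 9))
  dv <- cumtrapz(tr$t, biased$ay) - cumtrapz(tr$t, tr$ay)
  expect_equal(dv, b * (tr$t - tr$t[1]), tolerance = 1e-10)

  n1 <- corrupt_to_imu(tr, noise_model(seed = 5))
  n2 <- corrupt_to_imu(tr, noise_model(seed = 5))
  n3 <- corrupt_to_imu(tr, noise_model(seed = 6))
  expect_identical(n1$ax, n2$ax)
  expect_false(identical(n1$ax, n3$ax))

  expect_error(noise_model(accel_noise_sd = -1), "non-negative")
})

test_that("trial artifacts round-trip as plain text", {
  tr <- tiny_trial()
  d <- file.path(tempdir(), "trial_io")
  write_imu_trial(tr, d)
  back <- read_imu_trial(d)
  expect_equal(back$ay, tr$ay, tolerance = 1e-9)
  expect_equal(back$t, tr$t, tolerance = 1e-9)
  expect_equal(back$truth$events$hs_t, tr$truth$events$hs_t, tolerance = 1e-9)
  expect_equal(back$truth$stances[[3]]$T_knee, tr$truth$stances[[3]]$T_knee,
               tolerance = 1e-6)
  expect_equal(back$params$k, tr$params$k, tolerance = 1e-6)

  # a one-minute trial at 100 Hz has exactly 6000 rows
  fake <- tr
  fake$t <- seq(0, by = 0.01, length.out = 6000)
  fake$ax <- sin(fake$t); fake$ay <- cos(fake$t)
  fake$truth <- NULL
  d2 <- file.path(tempdir(), "trial_io2")
  write_imu_trial(fake, d2)
  expect_equal(nrow(read.csv(file.path(d2, "trial.csv"))), 6000L)

  # malformed inputs are named
  tc <- read.csv(file.path(d2, "trial.csv"))
  write.csv(tc[, c("t", "ax")], file.path(d2, "trial.csv"), row.names = FALSE)
  expect_error(read_imu_trial(d2), "missing column 'ay'")
  tc$ay <- tc$ax
  tc$t[100] <- tc$t[100] + 0.004
  write.csv(tc, file.path(d2, "trial.csv"), row.names = FALSE)
  expect_error(read_imu_trial(d2), "non-uniform timestamps")
})

test_that("generated signals carry the event signatures the detector needs", {
  tr <- tiny_trial()
  ev <- detect_gait_events(tr)
  tru <- tr$truth$events
  expect_gte(nrow(ev), nrow(tru) - 1)
  near <- function(det, ref) vapply(ref, function(x) min(abs(det - x)), 0)
  # apex: a vertical-acceleration minimum near each true apex
  expect_lte(median(near(ev$apex_t, tru$apex_t)), 0.05)
  # HS / TO located within the working tolerances on a clean trial
  expect_lte(mean(near(ev$hs_t, tru$hs_t)), 0.03)
  expect_lte(mean(near(ev$to_t, tru$to_t)), 0.025)
})

test_that("cohort generator reproduces the study layout", {
  coh <- generate_cohort(n_subjects = 2, steps_per_trial = 4, seed = 3)
  expect_length(coh, 6L)
  expect_setequal(unique(vapply(coh, `[[`, "", "speed_label")),
                  c("slow", "moderate", "fast"))
  sp <- cohort_speeds()
  expect_equal(dim(sp), c(3L, 7L))
  expect_equal(coh[["S2_fast"]]$speed, sp["fast", "S2"])
  # subjects differ in anthropometry and mechanics
  expect_gt(sd(vapply(coh, function(tr) tr$params$k, 0)), 0)
  expect_error(generate_cohort(n_subjects = 9), "more subjects")
})
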