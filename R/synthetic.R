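#' Sensor noise model for synthetic IMU trials
#'
#' White accelerometer noise plus a constant bias and a linearly growing bias
#' (the drift that the drift-removed integration must cancel).  Defaults are
#' chosen for a consumer MEMS accelerometer worn over clothing: noise well
#' above the quantization floor of a 0.001 g device, plus a slow thermal-like
#' bias ramp.
#'
#' @param accel_noise_sd white noise standard deviation (m/s^2).
#' @param bias constant bias (m/s^2), applied to both axes.
#' @param bias_drift_rate linear bias growth rate (m/s^3).
#' @param seed integer seed making the corruption reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(accel_noise_sd = 0.15, bias = 0.05,
                        bias_drift_rate = 0.01, seed = 1L) {
  if (accel_noise_sd < 0 || bias_drift_rate < 0)
    stop("noise_model: noise magnitudes must be non-negative", call. = FALSE)
  structure(list(accel_noise_sd = accel_noise_sd, bias = bias,
                 bias_drift_rate = bias_drift_rate, seed = as.integer(seed)),
            class = "noise_model")
}

# Damped counterpart of slip_forces used by the label generator (matches the
# C++ force law of the walking simulator).
leg_force_damped <- function(x, y, vx, vy, refs, params, damping,
                             push_off = 0, theta0 = NULL) {
  q <- leg_inverse_geometry(x, y, refs, params, theta0 = theta0)
  ls <- q[["ls"]]; th <- q[["theta"]]
  st <- sin(th); ct <- cos(th)
  F <- params$k * (params$l0 - (ls + params$R))
  A <- params$R + params$d * st + ls * ct
  B <- params$d * ct - ls * st
  det <- st * B - A * ct
  dls <- (B * vx - A * vy) / det
  dth <- (-ct * vx + st * vy) / det
  if (damping > 0) F <- F - damping * dls
  if (push_off > 0 && th > 0) F <- F + push_off * exp(-((th - 0.25) / 0.10)^2)
  if (F < 0) F <- 0
  fa <- -F * (params$d + params$R * st) / (ls + params$R * ct)
  gx <- F * st + fa * ct
  gy <- F * ct - fa * st
  list(fx = gx, fy = gy,
       Ta = params$d * ct * gy + (params$R + params$d * st) * gx,
       ls = ls, theta = th, dls = dls, dtheta = dth,
       contact = refs$c_hs + params$R * (th - refs$theta_hs))
}

ankle_of <- function(refs, params, theta) {
  px <- refs$c_hs + params$R * (theta - refs$theta_hs)
  c(px - params$d * cos(theta), params$R + params$d * sin(theta))
}

ankle_vel_of <- function(params, theta, dtheta) {
  c((params$R + params$d * sin(theta)) * dtheta,
    params$d * cos(theta) * dtheta)
}

#' Generate a synthetic sacrum-IMU walking trial with ground truth
#'
#' Runs the stitched compliant-walking simulation (alternating stances with
#' finite double support, leg damping absorbing the touchdown impact, and a
#' weak per-step treadmill speed regulator), samples the sacrum acceleration
#' at `fs`, and derives the full ground truth: per-step apex / heel-strike /
#' toe-off times and the eleven label channels (two GRFs, three stance-leg
#' joint torques from planar inverse dynamics, and the stance- and swing-leg
#' foot/shank/thigh angles).  A short damped 30 Hz oscillation
#' (positive-first) is added to the vertical channel at each touchdown,
#' emulating the heel-strike impact transient that a sacrum-mounted
#' accelerometer records and that heel-strike detection keys on; both
#' channels then pass a causal second-order anti-alias filter, the sensor
#' front end.  The CoM dynamics themselves are smooth.
#'
#' Swing-leg angles come from the contralateral stitched step: during the
#' neighbouring stances the contralateral leg's true geometry is used, and
#' across its swing the ankle path is interpolated (Hermite in position and
#' velocity, with a small mid-swing clearance and knee-flexion shortening).
#'
#' @param params a [slip_params()] object.
#' @param speed target mean forward speed (m/s).
#' @param n_steps number of recorded stance phases.
#' @param seed integer seed (drives the step-to-step touchdown-angle
#'   variability; the trial is reproducible given the seed).
#' @param fs output sampling rate (Hz).
#' @param damping leg damping of the walking generator (N*s/m).
#' @param push_off peak late-stance axial thrust (N), the ankle-powered
#'   push-off that produces the pre-touchdown acceleration crest; applied as
#'   a Gaussian bump in the leg angle centred at 0.25 rad.
#' @param theta_td mean touchdown leg angle (rad); default follows the
#'   speed-dependent policy `-0.32 - 0.03*(speed - 1)`.
#' @param theta_td_sd per-step touchdown-angle jitter (rad).
#' @param subject_id,speed_label metadata tokens carried in the trial.
#' @param dt integration step of the generator (s).
#' @return An object of class `imu_trial`: `t`, `ax`, `ay` at `fs`, plus
#'   `truth` (events data frame with `step, apex_t, hs_t, to_t`; `stances`, a
#'   list of per-stance label frames; `com`, the noise-free CoM kinematics on
#'   the trial clock; `speed_true`), and metadata.
#' @export
generate_walking_trial <- function(params, speed, n_steps, seed,
                                   fs = 100, damping = 700,
                                   push_off = 0,
                                   theta_td = -0.32 - 0.03 * (speed - 1),
                                   theta_td_sd = 0.01,
                                   subject_id = "S1", speed_label = "moderate",
                                   dt = 1e-3) {
  stopifnot(inherits(params, "slip_params"))
  if (n_steps < 2) stop("generate_walking_trial: n_steps must be at least 2", call. = FALSE)
  warmup <- 6L
  total <- n_steps + warmup + 2L
  set.seed(as.integer(seed))
  jit <- rnorm(total + 5L, 0, theta_td_sd)
  par <- c(m = params$m, g = params$g, k = params$k, l0 = params$l0,
           R = params$R, d = params$d, c = damping, fpo = push_off)
  rec_every <- max(1L, round(1 / (2 * fs) / dt))   # record at 2*fs (200 Hz default)
  # a subject whose jittered mechanics cannot *walk* at the policy angle
  # adapts the touchdown: steeper if the gait is unstable, shallower if the
  # feet leave the ground (running; walking requires double support)
  mean_ds <- function(w) {
    n <- min(length(w$lo_t), length(w$td_t) - 1L)
    if (n < warmup + 2L) return(-Inf)
    mean(w$lo_t[(warmup + 1L):n] - w$td_t[(warmup + 2L):(n + 1L)])
  }
  best <- NULL
  for (scl in c(1, 0.92, 0.85, 0.78, 1.1, 1.2, 1.35, 1.5)) {
    ttd_seq <- scl * theta_td + jit
    w <- cpp_simulate_walk(par, speed, ttd_seq, total, dt, rec_every, 0.5, 0L)
    if (nzchar(w$error)) next
    if (is.null(best) || mean_ds(w) > mean_ds(best)) best <- w
    if (mean_ds(w) >= 0.005) break
  }
  if (is.null(best))
    stop(sprintf("generate_walking_trial: unstable gait (%s) at step %d",
                 w$error, w$step_at_error), call. = FALSE)
  w <- best

  keep <- seq(warmup + 1L, warmup + n_steps)      # kept stance indices
  td <- w$td_t; lo <- w$lo_t
  refs_list <- lapply(seq_along(td), function(i)
    touchdown_refs(w$td_theta_hs[i], params$R + params$d * sin(w$td_theta_hs[i]) +
                     (params$l0 - params$R) * cos(w$td_theta_hs[i]),
                   w$td_c_hs[i], params))
  sm <- w$samples
  t2 <- sm[, "t"]

  # trial window with margins; re-zeroed clock, sampled at fs from the 2*fs grid
  t_start <- max(0, td[keep[1]] - 0.30)
  t_end <- min(t2[length(t2)], lo[keep[n_steps]] + 0.30)
  # snap the start to the 2*fs grid so the fs clock aligns with simulator samples
  i_start <- which(t2 >= t_start - 1e-9)[1]
  if (i_start %% 2L == 0L) i_start <- i_start + 1L
  idx2 <- seq(i_start, max(which(t2 <= t_end + 1e-9)))
  t2w <- t2[idx2]

  ax2 <- sm[idx2, "ax"]
  ay2 <- sm[idx2, "ay"]
  # heel-strike impact transient on the vertical channel: a damped 30 Hz
  # ringing, positive-first (the impact arrests the falling soft tissue, then
  # rebounds).  Written as the exact derivative of a decaying oscillation so
  # it carries zero net impulse: ringing must not change the mean velocity.
  omg <- 2 * pi * 30; tau <- 0.03
  for (tdi in td[td > t2w[1] - 0.2 & td < t2w[length(t2w)]]) {
    rel <- t2w - tdi
    j <- rel >= 0 & rel <= 0.12
    ay2[j] <- ay2[j] + (8 / omg) * exp(-rel[j] / tau) *
      (omg * cos(omg * rel[j]) - sin(omg * rel[j]) / tau)
  }

  # causal anti-alias band-limiting before decimation (the sensor front end;
  # causal so the impact transient rings only after contact)
  ax2 <- lowpass_causal(ax2, 2 * fs, 0.45 * fs, order = 2L)
  ay2 <- lowpass_causal(ay2, 2 * fs, 0.45 * fs, order = 2L)

  idx1 <- seq(1L, length(idx2), by = 2L)           # the fs-rate subsample
  t0 <- t2w[1]
  t_out <- t2w[idx1] - t0

  # ---- ground-truth events -------------------------------------------------
  apex_of_stance <- function(i) {
    j <- which(t2 >= td[i] & t2 <= lo[i])
    t2[j[which.max(sm[j, "y"])]]
  }
  ev <- data.frame(step = seq_len(n_steps),
                   apex_t = vapply(keep - 1L, apex_of_stance, 0) - t0,
                   hs_t = td[keep] - t0,
                   to_t = lo[keep] - t0)

  # ---- per-stance label channels ------------------------------------------
  interp_state <- function(tt) {
    # linear interpolation of the recorded CoM state at arbitrary times
    sapply(c("x", "y", "vx", "vy"), function(cn) approx(t2, sm[, cn], xout = tt)$y)
  }

  contral_ankle <- function(i, tt) {
    # ankle track of the contralateral leg (stances i-1 / i+1) at times tt
    lo_prev <- lo[i - 1L]; td_next <- td[i + 1L]
    out <- matrix(NA_real_, length(tt), 2)
    th3 <- numeric(length(tt))
    pre <- tt <= lo_prev; post <- tt >= td_next; mid <- !pre & !post
    for (j in which(pre)) {
      s <- interp_state(tt[j])
      f <- leg_force_damped(s[1], s[2], s[3], s[4], refs_list[[i - 1L]], params, 0)
      out[j, ] <- ankle_of(refs_list[[i - 1L]], params, f$theta); th3[j] <- f$theta
    }
    for (j in which(post)) {
      s <- interp_state(tt[j])
      f <- leg_force_damped(s[1], s[2], s[3], s[4], refs_list[[i + 1L]], params, 0)
      out[j, ] <- ankle_of(refs_list[[i + 1L]], params, f$theta); th3[j] <- f$theta
    }
    if (any(mid)) {
      s0 <- interp_state(lo_prev); s1 <- interp_state(td_next)
      f0 <- leg_force_damped(s0[1], s0[2], s0[3], s0[4], refs_list[[i - 1L]], params, 0)
      f1 <- leg_force_damped(s1[1], s1[2], s1[3], s1[4], refs_list[[i + 1L]], params, 0)
      a0 <- ankle_of(refs_list[[i - 1L]], params, f0$theta)
      a1 <- ankle_of(refs_list[[i + 1L]], params, f1$theta)
      v0 <- ankle_vel_of(params, f0$theta, f0$dtheta)
      v1 <- ankle_vel_of(params, f1$theta, f1$dtheta)
      Tsw <- td_next - lo_prev
      s <- (tt[mid] - lo_prev) / Tsw
      h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
      h01 <- -2 * s^3 + 3 * s^2;    h11 <- s^3 - s^2
      out[mid, 1] <- h00 * a0[1] + h10 * Tsw * v0[1] + h01 * a1[1] + h11 * Tsw * v1[1]
      out[mid, 2] <- h00 * a0[2] + h10 * Tsw * v0[2] + h01 * a1[2] + h11 * Tsw * v1[2] +
        0.02 * sin(pi * s)                       # toe clearance
      th3[mid] <- f0$theta + (f1$theta - f0$theta) * (3 * s^2 - 2 * s^3)
      attr(out, "swing_s") <- list(which = which(mid), s = s)
    }
    list(ankle = out, th3 = th3)
  }

  anthro <- anthropometrics(params$m)
  lens <- c(l1 = params$l1, l2 = params$l2, l3 = params$l3)
  stances <- vector("list", n_steps)
  for (kidx in seq_len(n_steps)) {
    i <- keep[kidx]
    # compute on a slightly extended window so the double differentiation in
    # the inverse dynamics sees no one-sided edge; trim afterwards
    jj <- which(t_out + t0 >= td[i] - 0.06 & t_out + t0 <= lo[i] + 0.06)
    tt <- t_out[jj] + t0
    st <- t(sapply(tt, interp_state))
    fr <- lapply(seq_along(tt), function(j)
      leg_force_damped(st[j, 1], st[j, 2], st[j, 3], st[j, 4],
                       refs_list[[i]], params, damping, push_off))
    grf <- cbind(fx = vapply(fr, `[[`, 0, "fx"), fy = vapply(fr, `[[`, 0, "fy"))
    cop <- vapply(fr, `[[`, 0, "contact")
    th_leg <- vapply(fr, `[[`, 0, "theta")
    # stance-leg segment angles by exact inverse kinematics
    ang_st <- t(vapply(seq_along(tt), function(j) {
      a <- ankle_of(refs_list[[i]], params, th_leg[j])
      com <- c(st[j, 1], st[j, 2])
      dv <- com - a; D <- sqrt(sum(dv^2))
      Dmax <- 0.985 * (params$l1 + params$l2)
      if (D > Dmax) a <- com - dv * (Dmax / D)   # only beyond the trimmed edges
      as.numeric(inverse_kinematics_multibody(com, a, params))
    }, numeric(3)))
    # contralateral (swing) leg angles
    ca <- contral_ankle(i, tt)
    ang_sw <- t(vapply(seq_along(tt), function(j) {
      com <- c(st[j, 1], st[j, 2]); an <- ca$ankle[j, ]
      dv <- com - an; D <- sqrt(sum(dv^2))
      Dmax <- 0.985 * (params$l1 + params$l2)
      if (D > Dmax) an <- com - dv * (Dmax / D)
      as.numeric(inverse_kinematics_multibody(com, an, params, "swing"))
    }, numeric(3)))
    torq <- planar_inverse_dynamics(ang_st[, c(1, 2, 3)], lens, anthro, grf, cop,
                                    fs, params = params, g = params$g)
    inwin <- tt >= td[i] - 1e-9 & tt <= lo[i] + 1e-9
    stances[[kidx]] <- data.frame(
      t = tt - t0,
      grf_x = grf[, "fx"], grf_y = grf[, "fy"],
      T_ank = torq$T_ank, T_knee = torq$T_knee, T_hip = torq$T_hip,
      th_foot_st = ang_st[, 3], th_shank_st = ang_st[, 2], th_thigh_st = ang_st[, 1],
      th_foot_sw = ang_sw[, 3], th_shank_sw = ang_sw[, 2],
      th_thigh_sw = ang_sw[, 1])[inwin, , drop = FALSE]
  }

  sp_true <- (sm[idx2[length(idx2)], "x"] - sm[idx2[1], "x"]) / (t2w[length(t2w)] - t2w[1])
  com <- data.frame(t = t_out,
                    x = sm[idx2[idx1], "x"], y = sm[idx2[idx1], "y"],
                    vx = sm[idx2[idx1], "vx"], vy = sm[idx2[idx1], "vy"])
  structure(list(
    subject_id = subject_id, speed_label = speed_label, speed = speed,
    fs = fs, t = t_out, ax = ax2[idx1], ay = ay2[idx1],
    truth = list(events = ev, stances = stances, com = com, speed_true = sp_true),
    params = params, seed = as.integer(seed),
    meta = list(damping = damping, push_off = push_off, theta_td = theta_td,
                theta_td_sd = theta_td_sd, n_steps = n_steps)
  ), class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %s %s: %.1f s at %g Hz, %d truth stances%s\n",
              x$subject_id, x$speed_label, diff(range(x$t)), x$fs,
              if (is.null(x$truth)) 0L else nrow(x$truth$events),
              if (is.null(x$noise)) " (noise-free)" else " (corrupted)"))
  invisible(x)
}

#' Corrupt a clean trial with accelerometer noise and drift
#'
#' Adds seeded white noise, a constant bias and a linearly growing bias to
#' both acceleration channels; the ground truth is left untouched.  A
#' zero-magnitude model returns the trial unchanged.
#'
#' @param trial an `imu_trial`.
#' @param noise a [noise_model()].
#' @return The corrupted `imu_trial` (with the `noise` model attached).
#' @export
corrupt_to_imu <- function(trial, noise) {
  stopifnot(inherits(trial, "imu_trial"), inherits(noise, "noise_model"))
  n <- length(trial$t)
  set.seed(noise$seed)
  drift <- noise$bias + noise$bias_drift_rate * trial$t
  trial$ax <- trial$ax + drift + rnorm(n, 0, noise$accel_noise_sd)
  trial$ay <- trial$ay + drift + rnorm(n, 0, noise$accel_noise_sd)
  trial$noise <- noise
  trial
}

#' Write / read a synthetic trial as plain-text artifacts
#'
#' Writes `trial.csv` (`t,ax,ay`), `events.csv` (`step,apex_t,hs_t,to_t`),
#' `labels_NNN.csv` (one per truth stance, `t` plus the 11 channels) and
#' `manifest.json` (subject, speed, seed, model parameters) under `dir`.
#' Reading restores an `imu_trial` losslessly to the printed precision.
#'
#' @param trial an `imu_trial`.
#' @param dir directory to hold the artifact files.
#' @return `write_imu_trial()` returns `dir` invisibly; `read_imu_trial()`
#'   the restored `imu_trial`.
#' @export
write_imu_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "imu_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) { df[] <- lapply(df, function(c) signif(c, 12)); df }
  write.csv(fmt(data.frame(t = trial$t, ax = trial$ax, ay = trial$ay)),
            file.path(dir, "trial.csv"), row.names = FALSE)
  if (!is.null(trial$truth)) {
    write.csv(fmt(trial$truth$events), file.path(dir, "events.csv"), row.names = FALSE)
    for (i in seq_along(trial$truth$stances))
      write.csv(fmt(trial$truth$stances[[i]]),
                file.path(dir, sprintf("labels_%03d.csv", i)), row.names = FALSE)
    all_lab <- do.call(rbind, lapply(seq_along(trial$truth$stances), function(i)
      cbind(step = i, trial$truth$stances[[i]])))
    write.csv(fmt(all_lab), file.path(dir, "labels.csv"), row.names = FALSE)
  }
  man <- list(subject_id = trial$subject_id, speed_label = trial$speed_label,
              speed = trial$speed, fs = trial$fs, seed = trial$seed,
              meta = trial$meta,
              params = unclass(trial$params)[c("m", "h", "g", "l0", "k", "R", "d",
                                               "k_a", "l1", "l2", "l3")],
              speed_true = trial$truth$speed_true)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_imu_trial
#' @export
read_imu_trial <- function(dir) {
  tc <- file.path(dir, "trial.csv")
  if (!file.exists(tc)) stop("read_imu_trial: no trial.csv in ", dir, call. = FALSE)
  df <- read.csv(tc)
  for (cn in c("t", "ax", "ay"))
    if (!cn %in% names(df))
      stop("read_imu_trial: missing column '", cn, "' in trial.csv", call. = FALSE)
  dtv <- diff(df$t)
  if (any(abs(dtv - stats::median(dtv)) > 1e-6))
    stop("read_imu_trial: non-uniform timestamps near row ",
         which.max(abs(dtv - stats::median(dtv))), call. = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  params <- do.call(slip_params, as.list(man$params))
  truth <- NULL
  evf <- file.path(dir, "events.csv")
  if (file.exists(evf)) {
    ev <- read.csv(evf)
    lab_files <- sort(list.files(dir, "^labels_\\d+\\.csv$", full.names = TRUE))
    truth <- list(events = ev, stances = lapply(lab_files, read.csv),
                  speed_true = man$speed_true)
  }
  structure(list(subject_id = man$subject_id, speed_label = man$speed_label,
                 speed = man$speed, fs = man$fs,
                 t = df$t, ax = df$ax, ay = df$ay,
                 truth = truth, params = params, seed = man$seed,
                 meta = man$meta),
            class = "imu_trial")
}

#' Treadmill speeds of the seven-subject reference cohort
#'
#' The slow / moderate / fast treadmill speeds (m/s) used as per-subject
#' defaults by [generate_cohort()].
#'
#' @return A 3 x 7 matrix (rows `slow`, `moderate`, `fast`).
#' @export
cohort_speeds <- function() {
  matrix(c(1.07, 1.71, 1.38, 1.22, 1.29, 1.00, 1.20,
           1.21, 1.87, 1.49, 1.37, 1.51, 1.14, 1.36,
           1.54, 2.26, 1.78, 1.76, 2.07, 1.49, 1.76),
         3, 7, byrow = TRUE,
         dimnames = list(c("slow", "moderate", "fast"), paste0("S", 1:7)))
}

#' Generate the synthetic walking cohort
#'
#' Builds one trial per subject and speed condition.  Subjects differ in
#' height and mass (drawn from the cohort statistics, mean 1.69 m / 72 kg)
#' and carry a multiplicative +/-10 percent jitter on rest leg length and
#' spring stiffness; their three treadmill speeds default to the reference
#' cohort table ([cohort_speeds()]).
#'
#' @param n_subjects number of subjects (up to 7 with the default speeds).
#' @param steps_per_trial stance phases recorded per trial.
#' @param seed master seed; every subject/trial seed derives from it.
#' @param speeds optional speed matrix like [cohort_speeds()].
#' @param noise optional [noise_model()] applied to every trial.
#' @return A list of `imu_trial` objects with class `imu_cohort`.
#' @export
generate_cohort <- function(n_subjects = 7, steps_per_trial = 30, seed = 1L,
                            speeds = NULL, noise = NULL) {
  if (is.null(speeds)) speeds <- cohort_speeds()
  if (n_subjects > ncol(speeds))
    stop("generate_cohort: more subjects than speed columns", call. = FALSE)
  set.seed(as.integer(seed))
  # the reference cohort reports *realized sample* statistics (mean 1.69 m /
  # 72 kg, sd 0.075 m / 7.7 kg); standardize the draws to match them exactly
  # so no synthetic subject sits far outside the stated anthropometry
  std_to <- function(z, mu, sdv) if (length(z) > 2) mu + (z - mean(z)) / sd(z) * sdv else z * 0 + mu
  hgt <- std_to(rnorm(n_subjects), 1.69, 0.075)
  mas <- std_to(rnorm(n_subjects), 72, 7.7)
  jit_l0 <- runif(n_subjects, 0.9, 1.1)
  jit_k <- runif(n_subjects, 0.9, 1.1)
  trials <- list()
  for (s in seq_len(n_subjects)) {
    l0s <- 0.9 * hgt[s] / 1.8 * jit_l0[s]
    ps <- slip_params(m = mas[s], h = hgt[s], l0 = l0s,
                      k = 20 * mas[s] * 9.81 / l0s * jit_k[s])
    for (v in rownames(speeds)) {
      tr_seed <- (as.integer(seed) + 7919L * s + 104729L * match(v, rownames(speeds))) %% 2147483647L
      tr <- generate_walking_trial(ps, speeds[v, s], steps_per_trial, tr_seed,
                                   subject_id = colnames(speeds)[s], speed_label = v)
      if (!is.null(noise)) {
        nz <- noise; nz$seed <- tr_seed + 1L
        tr <- corrupt_to_imu(tr, nz)
      }
      trials[[paste(colnames(speeds)[s], v, sep = "_")]] <- tr
    }
  }
  structure(trials, class = "imu_cohort")
}
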