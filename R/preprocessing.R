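# Strict local extrema with a refractory window and a minimum windowed
# prominence (the extremum must stand out by `prominence` on both sides
# within `win_n` samples); ties broken to the earliest index.
local_extrema <- function(x, refractory_n, minima = TRUE, prominence = 0,
                          win_n = 20L) {
  if (minima) x <- -x
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (prominence > 0 && length(cand)) {
    ok <- vapply(cand, function(i) {
      l <- x[max(1L, i - win_n):i]; r <- x[i:min(n, i + win_n)]
      (x[i] - min(l) >= prominence) && (x[i] - min(r) >= prominence)
    }, logical(1))
    cand <- cand[ok]
  }
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (i in cand[-1]) if (i - keep[length(keep)] > refractory_n) keep <- c(keep, i)
  keep
}

first_after <- function(idx, i0) {
  j <- idx[idx > i0]
  if (length(j)) j[1] else NA_integer_
}

#' Detect gait events from sacrum acceleration
#'
#' Implements the cascaded event search on a single sacrum accelerometer
#' stream.  Per step cycle: the CoM apex is the next local minimum of the
#' vertical acceleration low-passed at `apex_cutoff`; heel strike (HS) is the
#' first local minimum of the vertical acceleration low-passed at
#' `hs_cutoff` following the local maximum after the apex (the crest of the
#' push-off hump; in these units it may sit below zero); toe off (TO) is the
#' first local minimum of the horizontal acceleration low-passed at
#' `to_cutoff` after the apex — the contralateral-braking trough that
#' coincides with the trailing leg's unloading.  If the HS candidate falls
#' after the TO candidate, HS is re-identified as the preceding local minimum
#' of the 40 Hz trace.  The search then restarts from the TO event.
#'
#' Note the cycle structure: the HS of a cycle is the touchdown of the *next*
#' leg, and the TO is the liftoff of the leg whose apex opened the cycle, so
#' each cycle satisfies `apex < hs < to` and one stance phase spans from the
#' HS of one cycle to the TO of the following cycle (see [segment_trial()]).
#'
#' @param trial an `imu_trial` (or any list with `t`, `ax`, `ay`, `fs`).
#' @param hs_cutoff,to_cutoff,apex_cutoff Butterworth cutoffs (Hz).
#' @param refractory minimum spacing between admissible extrema (s); per
#'   trace it is capped at the half-period resolvable at that trace's cutoff.
#' @param prominence minimum windowed prominence (m/s^2) an extremum must
#'   have on both sides to count; suppresses micro-features that a strict
#'   neighbour comparison would accept on noise-free signals.
#' @return An `event_set`: data frame with one row per detected cycle
#'   (`apex_i`, `hs_i`, `to_i` sample indices; `apex_t`, `hs_t`, `to_t`
#'   times), with attribute `fs`.  Zero rows when no complete cycle is found.
#' @export
detect_gait_events <- function(trial, hs_cutoff = 40, to_cutoff = 10,
                               apex_cutoff = 10, refractory = 0.05,
                               prominence = 0.25) {
  fs <- trial$fs
  if (is.null(fs) || fs < 100)
    stop("detect_gait_events: trial must be sampled at 100 Hz or more", call. = FALSE)
  n <- length(trial$ay)
  if (n < 2 * fs)
    stop("detect_gait_events: trial shorter than two steps", call. = FALSE)
  ay_ap <- lowpass_filter(trial$ay, fs, apex_cutoff)
  ay_hs <- lowpass_filter(trial$ay, fs, min(hs_cutoff, 0.95 * fs / 2))
  ax_to <- lowpass_filter(trial$ax, fs, to_cutoff)
  # refractory per trace: never longer than the half-period resolvable at the
  # trace's own cutoff (a blanket 50 ms would erase the 40 Hz structure)
  rn10 <- max(1L, round(min(refractory, 1 / (2 * apex_cutoff)) * fs))
  rn40 <- max(1L, round(min(refractory, 1 / (2 * hs_cutoff)) * fs))

  wn <- max(5L, round(0.2 * fs))
  # the CoM apex is a height maximum, so its vertical acceleration is
  # negative; this rejects the shallow positive minima around liftoff
  min_ap <- local_extrema(ay_ap, rn10, minima = TRUE, prominence = prominence, win_n = wn)
  min_ap <- min_ap[ay_ap[min_ap] < 0]
  min_hs <- local_extrema(ay_hs, rn40, minima = TRUE, prominence = prominence, win_n = wn)
  max_hs <- local_extrema(ay_hs, rn40, minima = FALSE, prominence = prominence, win_n = wn)
  min_to <- local_extrema(ax_to, rn10, minima = TRUE, prominence = prominence, win_n = wn)

  rows <- list()
  pos <- 0L
  repeat {
    apex <- first_after(min_ap, pos)
    if (is.na(apex)) break
    crest <- first_after(max_hs, apex)
    hs <- if (is.na(crest)) NA_integer_ else first_after(min_hs, crest)
    to <- first_after(min_to, apex)
    if (is.na(hs) || is.na(to)) {
      if (!is.na(to)) { pos <- to; next }
      break
    }
    if (hs > to) {
      # validation rule: HS must precede TO; fall back to the preceding
      # minimum of the 40 Hz trace (bounded below by the previous cycle)
      prev <- min_hs[min_hs < hs & min_hs > pos]
      if (length(prev)) hs <- prev[length(prev)]
      if (hs > to) {
        warning("detect_gait_events: step near t = ", round(trial$t[apex], 2),
                " skipped (no HS before TO)")
        pos <- to
        next
      }
    }
    rows[[length(rows) + 1L]] <- c(apex, hs, to)
    pos <- to
  }
  ev <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    data.frame(apex = integer(0), hs = integer(0), to = integer(0))
  names(ev) <- c("apex_i", "hs_i", "to_i")
  ev$apex_t <- trial$t[ev$apex_i]
  ev$hs_t <- trial$t[ev$hs_i]
  ev$to_t <- trial$t[ev$to_i]
  structure(ev, class = c("event_set", "data.frame"), fs = fs)
}

#' Cut a trial into stance segments
#'
#' Pairs each detected (or ground-truth) HS with the first TO at least
#' `min_stance` later — for detected cycles this is the TO of the *following*
#' cycle, since the TO right after an HS is the contralateral liftoff ending
#' double support.  Acceleration channels are low-passed at `fc` before
#' slicing.  Each segment carries its duration `T`, mean acceleration
#' magnitude `A`, and gait frequency `f_gait` (inverse stride time between
#' ipsilateral heel strikes, falling back to half the inverse step time).
#'
#' @param trial an `imu_trial`.
#' @param events an `event_set` from [detect_gait_events()], or any data frame
#'   with `hs_t` and `to_t` columns (e.g. the generator's truth events).
#' @param fc low-pass cutoff applied to `ax`, `ay` before slicing (Hz).
#' @param min_stance,max_stance admissible stance durations (s).
#' @return List of `stance_segment` objects: `t` (absolute), `T`, `ax`, `ay`,
#'   `A`, `f_gait`, `hs_t`, `to_t`, `fs`.
#' @export
segment_trial <- function(trial, events, fc = 10, min_stance = 0.2, max_stance = 1.4) {
  fs <- trial$fs
  axf <- lowpass_filter(trial$ax, fs, fc)
  ayf <- lowpass_filter(trial$ay, fs, fc)
  hs <- sort(events$hs_t)
  tos <- sort(events$to_t)
  segs <- list()
  last_to <- -Inf
  for (k in seq_along(hs)) {
    cand <- tos[tos >= hs[k] + min_stance & tos <= hs[k] + max_stance]
    if (!length(cand)) next
    to <- cand[1]
    # stride-based gait frequency: ipsilateral heel strikes are two apart
    f_gait <- if (k + 2L <= length(hs)) 1 / (hs[k + 2L] - hs[k])
    else if (k >= 3L) 1 / (hs[k] - hs[k - 2L])
    else if (k + 1L <= length(hs)) 1 / (2 * (hs[k + 1L] - hs[k]))
    else 1 / (2 * (hs[k] - hs[k - 1L]))
    jj <- which(trial$t >= hs[k] - 1e-9 & trial$t <= to + 1e-9)
    if (length(jj) < 5L) next
    if (hs[k] < last_to - 0.5)
      stop("segment_trial: overlapping segments (window starts before the previous stance ends)",
           call. = FALSE)
    last_to <- to
    # extended integration window between the apexes bracketing the stance
    # (steady-gait periodicity holds apex to apex, not heel strike to toe
    # off); fall back to the stance window at the trial edges
    ext0 <- hs[k]; ext1 <- to
    if (!is.null(events$apex_t)) {
      ap <- sort(events$apex_t)
      before <- ap[ap < hs[k]]
      after <- ap[ap > to]
      if (length(before)) ext0 <- before[length(before)]
      if (length(after)) ext1 <- after[1]
    }
    ee <- which(trial$t >= ext0 - 1e-9 & trial$t <= ext1 + 1e-9)
    seg <- list(t = trial$t[jj], T = to - hs[k],
                ax = axf[jj], ay = ayf[jj],
                A = mean(sqrt(axf[jj]^2 + ayf[jj]^2)),
                f_gait = f_gait, hs_t = hs[k], to_t = to, fs = fs,
                t_ext = trial$t[ee], ax_ext = axf[ee], ay_ext = ayf[ee],
                subject_id = trial$subject_id, speed_label = trial$speed_label,
                h = if (!is.null(trial$params)) trial$params$h else NA_real_)
    class(seg) <- "stance_segment"
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

#' Drift-removed integration of stance acceleration
#'
#' Integrates acceleration by the cumulative trapezoid and removes the
#' integration drift linearly in time over the stance:
#' `v_hat(t) = v(t) - (v(T) - v(0)) * t / T`, so that `v_hat(T) = v_hat(0)`
#' exactly.  A constant acceleration bias therefore integrates to identically
#' zero velocity, and any acceleration with zero net impulse passes through
#' unchanged.
#'
#' @param a acceleration samples over one stance (m/s^2).
#' @param T stance duration (s).
#' @param fs sampling rate (Hz).
#' @return Drift-removed velocity track (m/s), starting at 0.
#' @export
integrate_drift_removed <- function(a, T, fs) {
  if (T <= 0) stop("integrate_drift_removed: stance duration must be positive", call. = FALSE)
  t <- seq(0, by = 1 / fs, length.out = length(a))
  v <- cumtrapz(t, a)
  v - (v[length(v)] - v[1]) * t / T
}

#' Gait-speed offset regression
#'
#' Fits the mean forward speed over a stance as an affine function of the
#' average acceleration magnitude `A` and the gait frequency `f`:
#' `v / sqrt(h*g) = a*A + b*f + c`, by least squares over training segments.
#' The `sqrt(h*g)` speed scale removes the subject-size effect.  Fit only on
#' training subjects: the returned model is applied unchanged to held-out
#' data.
#'
#' @param segments list of `stance_segment`s (each with `A`, `f_gait`, `h`),
#'   or a numeric vector `A` (then `f`, `v`, `h` must be given).
#' @param v known mean speeds per segment (m/s).
#' @param f,h gait frequencies (Hz) and subject heights (m) when `segments`
#'   is a bare vector.
#' @param g gravitational acceleration (m/s^2).
#' @return An `offset_model` with coefficients `a`, `b`, `c` and `g`.
#' @export
fit_speed_offset_model <- function(segments, v, f = NULL, h = NULL, g = 9.81) {
  if (is.list(segments) && !is.numeric(segments)) {
    A <- vapply(segments, `[[`, 0, "A")
    f <- vapply(segments, `[[`, 0, "f_gait")
    h <- vapply(segments, `[[`, 0, "h")
  } else A <- segments
  stopifnot(length(A) == length(v), length(f) == length(A), length(h) == length(A))
  if (length(A) < 3L)
    stop("fit_speed_offset_model: need at least 3 segments", call. = FALSE)
  if (sd(A) < 1e-12 && sd(f) < 1e-12)
    stop("fit_speed_offset_model: rank-deficient design (A and f_gait constant)",
         call. = FALSE)
  y <- v / sqrt(h * g)
  fit <- lm(y ~ A + f)
  co <- coef(fit)
  structure(list(a = unname(co["A"]), b = unname(co["f"]), c = unname(co["(Intercept)"]),
                 g = g, n = length(A)),
            class = "offset_model")
}

#' @rdname fit_speed_offset_model
#' @param model an `offset_model`.
#' @param segment a `stance_segment` (uses its `A`, `f_gait`, `h`).
#' @return `apply_speed_offset()` returns the speed offset `v0` (m/s) to add
#'   to the drift-removed horizontal velocity; the vertical offset is zero
#'   (steady walking).
#' @export
apply_speed_offset <- function(model, segment) {
  stopifnot(inherits(model, "offset_model"))
  (model$a * segment$A + model$b * segment$f_gait + model$c) *
    sqrt(segment$h * model$g)
}

#' Assemble the network input block for one stance
#'
#' Runs the integration chain on a segment — drift-removed velocities
#' (Eq.-(5)-style), zero-mean correction plus the horizontal speed offset,
#' trapezoidal positions with the horizontal position reset to zero at HS and
#' the vertical offset set to the leg length — and resamples the seven rows
#' `(t, x, y, vx, vy, ax, ay)` onto `n_points` equally spaced points of
#' normalized stance phase (the time row is the phase fraction `t/T`).
#' Optionally resamples 11 label channels onto the same phase grid.
#'
#' @param segment a `stance_segment`.
#' @param leg_length vertical position offset (m), the subject's leg length.
#' @param v0 horizontal speed offset (m/s), from [apply_speed_offset()].
#' @param labels optional data frame with column `t` and the 11 label
#'   channels on (a superset of) the segment window.
#' @param n_points number of phase samples (200 by default).
#' @return A `feature_block`: 7 x `n_points` matrix with rownames
#'   `t, x, y, vx, vy, ax, ay`; if `labels` were given, an 11 x `n_points`
#'   matrix attached as attribute `labels`.  The native-rate integration
#'   tracks (`t, ax, ay, vx, vy, px, py`) are attached as attribute
#'   `tracks`.
#' @export
assemble_features <- function(segment, leg_length, v0 = 0, labels = NULL,
                              n_points = 200L) {
  stopifnot(inherits(segment, "stance_segment"))
  fs <- segment$fs
  if (!is.null(segment$t_ext)) {
    # drift removal over the apex-to-apex window bracketing the stance, where
    # steady-gait periodicity holds; then slice the stance
    Te <- segment$t_ext[length(segment$t_ext)] - segment$t_ext[1]
    vx <- integrate_drift_removed(segment$ax_ext, Te, fs)
    vy <- integrate_drift_removed(segment$ay_ext, Te, fs)
    vx <- vx - mean(vx) + v0
    vy <- vy - mean(vy)
    jj <- which(segment$t_ext >= segment$hs_t - 1e-9 &
                  segment$t_ext <= segment$to_t + 1e-9)
    vx <- vx[jj]; vy <- vy[jj]
  } else {
    vx <- integrate_drift_removed(segment$ax, segment$T, fs)
    vy <- integrate_drift_removed(segment$ay, segment$T, fs)
    vx <- vx - mean(vx) + v0
    vy <- vy - mean(vy)
  }
  tloc <- segment$t - segment$t[1]
  px <- cumtrapz(tloc, vx)
  py <- cumtrapz(tloc, vy) + leg_length
  rows <- rbind(t = seq(0, 1, length.out = n_points),
                x = resample_linear(px, n_points),
                y = resample_linear(py, n_points),
                vx = resample_linear(vx, n_points),
                vy = resample_linear(vy, n_points),
                ax = resample_linear(segment$ax, n_points),
                ay = resample_linear(segment$ay, n_points))
  out <- structure(rows, class = "feature_block",
                   meta = list(subject_id = segment$subject_id,
                               speed_label = segment$speed_label,
                               T = segment$T, A = segment$A,
                               f_gait = segment$f_gait, v0 = v0))
  attr(out, "tracks") <- data.frame(t = segment$t, ax = segment$ax,
                                    ay = segment$ay, vx = vx, vy = vy,
                                    px = px, py = py)
  if (!is.null(labels)) {
    cn <- setdiff(names(labels), "t")
    if (length(cn) != 11L)
      stop("assemble_features: labels must carry exactly 11 channels", call. = FALSE)
    phase_t <- segment$t[1] + segment$T * seq(0, 1, length.out = n_points)
    lab <- vapply(cn, function(ch)
      approx(labels$t, labels[[ch]], xout = phase_t, rule = 2)$y,
      numeric(n_points))
    attr(out, "labels") <- t(lab)
  }
  out
}

#' Min-max normalization statistics over a training set
#'
#' Computes per-row minima and maxima over a list of feature blocks (or label
#' blocks); [apply_norm()] scales rows to `[0, 1]` with those frozen extrema
#' and [invert_norm()] undoes the scaling.  A degenerate row (max == min) is
#' mapped to the constant 0.5 with a warning.
#'
#' @param blocks list of matrices sharing rownames.
#' @return A `norm_stats` list with `lo`, `hi`.
#' @export
compute_norm_stats <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  lo <- do.call(pmin, lapply(blocks, function(b) apply(b, 1, min)))
  hi <- do.call(pmax, lapply(blocks, function(b) apply(b, 1, max)))
  structure(list(lo = lo, hi = hi), class = "norm_stats")
}

#' @rdname compute_norm_stats
#' @param block a matrix whose rows match the statistics.
#' @param stats a `norm_stats` object.
#' @export
apply_norm <- function(block, stats) {
  rng <- stats$hi - stats$lo
  deg <- rng <= 0
  if (any(deg)) {
    warning("apply_norm: degenerate channel(s) ",
            paste(names(which(deg)), collapse = ", "), " set to 0.5")
    rng[deg] <- 1
  }
  out <- (block - stats$lo) / rng
  out[deg, ] <- 0.5
  out
}

#' @rdname compute_norm_stats
#' @export
invert_norm <- function(block, stats) {
  rng <- stats$hi - stats$lo
  rng[rng <= 0] <- 1
  block * rng + stats$lo
}
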