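LABEL_CHANNELS <- c("grf_x", "grf_y", "T_ank", "T_knee", "T_hip",
                    "th_foot_st", "th_shank_st", "th_thigh_st",
                    "th_foot_sw", "th_shank_sw", "th_thigh_sw")

#' Segment a cohort into per-subject stance datasets
#'
#' Runs event handling and segmentation for every trial and pairs each
#' stance with its ground-truth label frame (the truth stance with maximal
#' time overlap).  Events can come from the detector (the realistic path) or
#' from the generator's truth.
#'
#' @param cohort an `imu_cohort` from [generate_cohort()].
#' @param events `"detected"` or `"truth"`.
#' @return A list keyed by subject id; each element is a list of entries
#'   `list(segment, labels, trial)`.
#' @export
cohort_segments <- function(cohort, events = c("truth", "detected")) {
  events <- match.arg(events)
  out <- list()
  for (tr in cohort) {
    ev <- if (events == "detected") detect_gait_events(tr) else tr$truth$events
    segs <- segment_trial(tr, ev)
    tru_ev <- tr$truth$events
    for (s in segs) {
      ovl <- pmin(s$to_t, tru_ev$to_t) - pmax(s$hs_t, tru_ev$hs_t)
      k <- which.max(ovl)
      if (ovl[k] < 0.5 * s$T) next    # no matching truth stance
      entry <- list(segment = s, labels = tr$truth$stances[[k]],
                    subject_id = tr$subject_id, speed_label = tr$speed_label,
                    leg_length = tr$params$l0, h = tr$params$h,
                    m = tr$params$m, g = tr$params$g,
                    speed_true = tr$truth$speed_true)
      out[[tr$subject_id]] <- c(out[[tr$subject_id]], list(entry))
    }
  }
  out
}

# Dimensionless label scale of one subject: forces per body weight, torques
# per (body weight x height); angles unscaled.  Dividing the labels by this
# before training removes the subject-size effect the same way the speed
# offset is normalized by sqrt(h*g); predictions are rescaled with the test
# subject's known anthropometry.
label_scale_of <- function(e) {
  bw <- e$m * e$g
  c(grf_x = bw, grf_y = bw,
    T_ank = bw * e$h, T_knee = bw * e$h, T_hip = bw * e$h,
    th_foot_st = 1, th_shank_st = 1, th_thigh_st = 1,
    th_foot_sw = 1, th_shank_sw = 1, th_thigh_sw = 1)
}

# Assemble aligned (X, Y) column matrices for a list of cohort entries, given
# a fitted speed-offset model.  Y is in dimensionless (size-normalized)
# units; the per-entry physical scales are returned alongside.
stack_blocks <- function(entries, offset_model, inputs, n_points = 200L) {
  Xs <- vector("list", length(entries)); Ys <- Xs; Ss <- Xs
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    v0 <- apply_speed_offset(offset_model, e$segment)
    fb <- assemble_features(e$segment, e$leg_length, v0 = v0,
                            labels = e$labels, n_points = n_points)
    sc <- label_scale_of(e)
    Xs[[i]] <- unclass(fb)[inputs, , drop = FALSE]
    Ys[[i]] <- attr(fb, "labels") / sc
    Ss[[i]] <- matrix(sc, length(sc), n_points)
  }
  list(X = do.call(cbind, Xs), Y = do.call(cbind, Ys),
       scale = do.call(cbind, Ss),
       per_block = n_points, n_blocks = length(entries))
}

#' Leave-one-subject-out evaluation of the kinetics predictor
#'
#' For every subject: the speed-offset regression, the feature and label
#' normalization extrema, and the network are fitted on the remaining
#' subjects only, then applied unchanged to the held-out subject.  Reported
#' metrics per output channel, subject and speed condition: NRMSE (percent,
#' normalized by the observed range of that subject's channel at that
#' speed), MAE (channel units), and Pearson correlation.
#'
#' @param cohort an `imu_cohort`, or the output of [cohort_segments()].
#' @param cfg a [train_config()].
#' @param inputs feature rows fed to the network (drop `"x"`, `"y"` to ablate
#'   the displacement input, etc.).
#' @param train_speeds speed labels used for training (`NULL` = all; e.g.
#'   `"moderate"` reproduces the restricted-training analysis).
#' @param events event source passed to [cohort_segments()].
#' @param n_points phase samples per stance.
#' @return A `metrics_report`: list with `metrics` (long data frame), `folds`
#'   (per-fold training-set sizes), and `config`.
#' @export
loo_evaluate <- function(cohort, cfg = train_config(),
                         inputs = c("t", "x", "y", "vx", "vy", "ax", "ay"),
                         train_speeds = NULL, events = "truth",
                         n_points = 200L) {
  by_subj <- if (inherits(cohort, "imu_cohort"))
    cohort_segments(cohort, events = events) else cohort
  subjects <- names(by_subj)
  if (length(subjects) < 2L)
    stop("loo_evaluate: need at least two subjects", call. = FALSE)

  metrics <- list()
  folds <- list()
  for (s in subjects) {
    train_entries <- unlist(lapply(by_subj[setdiff(subjects, s)], identity),
                            recursive = FALSE)
    if (!is.null(train_speeds))
      train_entries <- Filter(function(e) e$speed_label %in% train_speeds,
                              train_entries)
    test_entries <- by_subj[[s]]
    if (!length(test_entries)) {
      warning("loo_evaluate: subject ", s, " has no segments; fold skipped")
      next
    }
    # audit: the held-out subject never contributes to the training set
    stopifnot(!any(vapply(train_entries, `[[`, "", "subject_id") == s))

    om <- fit_speed_offset_model(lapply(train_entries, `[[`, "segment"),
                                 vapply(train_entries, `[[`, 0, "speed_true"))
    tr_blocks <- stack_blocks(train_entries, om, inputs, n_points)
    x_stats <- compute_norm_stats(list(tr_blocks$X))
    y_stats <- compute_norm_stats(list(tr_blocks$Y))
    Xn <- apply_norm(tr_blocks$X, x_stats)
    Yn <- apply_norm(tr_blocks$Y, y_stats)

    spec <- network_spec(input_dim = length(inputs))
    net <- build_network(spec, seed = cfg$seed)
    net <- train_network(net, Xn, Yn, cfg)
    net$x_stats <- x_stats
    net$y_stats <- y_stats
    folds[[s]] <- list(n_train_segments = tr_blocks$n_blocks,
                       n_train_columns = ncol(Xn),
                       loss_curve = attr(net, "loss_curve"))

    te_blocks <- stack_blocks(test_entries, om, inputs, n_points)
    pred <- predict_outputs(net, te_blocks$X) * te_blocks$scale
    obs <- te_blocks$Y * te_blocks$scale
    sp <- rep(vapply(test_entries, `[[`, "", "speed_label"), each = n_points)
    for (v in unique(sp)) {
      j <- sp == v
      for (ch in seq_len(nrow(obs))) {
        rng <- diff(range(obs[ch, j]))
        metrics[[length(metrics) + 1L]] <- data.frame(
          subject = s, speed = v, channel = LABEL_CHANNELS[ch],
          nrmse = compute_nrmse(pred[ch, j], obs[ch, j], rng),
          mae = mean(abs(pred[ch, j] - obs[ch, j])),
          pearson = suppressWarnings(stats::cor(pred[ch, j], obs[ch, j])))
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics), folds = folds,
                 config = list(inputs = inputs, train_speeds = train_speeds,
                               cfg = unclass(cfg), events = events)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat("<metrics_report>", length(x$folds), "folds,",
      nrow(m), "channel x subject x speed cells\n")
  agg <- stats::aggregate(nrmse ~ channel, m, mean)
  agg$nrmse <- round(agg$nrmse, 2)
  print(agg, row.names = FALSE)
  cat(sprintf("mean NRMSE %.2f%%, mean |r| %.3f\n",
              mean(m$nrmse), mean(abs(m$pearson), na.rm = TRUE)))
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' @param report a `metrics_report`.
#' @param path CSV path (`channel,subject,speed,nrmse,mae,pearson`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  write.csv(report$metrics[, c("channel", "subject", "speed",
                               "nrmse", "mae", "pearson")],
            path, row.names = FALSE)
  invisible(path)
}
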