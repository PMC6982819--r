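#' Segment anthropometrics
#'
#' Inertial properties of the foot, shank and thigh expressed as fractions of
#' body mass and segment length, following the standard anthropometric tables
#' of the biomechanics literature (Winter's conventions): segment mass as a
#' fraction of body mass, CoM location as a fraction of segment length from
#' the proximal end, and radius of gyration about the segment CoM as a
#' fraction of segment length.
#'
#' @param body_mass body mass (kg).
#' @param mass_frac,com_frac,rg_frac named length-3 numeric overrides
#'   (`foot`, `shank`, `thigh`), each in (0, 1).
#' @return An object of class `anthropometrics`: data frame with one row per
#'   segment and attribute `body_mass`.
#' @export
anthropometrics <- function(body_mass,
                            mass_frac = c(foot = 0.0145, shank = 0.0465, thigh = 0.100),
                            com_frac = c(foot = 0.50, shank = 0.433, thigh = 0.433),
                            rg_frac = c(foot = 0.475, shank = 0.302, thigh = 0.323)) {
  segs <- c("foot", "shank", "thigh")
  stopifnot(body_mass > 0,
            all(segs %in% names(mass_frac)), all(segs %in% names(com_frac)),
            all(segs %in% names(rg_frac)))
  fr <- cbind(mass_frac[segs], com_frac[segs], rg_frac[segs])
  if (any(fr <= 0) || any(fr >= 1))
    stop("anthropometrics: all fractions must lie in (0, 1)", call. = FALSE)
  if (sum(2 * mass_frac[segs]) > 1)
    stop("anthropometrics: segment masses exceed body mass", call. = FALSE)
  out <- data.frame(segment = segs,
                    mass = body_mass * mass_frac[segs],
                    com_frac = com_frac[segs],
                    rg_frac = rg_frac[segs],
                    row.names = segs)
  attr(out, "body_mass") <- body_mass
  class(out) <- c("anthropometrics", class(out))
  out
}

# Central-difference gradient with one-sided ends.
finite_gradient <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("finite_gradient: need at least 3 samples", call. = FALSE)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

#' Bottom-up Newton-Euler recursion for a planar segment chain
#'
#' Generic planar inverse dynamics: segments are ordered distal to proximal;
#' each is described by its mass, moment of inertia about its CoM, CoM
#' position track, angular acceleration track (counter-clockwise positive,
#' i.e. the negative of the clockwise segment-angle convention), and the
#' positions of its distal and proximal joints.  External force `F_dist` and
#' moment `M_dist` applied at the distal end of the first segment (the GRF at
#' the center of pressure enters this way, with `p_dist` set to the CoP).
#'
#' @param segments list of segments, each a list with `m`, `I`, `com` (T x 2),
#'   `a_com` (T x 2), `alpha` (length T, CCW), `p_dist`, `p_prox` (T x 2).
#' @param F_dist T x 2 external force at the distal end of segment 1 (N).
#' @param M_dist length-T external free moment at that end (N*m, CCW).
#' @param g gravitational acceleration (m/s^2).
#' @return List with `M_prox` (T x S matrix of CCW joint moments exerted by
#'   the proximal neighbour on each segment) and `F_prox` (list of T x 2
#'   proximal joint force tracks).
#' @export
newton_euler_chain <- function(segments, F_dist = NULL, M_dist = NULL, g = 9.81) {
  S <- length(segments)
  T_ <- nrow(segments[[1]]$com)
  if (is.null(F_dist)) F_dist <- matrix(0, T_, 2)
  if (is.null(M_dist)) M_dist <- numeric(T_)
  crossz <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  Mprox <- matrix(NA_real_, T_, S)
  Fprox <- vector("list", S)
  fd <- F_dist; md <- M_dist
  for (s in seq_len(S)) {
    sg <- segments[[s]]
    for (nm in c("m", "I", "com", "a_com", "alpha", "p_dist", "p_prox"))
      if (is.null(sg[[nm]])) stop("newton_euler_chain: segment ", s, " missing '", nm, "'",
                                  call. = FALSE)
    grav <- cbind(0, rep(-sg$m * g, T_))
    fp <- sg$m * sg$a_com - grav - fd
    mp <- sg$I * sg$alpha - md -
      crossz(sg$p_prox - sg$com, fp) -
      crossz(sg$p_dist - sg$com, fd)
    Mprox[, s] <- mp
    Fprox[[s]] <- fp
    fd <- -fp
    md <- -mp
  }
  colnames(Mprox) <- vapply(segments, function(sg) sg$name %||% "", "")
  list(M_prox = Mprox, F_prox = Fprox)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planar inverse dynamics of the stance leg
#'
#' Computes ankle, knee and hip torque tracks from segment-angle tracks, the
#' measured GRF and the center of pressure, by the bottom-up Newton-Euler
#' recursion foot -> shank -> thigh.  Segment positions are reconstructed from
#' the ankle position (derived from the CoP through the rolling-foot geometry
#' unless given explicitly); linear and angular accelerations come from
#' central differences after optional low-pass filtering.
#'
#' Torques are reported clockwise-positive, which for the ankle is the
#' extension (plantarflexion) direction: a vertical GRF whose CoP lies a
#' distance `delta` anterior to the ankle produces `T_ank = fy * delta` in
#' static stance.
#'
#' @param angles T x 3 matrix or data frame of `(thigh, shank, foot)` angles
#'   (rad, clockwise-positive from vertical).
#' @param lengths named lengths `l1` (thigh), `l2` (shank), `l3` (foot) (m).
#' @param anthro an [anthropometrics()] object.
#' @param grf T x 2 matrix `(fx, fy)` (N).
#' @param cop length-T CoP x-positions (m).
#' @param fs sampling rate (Hz).
#' @param params a [slip_params()] used for the CoP-to-ankle geometry
#'   (ignored when `ankle` is supplied).
#' @param ankle optional T x 2 ankle position track (m).
#' @param filter_cutoff low-pass cutoff for kinematic differentiation (Hz);
#'   `NA` to differentiate raw tracks.
#' @param g gravitational acceleration (m/s^2).
#' @return Data frame with columns `T_ank`, `T_knee`, `T_hip` (N*m).
#' @export
planar_inverse_dynamics <- function(angles, lengths, anthro, grf, cop, fs,
                                    params = NULL, ankle = NULL,
                                    filter_cutoff = 10, g = 9.81) {
  angles <- as.matrix(angles)
  grf <- as.matrix(grf)
  T_ <- nrow(angles)
  if (T_ < 5L) stop("planar_inverse_dynamics: need at least 5 samples", call. = FALSE)
  if (nrow(grf) != T_ || length(cop) != T_)
    stop("planar_inverse_dynamics: angles, grf and cop must share the time grid", call. = FALSE)
  if (ncol(angles) != 3L)
    stop("planar_inverse_dynamics: angles must have 3 columns (thigh, shank, foot)", call. = FALSE)
  stopifnot(inherits(anthro, "anthropometrics"))
  l1 <- lengths[["l1"]]; l2 <- lengths[["l2"]]; l3 <- lengths[["l3"]]
  dt <- 1 / fs

  smooth <- function(x) if (is.na(filter_cutoff)) x else lowpass_filter(x, fs, filter_cutoff)
  th1 <- smooth(angles[, 1]); th2 <- smooth(angles[, 2]); th3 <- smooth(angles[, 3])

  if (is.null(ankle)) {
    if (is.null(params))
      stop("planar_inverse_dynamics: supply either 'ankle' or 'params' for the CoP geometry",
           call. = FALSE)
    ankle <- cbind(cop - params$d * cos(th3), params$R + params$d * sin(th3))
  } else {
    ankle <- as.matrix(ankle)
  }

  up <- function(th) cbind(sin(th), cos(th))
  fwd <- function(th) cbind(cos(th), -sin(th))    # foot axis, anterior at 0
  knee <- ankle + l2 * up(th2)
  hip <- knee + l1 * up(th1)

  com_foot <- ankle + anthro["foot", "com_frac"] * l3 * fwd(th3)
  com_shank <- knee - anthro["shank", "com_frac"] * l2 * up(th2)
  com_thigh <- hip - anthro["thigh", "com_frac"] * l1 * up(th1)

  acc2 <- function(p) cbind(finite_gradient(finite_gradient(p[, 1], dt), dt),
                            finite_gradient(finite_gradient(p[, 2], dt), dt))
  # clockwise angle convention -> CCW angular acceleration is the negative
  alpha <- function(th) -finite_gradient(finite_gradient(th, dt), dt)

  seg <- function(name, L, com, a_dist, a_prox, th) {
    m <- anthro[name, "mass"]
    list(name = name, m = m, I = m * (anthro[name, "rg_frac"] * L)^2,
         com = com, a_com = acc2(com), alpha = alpha(th),
         p_dist = a_dist, p_prox = a_prox)
  }
  segments <- list(
    seg("foot", l3, com_foot, cbind(cop, 0), ankle, th3),
    seg("shank", l2, com_shank, ankle, knee, th2),
    seg("thigh", l1, com_thigh, knee, hip, th1)
  )
  res <- newton_euler_chain(segments, F_dist = grf, g = g)
  # clockwise-positive (extension-positive at the ankle) reporting
  data.frame(T_ank = -res$M_prox[, 1],
             T_knee = -res$M_prox[, 2],
             T_hip = -res$M_prox[, 3])
}
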