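#' Physical parameters of the compliant walking model
#'
#' Constructs and validates the parameter set of the sagittal-plane compliant
#' walking model: a point mass on a massless leg spring whose foot is an
#' off-centered rolling arc ("curvy foot"), with the foot orientation locked to
#' the leg by a constraint ankle torque.  Defaults are scaled from cohort-mean
#' anthropometry (body mass 72 kg, height 1.69 m) with literature-typical
#' dimensionless leg stiffness `k * l0 / (m * g)` of about 20.
#'
#' The linearization coefficients `cl` and `ck` are computed at the reference
#' configuration (vertical leg, uncompressed spring) rather than taken as free
#' inputs: `cl = 1 - R / l0` makes the affine ankle-torque row the exact
#' first-order expansion of the rolling-contact constraint torque, and
#' `ck = 1 - l1 * gamma1`, where `gamma1` is the sensitivity of the thigh angle
#' to leg length in the two-link inverse kinematics, does the same for the
#' thigh-angle row.
#'
#' @param m body mass (kg).
#' @param h subject height (m).
#' @param g gravitational acceleration (m/s^2).
#' @param l0 rest length of the total leg spring, contact to CoM (m).
#'   Default `0.9 * h / 1.8`.
#' @param k leg-spring stiffness (N/m). Default gives `k*l0/(m*g) = 20`.
#' @param R radius of the curvy foot (m).
#' @param d ankle offset from the foot center (m); the contact point sits `d`
#'   ahead of the ankle when the leg is vertical.
#' @param k_a ankle-spring stiffness (N*m/rad). Retained for interface
#'   compatibility; the stance dynamics lock the foot to the leg with a
#'   constraint torque, so `k_a` does not enter the equations of motion.
#' @param l1,l2 thigh and shank lengths (m). Defaults split the rest
#'   CoM-ankle distance `l0 - R` with a 4 percent slack so the knee is bent
#'   (away from the straight-leg singularity) at the reference configuration.
#' @param l3 foot segment length (m). Used by the inverse-dynamics label
#'   generator only.
#'
#' @return An object of class `slip_params`: a validated named list with the
#'   derived fields `l_a` (rest CoM-ankle length), `cl`, `ck`, `gamma1`,
#'   `gamma2` (segment-angle linearization sensitivities, 1/m).
#' @examples
#' p <- slip_params()
#' p$k * p$l0 / (p$m * p$g)   # dimensionless leg stiffness, about 20
#' @export
slip_params <- function(m = 72, h = 1.69, g = 9.81,
                        l0 = 0.9 * h / 1.8,
                        k = 20 * m * g / l0,
                        R = 0.3, d = 0.05,
                        k_a = 500,
                        l1 = 0.52 * (l0 - R),
                        l2 = 0.52 * (l0 - R),
                        l3 = 0.152 * h) {
  p <- list(m = m, h = h, g = g, l0 = l0, k = k, R = R, d = d, k_a = k_a,
            l1 = l1, l2 = l2, l3 = l3)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("slip_params: field '", nm, "' must be a finite scalar", call. = FALSE)
  }
  if (m <= 0 || k <= 0 || k_a <= 0) stop("slip_params: m, k, k_a must be > 0", call. = FALSE)
  if (any(c(l0, R, d, l1, l2, l3, h) <= 0)) stop("slip_params: lengths must be > 0", call. = FALSE)
  if (R >= l0) stop("slip_params: foot radius R must be smaller than l0", call. = FALSE)
  if (l1 + l2 > l0 + 1e-6) stop("slip_params: l1 + l2 must not exceed l0", call. = FALSE)
  if (l1 + l2 < l0 - R - 1e-12)
    stop("slip_params: thigh + shank cannot span the rest CoM-ankle distance", call. = FALSE)

  p$l_a <- l0 - R
  p$cl <- 1 - R / l0
  gam <- tryCatch(segment_angle_sensitivities(l1, l2, p$l_a),
                  error = function(e) c(gamma1 = NA_real_, gamma2 = NA_real_))
  p$gamma1 <- gam[["gamma1"]]
  p$gamma2 <- gam[["gamma2"]]
  p$ck <- 1 - l1 * p$gamma1
  # knee-bend offsets of the two-link chain at the reference configuration;
  # NA (with the gammas) when the chain is straight-singular there, in which
  # case the affine segment-angle maps are unavailable
  p$beta1_0 <- suppressWarnings(acos((l1^2 + p$l_a^2 - l2^2) / (2 * l1 * p$l_a)))
  p$beta2_0 <- suppressWarnings(acos((l2^2 + p$l_a^2 - l1^2) / (2 * l2 * p$l_a)))
  class(p) <- "slip_params"
  p
}

#' @export
print.slip_params <- function(x, ...) {
  cat("<slip_params>\n")
  cat(sprintf("  m = %.2f kg, h = %.3f m, g = %.3f m/s^2\n", x$m, x$h, x$g))
  cat(sprintf("  leg spring: k = %.1f N/m, l0 = %.3f m  (k*l0/(m*g) = %.2f)\n",
              x$k, x$l0, x$k * x$l0 / (x$m * x$g)))
  cat(sprintf("  curvy foot: R = %.3f m, d = %.3f m; segments l1 = %.3f, l2 = %.3f, l3 = %.3f m\n",
              x$R, x$d, x$l1, x$l2, x$l3))
  cat(sprintf("  linearization: cl = %.4f, ck = %.4f (gamma1 = %.3f, gamma2 = %.3f 1/m)\n",
              x$cl, x$ck, x$gamma1, x$gamma2))
  invisible(x)
}

# d(theta_thigh)/dl and d(theta_shank)/dl of the two-link inverse kinematics at
# the reference CoM-ankle distance D0 (straight-leg singularity excluded by the
# slip_params invariants).
segment_angle_sensitivities <- function(l1, l2, D0) {
  c1 <- (l1^2 + D0^2 - l2^2) / (2 * l1 * D0)
  c2 <- (l2^2 + D0^2 - l1^2) / (2 * l2 * D0)
  if (abs(c1) >= 1 || abs(c2) >= 1)
    stop("degenerate segment lengths: two-link triangle is singular at the reference", call. = FALSE)
  dbeta1 <- -((D0^2 - l1^2 + l2^2) / (2 * l1 * D0^2)) / sqrt(1 - c1^2)
  dbeta2 <- -((D0^2 - l2^2 + l1^2) / (2 * l2 * D0^2)) / sqrt(1 - c2^2)
  c(gamma1 = -dbeta1, gamma2 = dbeta2)
}

#' Touchdown reference values frozen over one stance
#'
#' Captures the leg configuration at heel strike: the leg angle `theta_hs`
#' (rad, clockwise-positive from vertical; negative when the contact point is
#' ahead of the CoM, as at touchdown), the CoM height `y_hs` (m), and the
#' ground-contact position `c_hs` (m).  The composite offset
#' `alpha = R * theta_hs - c_hs + d` is precomputed and frozen for the whole
#' stance; it is the constant that makes the linearized CoM-to-state map
#' affine.
#'
#' @param theta_hs leg angle at heel strike (rad).
#' @param y_hs CoM height at heel strike (m); must be positive.
#' @param c_hs ground contact position at heel strike (m).
#' @param params a [slip_params()] object supplying `R` and `d`.
#' @return An object of class `touchdown_refs` with fields `theta_hs`, `y_hs`,
#'   `c_hs`, `alpha`.
#' @export
touchdown_refs <- function(theta_hs, y_hs, c_hs, params) {
  stopifnot(inherits(params, "slip_params"))
  if (!is.finite(y_hs) || y_hs <= 0)
    stop("touchdown_refs: y_hs must be a positive height", call. = FALSE)
  structure(list(theta_hs = theta_hs, y_hs = y_hs, c_hs = c_hs,
                 alpha = params$R * theta_hs - c_hs + params$d),
            class = "touchdown_refs")
}

#' Touchdown references implied by a touchdown leg angle
#'
#' Convenience constructor: places the uncompressed leg (`l = l0`) at angle
#' `theta_hs` with contact at `c_hs` and derives the CoM height from the
#' rolling-foot geometry.
#'
#' @inheritParams touchdown_refs
#' @return A [touchdown_refs()] object.
#' @export
touchdown_refs_at <- function(theta_hs, params, c_hs = 0) {
  y_hs <- params$R + params$d * sin(theta_hs) + (params$l0 - params$R) * cos(theta_hs)
  touchdown_refs(theta_hs, y_hs, c_hs, params)
}

#' Full kinematic state of the stance model
#'
#' A `slip_state` carries the redundant coordinate set used throughout the
#' stance simulator: spring length `l` (contact-to-CoM, m), leg angle `theta`
#' (rad), CoM position `(x, y)` (m) and all four time derivatives.  Either the
#' generalized pair `(l, theta)` or the Cartesian pair `(x, y)` may be given;
#' the other is filled in from the rolling-foot geometry under `refs`.
#'
#' @param params a [slip_params()] object.
#' @param refs a [touchdown_refs()] object fixing the contact geometry.
#' @param l,theta generalized coordinates; supply with `dl`, `dtheta`.
#' @param x,y CoM position; supply with `dx`, `dy`.
#' @param dl,dtheta,dx,dy time derivatives (m/s, rad/s).
#' @return An object of class `slip_state`.
#' @export
slip_state <- function(params, refs, l = NULL, theta = NULL, dl = NULL, dtheta = NULL,
                       x = NULL, y = NULL, dx = NULL, dy = NULL) {
  stopifnot(inherits(params, "slip_params"), inherits(refs, "touchdown_refs"))
  num <- function(v) if (is.null(v)) v else unname(as.numeric(v))
  l <- num(l); theta <- num(theta); dl <- num(dl); dtheta <- num(dtheta)
  x <- num(x); y <- num(y); dx <- num(dx); dy <- num(dy)
  if (!is.null(l) && !is.null(theta)) {
    if (l <= 0) stop("slip_state: spring length must be positive", call. = FALSE)
    ls <- l - params$R
    pos <- leg_forward_geometry(ls, theta, refs, params)
    if (is.null(dl)) dl <- 0
    if (is.null(dtheta)) dtheta <- 0
    J <- leg_geometry_jacobian(ls, theta, params)
    v <- J %*% c(dl, dtheta)
    out <- list(l = l, theta = theta, x = unname(pos[1]), y = unname(pos[2]),
                dl = dl, dtheta = dtheta, dx = unname(v[1]), dy = unname(v[2]))
  } else if (!is.null(x) && !is.null(y)) {
    if (y <= 0) stop("slip_state: CoM height must be positive during stance", call. = FALSE)
    q <- leg_inverse_geometry(x, y, refs, params)
    if (is.null(dx)) dx <- 0
    if (is.null(dy)) dy <- 0
    J <- leg_geometry_jacobian(q[["ls"]], q[["theta"]], params)
    qd <- solve(J, c(dx, dy))
    out <- list(l = unname(q[["ls"]]) + params$R, theta = unname(q[["theta"]]),
                x = x, y = y,
                dl = unname(qd[1]), dtheta = unname(qd[2]), dx = dx, dy = dy)
  } else {
    stop("slip_state: supply either (l, theta) or (x, y)", call. = FALSE)
  }
  structure(out, class = "slip_state")
}

# CoM position from generalized coordinates (ls = l - R is the CoM-ankle
# length).  Contact rolls with the leg angle: p_x = c_hs + R*(theta-theta_hs).
leg_forward_geometry <- function(ls, theta, refs, params) {
  px <- refs$c_hs + params$R * (theta - refs$theta_hs)
  c(x = px - params$d * cos(theta) + ls * sin(theta),
    y = params$R + params$d * sin(theta) + ls * cos(theta))
}

# Jacobian d(x,y)/d(l, theta); dls = dl since R is constant.
leg_geometry_jacobian <- function(ls, theta, params) {
  matrix(c(sin(theta), params$R + params$d * sin(theta) + ls * cos(theta),
           cos(theta), params$d * cos(theta) - ls * sin(theta)),
         2, 2, byrow = TRUE)
}

# Invert the rolling-foot geometry: (x, y) -> (ls, theta) by Newton iteration
# on the scalar residual in theta.
leg_inverse_geometry <- function(x, y, refs, params, theta0 = NULL) {
  R <- params$R; d <- params$d
  if (is.null(theta0)) {
    cx <- refs$c_hs - R * refs$theta_hs + d
    theta0 <- atan2(x - cx, y)
  }
  theta <- theta0
  for (i in 1:60) {
    st <- sin(theta); ct <- cos(theta)
    ls <- (y - R - d * st) / ct
    f <- refs$c_hs + R * (theta - refs$theta_hs) - d * ct + ls * st - x
    dls <- (-d * ct * ct + (y - R - d * st) * st) / ct^2
    df <- R + d * st + ls * ct + dls * st
    step <- f / df
    theta <- theta - step
    if (abs(step) < 1e-14) break
  }
  st <- sin(theta); ct <- cos(theta)
  ls <- (y - R - d * st) / ct
  if (!is.finite(ls) || ls <= 0)
    stop("leg_inverse_geometry: no contact-consistent configuration for this CoM position",
         call. = FALSE)
  c(ls = unname(ls), theta = unname(theta))
}
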