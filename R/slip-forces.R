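#' Nonlinear stance force law of the curvy-foot model
#'
#' Given the generalized coordinates of a loaded leg — CoM-ankle length
#' `ls = l - R` and leg angle `theta` — returns the ground reaction force, the
#' constraint ankle torque and the constraint force.  The massless leg-foot
#' assembly is in equilibrium at every instant: the spring force
#' `F = k*(l0 - l)` acts along the leg axis, the prismatic constraint
#' transmits the perpendicular force `fa`, and the torque balance about the
#' rolling contact fixes `fa = -F*(d + R*sin(theta)) / (ls + R*cos(theta))`.
#' The resulting GRF passes through the CoM; its moment about the ankle is the
#' extension-positive constraint torque `Ta`.
#'
#' This is the nonlinear counterpart of [state_to_kinetics()]; the affine map
#' is its exact expansion in the augmented state at the reference
#' configuration.
#'
#' @param ls CoM-ankle length (m), `l - R`.
#' @param theta leg angle (rad, clockwise-positive from vertical).
#' @param params a [slip_params()] object.
#' @return A list with `fx`, `fy` (N), `Ta` (N*m), `fa` (N), and the spring
#'   force magnitude `F` (N).
#' @export
slip_forces <- function(ls, theta, params) {
  k <- params$k; l0 <- params$l0; R <- params$R; d <- params$d
  st <- sin(theta); ct <- cos(theta)
  F <- k * (l0 - (ls + R))
  fa <- -F * (d + R * st) / (ls + R * ct)
  gx <- F * st + fa * ct
  gy <- F * ct - fa * st
  # moment of the GRF about the ankle, z out of the sagittal plane
  Ta <- d * ct * gy + (R + d * st) * gx
  list(fx = gx, fy = gy, Ta = Ta, fa = fa, F = F)
}

#' Exact two-link inverse kinematics of the leg
#'
#' Solves the thigh and shank angles that place the two-link chain between the
#' CoM (taken as the hip of the point-mass model) and the ankle, plus the foot
#' angle from the rolling-foot convention (the foot is locked to the
#' ankle-to-CoM axis).  Angles are clockwise-positive from vertical and the
#' knee points anteriorly for both legs.
#'
#' @param com numeric length-2 CoM position (m).
#' @param ankle numeric length-2 ankle position (m).
#' @param params a [slip_params()] object (uses `l1`, `l2`).
#' @param leg `"stance"` or `"swing"` (same anterior-knee convention; the
#'   selector is kept for interface symmetry with
#'   [state_to_segment_angles()]).
#' @return A length-3 `segment_angles` vector `(thigh, shank, foot)`.  The
#'   attribute `near_singular` is `TRUE` when the knee is within 1e-3 rad of
#'   the straight-leg singularity.
#' @export
inverse_kinematics_multibody <- function(com, ankle, params, leg = c("stance", "swing")) {
  leg <- match.arg(leg)
  stopifnot(inherits(params, "slip_params"),
            is.numeric(com), length(com) == 2L,
            is.numeric(ankle), length(ankle) == 2L)
  l1 <- params$l1; l2 <- params$l2
  dv <- com - ankle
  D <- sqrt(sum(dv^2))
  if (D > l1 + l2 + 1e-12)
    stop(sprintf("inverse_kinematics_multibody: target distance %.4f m exceeds l1 + l2 = %.4f m",
                 D, l1 + l2), call. = FALSE)
  if (D < abs(l1 - l2))
    stop("inverse_kinematics_multibody: target closer than |l1 - l2|", call. = FALSE)
  theta_dir <- atan2(dv[1], dv[2])
  c1 <- pmin(1, pmax(-1, (l1^2 + D^2 - l2^2) / (2 * l1 * D)))
  c2 <- pmin(1, pmax(-1, (l2^2 + D^2 - l1^2) / (2 * l2 * D)))
  beta1 <- acos(c1); beta2 <- acos(c2)
  th <- c(thigh = theta_dir - beta1, shank = theta_dir + beta2, foot = theta_dir)
  class(th) <- "segment_angles"
  attr(th, "near_singular") <- (l1 + l2 - D) < 1e-3 * (l1 + l2)
  th
}

#' Forward kinematics of the leg chain
#'
#' Rebuilds the knee and CoM (hip) positions from segment angles and the ankle
#' position; the exact inverse of [inverse_kinematics_multibody()].
#'
#' @param angles length-3 `(thigh, shank, foot)` angles (rad).
#' @param ankle numeric length-2 ankle position (m).
#' @param params a [slip_params()] object.
#' @return A list with `knee` and `com` positions (each length 2).
#' @export
forward_kinematics <- function(angles, ankle, params) {
  a <- as.numeric(angles)
  knee <- ankle + params$l2 * c(sin(a[2]), cos(a[2]))
  com <- knee + params$l1 * c(sin(a[1]), cos(a[1]))
  list(knee = knee, com = com)
}

#' Ankle and contact positions of a loaded leg
#'
#' @param ls CoM-ankle length (m); only the contact depends on `theta` alone.
#' @param theta leg angle (rad).
#' @param refs a [touchdown_refs()] object.
#' @param params a [slip_params()] object.
#' @return List with `contact`, `ankle`, `com` positions (length-2 each).
#' @export
leg_points <- function(ls, theta, refs, params) {
  px <- refs$c_hs + params$R * (theta - refs$theta_hs)
  ankle <- c(px - params$d * cos(theta), params$R + params$d * sin(theta))
  com <- ankle + ls * c(sin(theta), cos(theta))
  list(contact = c(px, 0), ankle = ankle, com = com)
}
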