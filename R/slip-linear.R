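#' Linearized map from CoM position to the augmented leg state
#'
#' The augmented state `z = (l, theta, l*theta)` collects the leg-spring
#' length, the leg angle and their product, so that maps which are quadratic
#' in `(l, theta)` become affine in `z`.  Around the reference configuration
#' (vertical leg, uncompressed spring) the CoM position `x = (x, y)`
#' determines `z` through the affine map
#' `z = W1 %*% x + b1`, with
#' \preformatted{
#'   W1 = | 0      1 |        b1 = | 0          |
#'        | 1/y_hs 0 |             | alpha/y_hs |
#'        | 1      0 |             | alpha      |
#' }
#' where `alpha = R*theta_hs - c_hs + d` is the frozen touchdown offset.
#'
#' @param x numeric length-2 CoM position `(x, y)` (m).
#' @param refs a [touchdown_refs()] object.
#' @return An object of class `augmented_state`: numeric `z` of length 3 with
#'   attribute `construction = "linearized"`.
#' @examples
#' p <- slip_params()
#' r <- touchdown_refs_at(-0.3, p)
#' linearized_state_map(c(-r$alpha, r$y_hs), r)  # (y_hs, 0, 0)
#' @export
linearized_state_map <- function(x, refs) {
  if (!inherits(refs, "touchdown_refs") || !is.finite(refs$y_hs) || refs$y_hs <= 0)
    stop("linearized_state_map: invalid touchdown reference (y_hs must be > 0)", call. = FALSE)
  stopifnot(is.numeric(x), length(x) == 2L)
  Wb <- state_map_matrices(refs)
  z <- drop(Wb$W1 %*% x + Wb$b1)
  augmented_state(z, construction = "linearized")
}

#' @rdname linearized_state_map
#' @return `state_map_matrices()` returns the pair `list(W1, b1)`.
#' @export
state_map_matrices <- function(refs) {
  yh <- refs$y_hs; a <- refs$alpha
  list(W1 = matrix(c(0, 1, 1 / yh, 0, 1, 0), 3, 2, byrow = TRUE),
       b1 = c(0, a / yh, a))
}

#' Augmented state vector
#'
#' @param z numeric length 3: `(l, theta, l*theta)`.
#' @param construction `"exact"` when built from a consistent `slip_state`
#'   (then `z[3] == z[1]*z[2]`), `"linearized"` when produced by the affine
#'   map (the product identity holds only to first order).
#' @return An `augmented_state` object.
#' @export
augmented_state <- function(z, construction = c("exact", "linearized")) {
  construction <- match.arg(construction)
  stopifnot(is.numeric(z), length(z) == 3L, all(is.finite(z)))
  if (construction == "exact" && abs(z[3] - z[1] * z[2]) > 1e-8 * max(1, abs(z[1] * z[2])))
    stop("augmented_state: z[3] must equal z[1]*z[2] for an exact construction", call. = FALSE)
  structure(as.numeric(z), class = "augmented_state", construction = construction)
}

#' @rdname augmented_state
#' @param state a `slip_state`.
#' @export
augment <- function(state) {
  stopifnot(inherits(state, "slip_state"))
  augmented_state(c(state$l, state$theta, state$l * state$theta), "exact")
}

#' Affine map from the augmented state to GRFs and ankle torque
#'
#' Returns `f = (fx, fy, Ta)`: horizontal and vertical ground reaction force
#' (N) and the constraint ankle torque (N*m, extension-positive), as the
#' affine map `f = W2 %*% z + b2` whose entries are written in terms of
#' `k, d, l0, R` and the linearization coefficient `cl = 1 - R/l0`:
#' \preformatted{
#'  W2 = k * |  d/l0     l0 - R     R/l0 - 1 |     b2 = k * | -d        |
#'           | -1        d         -d/l0     |              |  l0       |
#'           | -d*cl     R*l0*cl   -R*cl     |              |  d*l0*cl  |
#' }
#' This is the exact expansion of the nonlinear rolling-contact force law in
#' the augmented state: terms linear in `z` capture products `(l0-l)*theta`
#' through the `l*theta` component.
#'
#' @param z an [augmented_state()] (or numeric length 3).
#' @param params a [slip_params()] object.
#' @return Numeric length 3 with names `fx, fy, Ta`, class `kinetics_vector`.
#' @export
state_to_kinetics <- function(z, params) {
  stopifnot(inherits(params, "slip_params"))
  z <- as.numeric(z); stopifnot(length(z) == 3L)
  Wb <- kinetics_matrices(params)
  f <- drop(Wb$W2 %*% z + Wb$b2)
  names(f) <- c("fx", "fy", "Ta")
  class(f) <- "kinetics_vector"
  f
}

#' @rdname state_to_kinetics
#' @export
kinetics_matrices <- function(params) {
  k <- params$k; d <- params$d; l0 <- params$l0; R <- params$R; cl <- params$cl
  W2 <- k * matrix(c(d / l0,  l0 - R,    R / l0 - 1,
                     -1,      d,        -d / l0,
                     -d * cl, R * l0 * cl, -R * cl),
                   3, 3, byrow = TRUE)
  b2 <- k * c(-d, l0, d * l0 * cl)
  list(W2 = W2, b2 = b2)
}

#' Affine map from the augmented state to segment angles
#'
#' Returns the thigh, shank and foot angles `theta = (theta1, theta2, theta3)`
#' (rad, clockwise-positive from vertical) of the selected leg as
#' `theta = W3 %*% z + b3`.  The rows are the first-order expansion of the
#' exact two-link inverse kinematics around the reference configuration; the
#' entries that depend on the spring length (first column and bias) flip sign
#' between the stance and the swing leg, while the leg-angle column is shared:
#' \preformatted{
#'   stance:  W3 = | +gamma1 1 0 |   b3 = | -beta1_0 - gamma1*l0 |
#'                 | +gamma2 1 0 |        | +beta2_0 - gamma2*l0 |
#'                 |  0      1 0 |        |  0                   |
#'   swing :  first column and bias negated in rows 1-2
#' }
#' `beta1_0`, `beta2_0` are the constant knee-bend offsets of the two-link
#' chain at the reference configuration.
#' with `gamma1 = (1 - ck)/l1`.  The swing-leg rows come from the mirror
#' symmetry of steady gait: the contralateral leg's configuration is the
#' reflection of the stance configuration at the mirrored leg angle.
#'
#' @inheritParams state_to_kinetics
#' @param leg `"stance"` or `"swing"`.
#' @return Numeric length 3 (`thigh, shank, foot`), class `segment_angles`.
#' @export
state_to_segment_angles <- function(z, params, leg = c("stance", "swing")) {
  leg <- match.arg(leg)
  stopifnot(inherits(params, "slip_params"))
  z <- as.numeric(z); stopifnot(length(z) == 3L)
  Wb <- segment_angle_matrices(params, leg)
  th <- drop(Wb$W3 %*% z + Wb$b3)
  if (any(abs(th) >= pi))
    warning("state_to_segment_angles: angle outside (-pi, pi); far from the linearization reference")
  names(th) <- c("thigh", "shank", "foot")
  class(th) <- "segment_angles"
  th
}

#' @rdname state_to_segment_angles
#' @export
segment_angle_matrices <- function(params, leg = c("stance", "swing")) {
  leg <- match.arg(leg)
  if (!is.finite(params$gamma1) || !is.finite(params$gamma2))
    stop("segment_angle_matrices: degenerate segment lengths (two-link chain singular at the reference)",
         call. = FALSE)
  g1 <- params$gamma1; g2 <- params$gamma2; l0 <- params$l0
  s <- if (leg == "stance") 1 else -1
  W3 <- matrix(c(s * g1, 1, 0,
                 s * g2, 1, 0,
                 0,      1, 0), 3, 3, byrow = TRUE)
  b3 <- c(s * (-params$beta1_0 - g1 * l0),
          s * (params$beta2_0 - g2 * l0),
          0)
  list(W3 = W3, b3 = b3)
}

#' CoM position to lower-limb kinetics and kinematics in one affine map
#'
#' Composes [linearized_state_map()] with [state_to_kinetics()] and
#' [state_to_segment_angles()] for both legs.  The result is identical (to
#' round-off) to the single stacked affine map
#' `rbind(W2 %*% W1, W3s %*% W1, W3w %*% W1) %*% x + bias`, which is the sense
#' in which every output channel is a weighted sum of the CoM position.
#'
#' @inheritParams linearized_state_map
#' @param params a [slip_params()] object.
#' @param stacked if `TRUE`, evaluate through the precomposed 9 x 2 matrix
#'   instead of the two-step route (both agree to round-off).
#' @return A list with `kinetics` (length-3 `kinetics_vector`), `stance` and
#'   `swing` (length-3 `segment_angles`).
#' @export
com_to_outputs <- function(x, refs, params, stacked = FALSE) {
  z <- linearized_state_map(x, refs)
  if (!stacked) {
    return(list(kinetics = state_to_kinetics(z, params),
                stance = state_to_segment_angles(z, params, "stance"),
                swing = state_to_segment_angles(z, params, "swing")))
  }
  m <- com_output_matrices(refs, params)
  out <- drop(m$W %*% as.numeric(x) + m$b)
  kin <- out[1:3]; names(kin) <- c("fx", "fy", "Ta"); class(kin) <- "kinetics_vector"
  st <- out[4:6]; sw <- out[7:9]
  names(st) <- names(sw) <- c("thigh", "shank", "foot")
  class(st) <- class(sw) <- "segment_angles"
  list(kinetics = kin, stance = st, swing = sw)
}

#' @rdname com_to_outputs
#' @export
com_output_matrices <- function(refs, params) {
  m1 <- state_map_matrices(refs)
  m2 <- kinetics_matrices(params)
  m3s <- segment_angle_matrices(params, "stance")
  m3w <- segment_angle_matrices(params, "swing")
  W <- rbind(m2$W2 %*% m1$W1, m3s$W3 %*% m1$W1, m3w$W3 %*% m1$W1)
  b <- c(m2$W2 %*% m1$b1 + m2$b2,
         m3s$W3 %*% m1$b1 + m3s$b3,
         m3w$W3 %*% m1$b1 + m3w$b3)
  list(W = W, b = b)
}
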