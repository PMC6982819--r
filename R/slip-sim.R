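#' Simulate one stance phase of the compliant walking model
#'
#' Integrates the nonlinear stance dynamics — leg spring, rolling curvy-foot
#' contact, and the constraint ankle torque that locks the foot to the leg —
#' from the given initial state until the leg spring unloads (vertical GRF
#' crosses zero at the rest length), using a fixed-step 4th-order Runge-Kutta
#' scheme with the liftoff time located by bisection to `dt/100`.  The system
#' is conservative: kinetic plus gravitational plus elastic energy is an
#' invariant of the exact dynamics, and the integrator's energy drift
#' converges at 4th order in `dt`.
#'
#' @param params a [slip_params()] object.
#' @param initial a [slip_state()]; must be contact-consistent with `refs`
#'   (its `(x, y)` must equal the geometry implied by its `(l, theta)`).
#' @param refs a [touchdown_refs()] object (frozen for the whole stance).
#' @param dt integration step (s).
#' @param tmax give up if no liftoff occurred by this time (s).
#' @return A `stance_trajectory`: list with `t`, `states`
#'   (data frame `x, y, vx, vy, l, theta`), `grf` (data frame `fx, fy`),
#'   `ankle_torque`, `constraint_force`, `energy`, and `events`
#'   (`touchdown = 0`, `liftoff`).
#' @export
simulate_stance <- function(params, initial, refs, dt = 1e-4, tmax = 3) {
  stopifnot(inherits(params, "slip_params"), inherits(initial, "slip_state"),
            inherits(refs, "touchdown_refs"))
  if (dt <= 0) stop("simulate_stance: dt must be positive", call. = FALSE)
  pos <- leg_forward_geometry(initial$l - params$R, initial$theta, refs, params)
  if (max(abs(pos - c(initial$x, initial$y))) > 1e-6)
    stop("simulate_stance: initial state is not contact-consistent with refs (foot not on the ground)",
         call. = FALSE)
  par <- c(m = params$m, g = params$g, k = params$k,
           l0 = params$l0, R = params$R, d = params$d)
  res <- cpp_simulate_stance(par, refs$theta_hs, refs$c_hs,
                             c(initial$x, initial$y, initial$dx, initial$dy),
                             dt, tmax)
  if (nzchar(res$error))
    stop("simulate_stance: ", res$error, call. = FALSE)
  tr <- res$trace
  energy <- 0.5 * params$m * (tr[, "vx"]^2 + tr[, "vy"]^2) +
    params$m * params$g * tr[, "y"] +
    0.5 * params$k * (params$l0 - tr[, "l"])^2
  structure(list(
    t = tr[, "t"],
    states = data.frame(x = tr[, "x"], y = tr[, "y"], vx = tr[, "vx"], vy = tr[, "vy"],
                        l = tr[, "l"], theta = tr[, "theta"]),
    grf = data.frame(fx = tr[, "fx"], fy = tr[, "fy"]),
    ankle_torque = tr[, "Ta"],
    constraint_force = tr[, "fa"],
    energy = energy,
    events = c(touchdown = 0, liftoff = res$liftoff),
    params = params, refs = refs, dt = dt
  ), class = "stance_trajectory")
}

#' @export
print.stance_trajectory <- function(x, ...) {
  cat("<stance_trajectory>\n")
  cat(sprintf("  duration %.3f s (%d samples, dt = %g s)\n",
              x$events[["liftoff"]], length(x$t), x$dt))
  cat(sprintf("  peak vertical GRF %.1f N; energy drift %.3g%%\n",
              max(x$grf$fy), 100 * diff(range(x$energy)) / x$energy[1]))
  invisible(x)
}

#' Write / read a stance trajectory as CSV with a JSON sidecar
#'
#' The CSV has the header `t,x,y,l,theta,fx,fy,Ta,fa`; the sidecar
#' (`<path>.json`) stores the model parameters and touchdown references so a
#' trajectory round-trips losslessly together with its provenance.
#'
#' @param traj a `stance_trajectory`.
#' @param path CSV file path.
#' @return `write_stance_trajectory()` returns `path` invisibly;
#'   `read_stance_trajectory()` returns a list with `data` (data frame),
#'   `params`, `refs`.
#' @export
write_stance_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "stance_trajectory"))
  df <- data.frame(t = traj$t, x = traj$states$x, y = traj$states$y,
                   l = traj$states$l, theta = traj$states$theta,
                   fx = traj$grf$fx, fy = traj$grf$fy,
                   Ta = traj$ankle_torque, fa = traj$constraint_force)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(params = unclass(traj$params)[c("m", "h", "g", "l0", "k", "R", "d",
                                               "k_a", "l1", "l2", "l3")],
               refs = unclass(traj$refs), dt = traj$dt,
               events = as.list(traj$events))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stance_trajectory
#' @export
read_stance_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "l", "theta", "fx", "fy", "Ta", "fa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_stance_trajectory: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  params <- if (!is.null(side)) do.call(slip_params, as.list(side$params)) else NULL
  refs <- if (!is.null(side))
    touchdown_refs(side$refs$theta_hs, side$refs$y_hs, side$refs$c_hs, params) else NULL
  list(data = df, params = params, refs = refs)
}
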