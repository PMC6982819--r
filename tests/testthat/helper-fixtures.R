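# Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

default_params <- function() memo("params", function() slip_params())

# a short clean walking trial used by several preprocessing tests
tiny_trial <- function() memo("tiny_trial", function() {
  generate_walking_trial(default_params(), 1.25, 12, seed = 7)
})

# symmetric, point-ankle parameter set for linearization tests: the affine
# maps drop the O(d*theta) height term, so first-order agreement requires a
# vanishing ankle offset; extra knee slack keeps the two-link chain reachable
# over the perturbation range
sym_params <- function() memo("sym_params", function() {
  p0 <- slip_params()
  slip_params(d = 1e-12, l1 = 0.62 * p0$l_a, l2 = 0.62 * p0$l_a)
})

# independent point-foot SLIP integrator (RK4 on the Cartesian state with a
# central force law), used as an oracle for the R = d = 0 limit
point_slip_trajectory <- function(params, contact_x, init, dt, n_steps) {
  k <- params$k; l0 <- params$l0; m <- params$m; g <- params$g
  deriv <- function(s) {
    dx <- s[1] - contact_x; dy <- s[2]
    r <- sqrt(dx^2 + dy^2)
    f <- if (r < l0) k * (l0 - r) / r else 0
    c(s[3], s[4], f * dx / m, f * dy / m - g)
  }
  out <- matrix(NA_real_, n_steps + 1, 4)
  s <- init
  out[1, ] <- s
  for (i in seq_len(n_steps)) {
    k1 <- deriv(s); k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2); k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- s
  }
  out
}

# brute-force local extrema scan (oracle for the detector's crafted-signal
# tests): strict neighbour comparison only
brute_minima <- function(x) which(diff(sign(diff(x))) > 0) + 1L

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(1e-12, max(abs(b))), tol)
}
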