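test_that("linearized state map matches its defining affine structure", {
  p <- default_params()
  r <- touchdown_refs_at(-0.3, p)

  # horizontal position cancelling the offset zeroes theta and l*theta
  z <- linearized_state_map(c(-r$alpha, r$y_hs), r)
  expect_equal(as.numeric(z), c(r$y_hs, 0, 0), tolerance = 1e-12)

  # zero-geometry reference: alpha = 0
  p0 <- slip_params(R = 1e-9, d = 1e-9, l1 = 0.4225, l2 = 0.4225)
  r0 <- touchdown_refs(0, 1, 0, p0)
  expect_equal(as.numeric(linearized_state_map(c(0, 1), r0)), c(1, 0, 0),
               tolerance = 1e-8)

  # oracle: independent term-by-term scalar expansion
  set.seed(11)
  for (i in 1:20) {
    x <- c(rnorm(1, 0, 0.3), runif(1, 0.5, 1.2))
    rr <- touchdown_refs(rnorm(1, -0.3, 0.1), runif(1, 0.6, 1.0), rnorm(1, 0, 0.2), p)
    z <- as.numeric(linearized_state_map(x, rr))
    expect_equal(z[1], x[2], tolerance = 1e-14)
    expect_equal(z[2], x[1] / rr$y_hs + rr$alpha / rr$y_hs, tolerance = 1e-12)
    expect_equal(z[3], x[1] + rr$alpha, tolerance = 1e-12)
  }

  expect_error(linearized_state_map(c(0, 1), touchdown_refs(0, 1, 0, p)$y_hs),
               "invalid")
  expect_error(touchdown_refs(0, -1, 0, p), "positive")
})

test_that("state-to-kinetics map is affine and consistent with the force law", {
  p <- default_params()
  set.seed(2)
  for (i in 1:10) {
    z1 <- rnorm(3, c(0.8, 0, 0), 0.1)
    z2 <- rnorm(3, c(0.8, 0, 0), 0.1)
    W2 <- kinetics_matrices(p)$W2
    d12 <- as.numeric(state_to_kinetics(z1 + z2, p)) - as.numeric(state_to_kinetics(z2, p))
    expect_equal(d12, as.numeric(W2 %*% z1), tolerance = 1e-9)
  }
  expect_equal(as.numeric(state_to_kinetics(c(0, 0, 0), p)),
               as.numeric(kinetics_matrices(p)$b2), tolerance = 1e-12)

  # near the reference configuration the affine map agrees with the exact
  # nonlinear force law; halving the perturbation cuts the error at least in
  # half (asymptotically by four)
  refz <- c(p$l0, 0, 0)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.5, -1, -0.8))
  for (kdir in 1:nrow(dirs)) {
    err <- sapply(c(2e-2, 1e-2, 5e-3, 2.5e-3), function(eps) {
      dz <- eps * dirs[kdir, ] * c(1, 1, p$l0)
      l <- refz[1] + dz[1]; th <- refz[2] + dz[2]
      zq <- c(l, th, l * th)   # consistent augmented state
      f_lin <- as.numeric(state_to_kinetics(zq, p))[1:2]
      fr <- slip_forces(l - p$R, th, p)
      max(abs(f_lin - c(fr$fx, fr$fy)))
    })
    expect_true(all(err[-1] <= 0.55 * err[-length(err)] + 1e-10))
  }
})

test_that("segment-angle map: affine cancellation, leg selector, IK agreement", {
  p <- default_params()
  W3s <- segment_angle_matrices(p, "stance")
  W3w <- segment_angle_matrices(p, "swing")

  set.seed(3)
  z1 <- rnorm(3, c(0.42, 0, 0), 0.03); z2 <- rnorm(3, c(0.42, 0, 0), 0.03)
  d12 <- suppressWarnings(as.numeric(state_to_segment_angles(z1 + z2, p)) -
    as.numeric(state_to_segment_angles(z2, p)))
  expect_equal(d12, as.numeric(W3s$W3 %*% z1), tolerance = 1e-10)

  # stance and swing differ exactly in the sign-flipped entries (first
  # column and bias of the thigh/shank rows); the leg-angle column is shared
  expect_equal(W3w$W3[, 1], -W3s$W3[, 1])
  expect_equal(W3w$W3[, 2:3], W3s$W3[, 2:3])
  expect_equal(W3w$b3, -W3s$b3)

  # first-order agreement with the exact inverse kinematics
  ps <- sym_params()
  r0 <- touchdown_refs(0, ps$l0, 0, ps)
  err <- sapply(c(4e-2, 2e-2, 1e-2, 5e-3), function(eps) {
    l <- ps$l0 - eps; th <- 0.5 * eps / ps$l0
    lin <- as.numeric(state_to_segment_angles(c(l, th, l * th), ps, "stance"))
    pts <- leg_points(l - ps$R, th, r0, ps)
    ik <- as.numeric(inverse_kinematics_multibody(pts$com, pts$ankle, ps))
    max(abs(lin - ik))
  })
  expect_true(all(err[-1] <= 0.55 * err[-length(err)] + 1e-12))

  expect_error(slip_params(l1 = 1e-3, l2 = 1e-3), "span|exceed|segment")
})

test_that("composed CoM-to-outputs map equals its stacked affine form", {
  p <- default_params()
  r <- touchdown_refs_at(-0.32, p)
  set.seed(4)
  for (i in 1:100) {
    x <- c(rnorm(1, -r$alpha, 0.1), r$y_hs + rnorm(1, 0, 0.05))
    a <- com_to_outputs(x, r, p, stacked = FALSE)
    b <- com_to_outputs(x, r, p, stacked = TRUE)
    va <- c(as.numeric(a$kinetics), as.numeric(a$stance), as.numeric(a$swing))
    vb <- c(as.numeric(b$kinetics), as.numeric(b$stance), as.numeric(b$swing))
    expect_rel_equal(va, vb, 1e-12)
  }
  # offset-cancelling input reproduces the pure state evaluation
  a <- com_to_outputs(c(-r$alpha, r$y_hs), r, p)
  expect_equal(as.numeric(a$kinetics),
               as.numeric(state_to_kinetics(c(r$y_hs, 0, 0), p)),
               tolerance = 1e-9)
})

test_that("full linearization is first-order accurate around the reference", {
  ps <- sym_params()
  r0 <- touchdown_refs(0, ps$l0, 0, ps)
  xref <- c(-r0$alpha, r0$y_hs)
  set.seed(5)
  dirs <- matrix(rnorm(12), 6, 2); dirs <- dirs / sqrt(rowSums(dirs^2))
  eps <- 10^seq(-4, -1, length.out = 10)
  err <- sapply(eps, function(e) {
    m <- 0
    for (i in seq_len(nrow(dirs))) {
      xx <- xref + e * dirs[i, ]
      lin <- com_to_outputs(xx, r0, ps)
      st <- slip_state(ps, r0, x = xx[1], y = xx[2])
      fr <- slip_forces(st$l - ps$R, st$theta, ps)
      pts <- leg_points(st$l - ps$R, st$theta, r0, ps)
      ik <- as.numeric(inverse_kinematics_multibody(pts$com, pts$ankle, ps))
      ptsm <- leg_points(st$l - ps$R, -st$theta, r0, ps)
      ikm <- -as.numeric(inverse_kinematics_multibody(ptsm$com, ptsm$ankle, ps))
      nl <- c(fr$fx, fr$fy, fr$Ta, ik, ikm)
      li <- c(as.numeric(lin$kinetics), as.numeric(lin$stance), as.numeric(lin$swing))
      m <- max(m, max(abs(nl - li)))
    }
    m
  })
  slope <- coef(lm(log(err) ~ log(eps)))[2]
  expect_gte(slope, 1.9)
})

test_that("stance simulation conserves energy with 4th-order convergence", {
  p <- default_params()
  r <- touchdown_refs_at(-0.33, p)
  init <- slip_state(p, r, l = p$l0, theta = -0.33)
  init <- slip_state(p, r, x = init$x, y = init$y, dx = 1.25, dy = -0.25)

  # measure convergence where truncation still dominates round-off: at
  # dt = 2e-3 the drift is already ~1e-10 of the total energy
  tr1 <- simulate_stance(p, init, r, dt = 4e-3)
  drift1 <- diff(range(tr1$energy)) / tr1$energy[1]
  expect_lt(drift1, 1e-3)
  tr2 <- simulate_stance(p, init, r, dt = 2e-3)
  drift2 <- diff(range(tr2$energy)) / tr2$energy[1]
  expect_gte(drift1 / drift2, 4)

  # vertical GRF non-negative, exactly zero at the bisected liftoff
  expect_true(all(tr1$grf$fy >= 0))
  expect_equal(tail(tr1$grf$fy, 1), 0)
  expect_true(all(diff(tr1$t) > 0))
})

test_that("a stance through the symmetric midpoint is time-reversal symmetric", {
  # construct the touchdown state by running the second half of the stance
  # from a mirror-invariant midpoint (CoM above the contact center, level
  # velocity, compressed well past equilibrium so the spring re-extends
  # within a walking-like sweep) and reflecting the liftoff state
  p0 <- slip_params(d = 1e-12)
  th_hs <- -0.3
  r <- touchdown_refs(th_hs, p0$l0, p0$R * th_hs, p0)  # c_hs - R*theta_hs = 0
  v <- 1.2
  del <- 2.6 * (p0$m * p0$g - p0$m * v^2 / p0$l0) / p0$k
  mid <- slip_state(p0, r, l = p0$l0 - del, theta = 0)
  mid <- slip_state(p0, r, x = mid$x, y = mid$y, dx = v, dy = 0)
  half <- simulate_stance(p0, mid, r, dt = 5e-4)
  lo <- half$states[nrow(half$states), ]
  init <- slip_state(p0, r, x = -lo$x, y = lo$y, dx = lo$vx, dy = -lo$vy)
  full <- simulate_stance(p0, init, r, dt = 5e-4)

  Td <- full$events[["liftoff"]]
  g <- seq(0.02 * Td, 0.98 * Td, length.out = 300)
  f1 <- approx(full$t, full$grf$fy, g)$y
  f2 <- approx(full$t, full$grf$fy, Td - g)$y
  expect_lt(max(abs(f1 - f2)) / max(f1), 0.01)
  n <- nrow(full$states)
  impulse <- p0$m * (full$states$vx[n] - full$states$vx[1])
  expect_lt(abs(impulse), 1e-4 * p0$m * v)
})

test_that("R = d = 0 limit reduces to the point-foot model", {
  p0 <- slip_params(R = 1e-9, d = 1e-9, l1 = 0.4225, l2 = 0.4225)
  r <- touchdown_refs_at(-0.3, p0)
  init <- slip_state(p0, r, l = p0$l0, theta = -0.3)
  init <- slip_state(p0, r, x = init$x, y = init$y, dx = 1.2, dy = -0.3)
  tr <- simulate_stance(p0, init, r, dt = 1e-3)

  # GRF is always directed along the contact-to-CoM line
  px <- r$c_hs - p0$R * r$theta_hs
  along <- with(tr, cbind(states$x - px, states$y))
  cr <- tr$grf$fx * along[, 2] - tr$grf$fy * along[, 1]
  expect_lt(max(abs(cr)) / max(tr$grf$fy), 1e-6)

  # trajectory matches an independent point-foot integrator
  n <- min(300, length(tr$t) - 1)
  orc <- point_slip_trajectory(p0, px, c(init$x, init$y, init$dx, init$dy),
                               1e-3, n)
  expect_lt(max(abs(orc[, 1] - tr$states$x[1:(n + 1)])), 1e-6)
  expect_lt(max(abs(orc[, 2] - tr$states$y[1:(n + 1)])), 1e-6)
})

test_that("simulate_stance rejects inconsistent initial states", {
  p <- default_params()
  r <- touchdown_refs_at(-0.3, p)
  bad <- slip_state(p, r, l = p$l0, theta = -0.3)
  bad$x <- bad$x + 0.05
  expect_error(simulate_stance(p, bad, r), "contact")
})

test_that("two-link inverse kinematics round-trips exactly", {
  p <- default_params()
  # straight vertical leg
  ps <- slip_params(l1 = 0.3, l2 = 0.3, l0 = 0.61, R = 0.02, d = 0.01, h = 1.69)
  th <- inverse_kinematics_multibody(c(0, 0.6), c(0, 0), ps)
  expect_equal(as.numeric(th)[1:2], c(0, 0), tolerance = 1e-10)
  expect_true(attr(th, "near_singular"))

  set.seed(6)
  worst <- 0
  for (i in 1:1000) {
    ankle <- c(rnorm(1, 0, 0.3), runif(1, 0, 0.3))
    D <- runif(1, abs(p$l1 - p$l2) + 0.02, 0.999 * (p$l1 + p$l2))
    ang <- runif(1, -0.9, 0.9)
    com <- ankle + D * c(sin(ang), cos(ang))
    th <- inverse_kinematics_multibody(com, ankle, p)
    fk <- forward_kinematics(th, ankle, p)
    worst <- max(worst, max(abs(fk$com - com)))
  }
  expect_lt(worst, 1e-8)

  expect_error(inverse_kinematics_multibody(c(0, 1), c(0, 0), p), "exceeds")
})

test_that("stance trajectory CSV round-trips with its JSON sidecar", {
  p <- default_params()
  r <- touchdown_refs_at(-0.3, p)
  init <- slip_state(p, r, l = p$l0, theta = -0.3)
  init <- slip_state(p, r, x = init$x, y = init$y, dx = 1.2, dy = -0.3)
  tr <- simulate_stance(p, init, r, dt = 2e-3)
  path <- file.path(tempdir(), "stance.csv")
  write_stance_trajectory(tr, path)
  back <- read_stance_trajectory(path)
  expect_equal(back$data$fy, tr$grf$fy, tolerance = 1e-9)
  expect_equal(back$params$k, p$k, tolerance = 1e-9)
  expect_equal(back$refs$alpha, r$alpha, tolerance = 1e-12)
  writeLines(sub("\"t\"", "\"time\"", readLines(path)), path)
  expect_error(read_stance_trajectory(path), "missing column")
})
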