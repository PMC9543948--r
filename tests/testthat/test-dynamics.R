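test_that("straight unforced weightless body at rest is an equilibrium", {
  b <- body_params(g = 0, cd1 = 0, cd2 = 0, beta0 = 0.2)
  s <- moth_state(theta = 1.0, phi = 1.2)  # phi - theta = beta0
  d <- state_derivative(s, moth_controls(), b)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("centre-of-mass acceleration obeys Newton's second law", {
  for (k in 1:8) {
    b <- rand_body(100 + k)
    s <- rand_state(200 + k)
    u <- rand_controls(300 + k)
    d <- state_derivative(s, u, b)
    acc <- segment_accels(s, d, b)
    total <- b$m1 * acc$a1 + b$m2 * acc$a2
    expect_equal(total, external_force(s, u, b), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("drag-free unforced body has centre-of-mass acceleration (0, -g)", {
  b <- rand_body(7, cd1 = 0, cd2 = 0)
  s <- rand_state(8)
  d <- state_derivative(s, moth_controls(tau = 3e-4), b)
  acc <- segment_accels(s, d, b)
  com_acc <- (b$m1 * acc$a1 + b$m2 * acc$a2) / (b$m1 + b$m2)
  expect_equal(com_acc, c(0, -b$g), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("internal joint torques never change total linear momentum", {
  b <- rand_body(11)
  s <- rand_state(12)
  base <- state_derivative(s, moth_controls(tau = 0), b)
  tweaked <- state_derivative(s, moth_controls(tau = 4e-4), b)
  f_base <- segment_accels(s, base, b)
  f_tw <- segment_accels(s, tweaked, b)
  expect_equal(b$m1 * f_base$a1 + b$m2 * f_base$a2,
               b$m1 * f_tw$a1 + b$m2 * f_tw$a2, tolerance = 1e-10)

  # spring/damper constants likewise leave dP/dt untouched
  b2 <- rand_body(11, K = 0, C = 0)
  free <- state_derivative(s, moth_controls(tau = 0), b2)
  f_free <- segment_accels(s, free, b2)
  expect_equal(b$m1 * f_base$a1 + b$m2 * f_base$a2,
               b2$m1 * f_free$a1 + b2$m2 * f_free$a2, tolerance = 1e-10)
})

test_that("ballistic configuration reproduces closed-form projectile motion", {
  b <- body_params(cd1 = 0, cd2 = 0, K = 0, C = 0)
  s0 <- moth_state(theta = 1.0, phi = 0.8, xdot = 0.3, ydot = 0.4,
                   thetadot = 2, phidot = -1)
  traj <- simulate_segment(s0, moth_controls(), b)
  c0 <- com_state(s0, b)
  for (i in c(5, 11, nrow(traj))) {
    t <- traj$t[i]
    ci <- com_state(state_from_traj_row(traj, i), b)
    expect_equal(ci[["com_x"]], c0[["com_x"]] + c0[["com_xdot"]] * t,
                 tolerance = 1e-7)
    expect_equal(ci[["com_y"]],
                 c0[["com_y"]] + c0[["com_ydot"]] * t - b$g * t^2 / 2,
                 tolerance = 1e-7)
  }
  expect_equal(traj$t[nrow(traj)], 0.02)
})

test_that("mechanical energy is conserved in the conservative limit", {
  b <- rand_body(21, cd1 = 0, cd2 = 0, C = 0)
  s0 <- rand_state(22)
  traj <- simulate_segment(s0, moth_controls(), b)
  E <- vapply(seq_len(nrow(traj)), function(i)
    mechanical_energy(state_from_traj_row(traj, i), b), 0)
  expect_lt(max(abs(E - E[1])), 1e-6 * max(abs(E[1]), 1e-6))
})

test_that("with damping and drag but no thrust, energy never increases", {
  b <- rand_body(31)
  s0 <- rand_state(32)
  traj <- simulate_segment(s0, moth_controls(), b)
  E <- vapply(seq_len(nrow(traj)), function(i)
    mechanical_energy(state_from_traj_row(traj, i), b), 0)
  expect_true(all(diff(E) <= 1e-10))
})

test_that("momentum theorem holds along simulated segments", {
  b <- rand_body(41)
  s0 <- rand_state(42)
  u <- rand_controls(43)
  traj <- simulate_segment(s0, u, b, dt = 5e-4)
  # central finite differences of momentum vs external force
  for (i in c(10, 20, 30)) {
    dt <- traj$t[i + 1] - traj$t[i - 1]
    p_lo <- linear_momentum(state_from_traj_row(traj, i - 1), b)
    p_hi <- linear_momentum(state_from_traj_row(traj, i + 1), b)
    f <- external_force(state_from_traj_row(traj, i), u, b)
    expect_equal((p_hi - p_lo) / dt, f, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("quadratic drag law dissipates energy and opposes motion", {
  b <- rand_body(51, drag = "quadratic")
  s <- rand_state(52)
  k <- mothprune:::segment_kinematics(s, b)
  f <- external_force(s, moth_controls(), b)
  drag_part <- f - c(0, -(b$m1 + b$m2) * b$g)
  # drag power on the two centroids is non-positive
  power <- sum(drag_part * (b$m1 * k$v1 + b$m2 * k$v2) / (b$m1 + b$m2))
  traj <- simulate_segment(s, moth_controls(F = 0), body_params(
    drag = "quadratic", g = 0, K = 0, C = 0))
  E <- vapply(seq_len(nrow(traj)), function(i)
    mechanical_energy(state_from_traj_row(traj, i),
                      body_params(drag = "quadratic", g = 0, K = 0, C = 0)), 0)
  expect_true(all(diff(E) <= 1e-12))
})

test_that("COM sits at the joint for symmetric bodies and at the head-thorax
           centroid in the vanishing-abdomen limit", {
  b <- body_params(m1 = 1e-3, m2 = 1e-3, L1 = 0.02, L2 = 0.02)
  s <- moth_state(x = 0.3, y = -0.1, theta = 0.7, phi = 0.7)
  cs <- com_state(s, b)
  expect_equal(unname(cs[c("com_x", "com_y")]), c(0.3, -0.1),
               tolerance = 1e-12)
  b2 <- body_params(m1 = 1e-3, m2 = 1e-12)
  cs2 <- com_state(s, b2)
  r1 <- c(0.3 + 0.01 * cos(0.7), -0.1 + 0.01 * sin(0.7))
  expect_equal(unname(cs2[c("com_x", "com_y")]), r1, tolerance = 1e-6)
})

test_that("COM velocity matches finite differences of COM position", {
  b <- rand_body(61)
  traj <- simulate_segment(rand_state(62), rand_controls(63), b, dt = 2e-4)
  pos <- t(vapply(seq_len(nrow(traj)), function(i)
    com_state(state_from_traj_row(traj, i), b)[c("com_x", "com_y")],
    numeric(2)))
  i <- 25
  v_fd <- (pos[i + 1, ] - pos[i - 1, ]) / (traj$t[i + 1] - traj$t[i - 1])
  v <- com_state(state_from_traj_row(traj, i), b)[c("com_xdot", "com_ydot")]
  expect_equal(unname(v), unname(v_fd), tolerance = 1e-4)
})

test_that("energy decomposition: doubling velocities quadruples kinetic part", {
  b <- rand_body(71)
  s <- rand_state(72)
  s0 <- s; s0[c("xdot", "ydot", "thetadot", "phidot")] <- 0
  pot <- mechanical_energy(s0, b)
  kin1 <- mechanical_energy(s, b) - pot
  s2 <- s; s2[c("xdot", "ydot", "thetadot", "phidot")] <-
    2 * s[c("xdot", "ydot", "thetadot", "phidot")]
  kin2 <- mechanical_energy(s2, b) - pot
  expect_equal(kin2, 4 * kin1, tolerance = 1e-12)
  # zero at rest, at reference height, spring at rest angle
  b0 <- body_params(beta0 = 0.1, g = 0)
  expect_equal(mechanical_energy(moth_state(theta = 1, phi = 1.1), b0), 0)
})

test_that("batch integrator agrees with deSolve on random strokes", {
  b <- rand_body(81)
  n <- 6
  set.seed(82)
  states <- t(vapply(1:n, function(i) rand_state(500 + i), numeric(8)))
  controls <- t(vapply(1:n, function(i) rand_controls(600 + i), numeric(3)))
  batch <- mothprune:::.integrate_segments_cpp(
    states, controls, mothprune:::as_param_vector(b), 0.02, 1e-10, 1e-12)
  expect_true(all(batch$ok))
  for (i in 1:n) {
    fs <- final_state(simulate_segment(states[i, ], controls[i, ], b,
                                       rtol = 1e-10, atol = 1e-12))
    expect_equal(unname(fs), unname(batch$final[i, ]), tolerance = 1e-7)
  }
})

test_that("grid refinement and tolerance tightening leave the final state", {
  b <- rand_body(91)
  s0 <- rand_state(92)
  u <- rand_controls(93)
  coarse <- final_state(simulate_segment(s0, u, b, dt = 1e-3))
  fine <- final_state(simulate_segment(s0, u, b, dt = 5e-4))
  expect_equal(coarse, fine, tolerance = 1e-7)
  # tightening tolerances converges toward the high-accuracy reference
  ref <- final_state(simulate_segment(s0, u, b, rtol = 1e-12, atol = 1e-13))
  err6 <- max(abs(final_state(simulate_segment(s0, u, b, rtol = 1e-6,
                                               atol = 1e-8)) - ref))
  err8 <- max(abs(final_state(simulate_segment(s0, u, b, rtol = 1e-8,
                                               atol = 1e-10)) - ref))
  expect_lt(err8, err6)
  expect_lt(err8, 1e-5)
})

test_that("invalid dynamics inputs are rejected with diagnostics", {
  b <- body_params()
  expect_error(state_derivative(c(rep(0, 7), NaN), moth_controls(), b),
               "finite")
  expect_error(state_derivative(moth_state(), c(-0.1, 0, 0), b),
               "non-negative")
  expect_error(moth_controls(F = -1), "non-negative")
  expect_error(body_params(m1 = -1), "positive")
  expect_error(body_params(rF = 0.5), "rF")
  expect_error(simulate_segment(moth_state(), moth_controls(), b,
                                duration = -1), "positive")
})

test_that("trajectory export writes the documented columns", {
  traj <- simulate_segment(moth_state(), moth_controls(F = 0.02),
                           body_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_named(back, c("t", "x", "y", "theta", "phi",
                       "xdot", "ydot", "thetadot", "phidot"))
  expect_equal(back$t[1], 0)
  expect_true(all(diff(back$t) > 0))
})
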