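#' Body parameters for the two-segment moth model
#'
#' The simulated moth is two rigid segments -- the head-thorax and the
#' abdomen -- joined at a pin joint carrying a torsional spring and damper.
#' The head-thorax centroid sits at the joint plus `L1/2` along the
#' head-thorax axis (angle `theta`, measured counterclockwise from the
#' positive x axis); the abdomen centroid sits at the joint minus `L2/2`
#' along the abdomen axis (angle `phi`), so the abdomen extends opposite the
#' head-thorax direction when `phi = theta`.
#'
#' The shipped defaults are hawkmoth-scale stand-ins (masses of order a gram,
#' segment lengths of order two centimetres, a joint spring that puts the
#' abdominal pendulum near 10 Hz); every physics test in the package is a
#' parameter-independent invariant, so none of these numbers is load-bearing.
#'
#' @param m1,m2 Segment masses (kg): head-thorax and abdomen.
#' @param L1,L2 Segment lengths (m).
#' @param I1,I2 Segment moments of inertia about their own centroids
#'   (kg m^2).
#' @param K Torsional spring stiffness at the joint (N m / rad).
#' @param C Torsional damping coefficient at the joint (N m s / rad).
#' @param beta0 Spring rest angle (rad): the joint torque vanishes when
#'   `phi - theta = beta0`.
#' @param cd1,cd2 Translational drag coefficients per segment. Under the
#'   default linear drag law the drag force is `-cd * v` (N s / m); under the
#'   quadratic law it is `-cd * |v| * v`.
#' @param g Gravitational acceleration (m / s^2).
#' @param rF Offset of the thrust application point from the joint along the
#'   head-thorax axis (m). With the default `rF = 0` the wing force acts at
#'   the joint and exerts no direct moment about it.
#' @param drag Drag law, `"linear"` (default) or `"quadratic"`.
#' @return An object of class `moth_body`.
#' @examples
#' body <- body_params()
#' state_derivative(moth_state(theta = pi / 2, phi = pi / 2),
#'                  moth_controls(F = 0.02, alpha = 0, tau = 0), body)
#' @export
body_params <- function(m1 = 1.2e-3, m2 = 0.8e-3,
                        L1 = 0.020, L2 = 0.026,
                        I1 = 4.0e-8, I2 = 4.5e-8,
                        K = 1.0e-3, C = 1.0e-5, beta0 = 0,
                        cd1 = 5e-3, cd2 = 5e-3,
                        g = 9.81, rF = 0,
                        drag = c("linear", "quadratic")) {
  drag <- match.arg(drag)
  vals <- c(m1 = m1, m2 = m2, L1 = L1, L2 = L2, I1 = I1, I2 = I2,
            K = K, C = C, beta0 = beta0, cd1 = cd1, cd2 = cd2,
            g = g, rF = rF)
  if (!all(is.finite(vals)))
    stop("all body parameters must be finite")
  if (any(vals[c("m1", "m2", "L1", "L2", "I1", "I2")] <= 0))
    stop("masses, lengths and inertias must be positive")
  if (any(vals[c("K", "C", "cd1", "cd2", "g")] < 0))
    stop("K, C, cd1, cd2 and g must be non-negative")
  if (rF < 0 || rF > L1)
    stop("rF must lie in [0, L1]")
  structure(c(as.list(vals), list(drag = drag)), class = "moth_body")
}

# parameter vector in the layout the compiled dynamics expects
as_param_vector <- function(params) {
  stopifnot(inherits(params, "moth_body"))
  c(params$m1, params$m2, params$L1, params$L2, params$I1, params$I2,
    params$K, params$C, params$beta0, params$cd1, params$cd2,
    params$g, params$rF, if (params$drag == "quadratic") 1 else 0)
}

state_names <- c("x", "y", "theta", "phi",
                 "xdot", "ydot", "thetadot", "phidot")

#' Construct a moth state vector
#'
#' `(x, y)` is the joint position; `theta` and `phi` are the head-thorax and
#' abdomen axis angles, counterclockwise from the positive x axis.
#'
#' @param x,y Joint position (m).
#' @param theta,phi Segment angles (rad).
#' @param xdot,ydot Joint velocity (m/s).
#' @param thetadot,phidot Angular velocities (rad/s).
#' @return Named numeric vector of length 8.
#' @export
moth_state <- function(x = 0, y = 0, theta = pi / 2, phi = pi / 2,
                       xdot = 0, ydot = 0, thetadot = 0, phidot = 0) {
  s <- c(x = x, y = y, theta = theta, phi = phi,
         xdot = xdot, ydot = ydot, thetadot = thetadot, phidot = phidot)
  if (!all(is.finite(s))) stop("all state entries must be finite")
  s
}

#' Construct a controls vector
#'
#' @param F Stroke-averaged wing force magnitude (N), `F >= 0`.
#' @param alpha Thrust direction relative to the head-thorax midline (rad);
#'   the force acts along world angle `theta + alpha`.
#' @param tau Abdominal torque about the joint (N m), applied to the abdomen
#'   with an equal-and-opposite reaction on the head-thorax.
#' @return Named numeric vector `c(F, alpha, tau)`.
#' @export
moth_controls <- function(F = 0, alpha = 0, tau = 0) {
  u <- c(F = F, alpha = alpha, tau = tau)
  if (!all(is.finite(u))) stop("all controls must be finite")
  if (F < 0) stop("force magnitude F must be non-negative")
  u
}

check_state <- function(state) {
  if (length(state) != 8 || !all(is.finite(state)))
    stop("state must be a finite numeric vector of length 8")
  invisible(state)
}

#' Time derivative of the moth state
#'
#' Evaluates the equations of motion of the coupled two-segment system in the
#' generalized coordinates `(x, y, theta, phi)`: joint spring/damper torque
#' `K((phi - theta) - beta0) + C(phidot - thetadot)` acting equal and
#' opposite on the two segments, the control torque `tau` on the abdomen with
#' its reaction, thrust of magnitude `F` along world angle `theta + alpha`
#' applied `rF` along the head-thorax axis, gravity on each centroid, and
#' drag on each centroid.
#'
#' @param state State vector, see [moth_state()].
#' @param controls Controls vector, see [moth_controls()].
#' @param params A [body_params()] object.
#' @return Named numeric vector of length 8:
#'   `(xdot, ydot, thetadot, phidot, xddot, yddot, thetaddot, phiddot)`.
#' @export
state_derivative <- function(state, controls, params) {
  check_state(state)
  if (length(controls) != 3 || !all(is.finite(controls)))
    stop("controls must be a finite numeric vector of length 3")
  if (controls[[1]] < 0) stop("force magnitude F must be non-negative")
  ds <- .moth_rhs_cpp(as.numeric(state), as.numeric(controls),
                      as_param_vector(params))
  names(ds) <- c("xdot", "ydot", "thetadot", "phidot",
                 "xddot", "yddot", "thetaddot", "phiddot")
  ds
}

#' Simulate one constant-control stroke
#'
#' Integrates the moth dynamics over one stroke (default 20 ms, half the
#' 25 Hz wingbeat cycle) with the controls held constant, using an adaptive
#' integrator from \pkg{deSolve} with dense output on a fixed reporting grid.
#'
#' @inheritParams state_derivative
#' @param duration Stroke duration (s).
#' @param dt Reporting grid step (s); the final time `duration` is always
#'   included.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method \pkg{deSolve} method name (default `"lsoda"`).
#' @return A `moth_trajectory`: data frame with columns `t`, `x`, `y`,
#'   `theta`, `phi`, `xdot`, `ydot`, `thetadot`, `phidot`.
#' @examples
#' traj <- simulate_segment(moth_state(), moth_controls(F = 0.02),
#'                          body_params())
#' final_state(traj)
#' @export
simulate_segment <- function(state0, controls, params, duration = 0.02,
                             dt = 1e-3, rtol = 1e-8, atol = 1e-10,
                             method = "lsoda") {
  check_state(state0)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive")
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  pvec <- as_param_vector(params)
  u <- as.numeric(controls)
  if (u[1] < 0) stop("force magnitude F must be non-negative")
  rhs <- function(t, y, parms) list(.moth_rhs_cpp(y, u, parms))
  out <- deSolve::ode(y = as.numeric(state0), times = times, func = rhs,
                      parms = pvec, method = method,
                      rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("t", state_names)
  if (nrow(out) < length(times) || !all(is.finite(as.matrix(out)))) {
    bad <- out[nrow(out), ]
    stop(errorCondition(
      sprintf("integrator failed at t = %g", bad$t),
      failing_state = bad, class = "mothprune_integration_error"))
  }
  class(out) <- c("moth_trajectory", "data.frame")
  out
}

#' Final state of a trajectory
#' @param traj A `moth_trajectory`.
#' @return Named state vector (length 8).
#' @export
final_state <- function(traj) {
  s <- as.numeric(traj[nrow(traj), state_names])
  names(s) <- state_names
  s
}

segment_kinematics <- function(state, params) {
  a <- params$L1 / 2
  b <- params$L2 / 2
  th <- state[["theta"]]; ph <- state[["phi"]]
  list(
    r1 = c(state[["x"]] + a * cos(th), state[["y"]] + a * sin(th)),
    r2 = c(state[["x"]] - b * cos(ph), state[["y"]] - b * sin(ph)),
    v1 = c(state[["xdot"]] - a * sin(th) * state[["thetadot"]],
           state[["ydot"]] + a * cos(th) * state[["thetadot"]]),
    v2 = c(state[["xdot"]] + b * sin(ph) * state[["phidot"]],
           state[["ydot"]] - b * cos(ph) * state[["phidot"]]))
}

#' Mechanical energy of the body
#'
#' Kinetic (translational and rotational, both segments) plus gravitational
#' potential (relative to `y = 0`) plus torsional spring potential
#' `K ((phi - theta) - beta0)^2 / 2`. In the conservative limit (no thrust,
#' no drag, no joint damping) this quantity is conserved along trajectories,
#' which the test suite uses as an integration oracle.
#'
#' @inheritParams state_derivative
#' @return Energy in joules.
#' @export
mechanical_energy <- function(state, params) {
  check_state(state)
  k <- segment_kinematics(state, params)
  kin <- 0.5 * params$m1 * sum(k$v1^2) +
    0.5 * params$I1 * state[["thetadot"]]^2 +
    0.5 * params$m2 * sum(k$v2^2) +
    0.5 * params$I2 * state[["phidot"]]^2
  pot <- params$g * (params$m1 * k$r1[2] + params$m2 * k$r2[2]) +
    0.5 * params$K * ((state[["phi"]] - state[["theta"]]) - params$beta0)^2
  kin + pot
}

#' Centre of mass position and velocity
#'
#' Mass-weighted average of the two segment centroids and their velocities.
#'
#' @inheritParams state_derivative
#' @return Named vector `(com_x, com_y, com_xdot, com_ydot)`.
#' @export
com_state <- function(state, params) {
  check_state(state)
  k <- segment_kinematics(state, params)
  mt <- params$m1 + params$m2
  c(com_x = (params$m1 * k$r1[1] + params$m2 * k$r2[1]) / mt,
    com_y = (params$m1 * k$r1[2] + params$m2 * k$r2[2]) / mt,
    com_xdot = (params$m1 * k$v1[1] + params$m2 * k$v2[1]) / mt,
    com_ydot = (params$m1 * k$v1[2] + params$m2 * k$v2[2]) / mt)
}

#' Total linear momentum of the body
#' @inheritParams state_derivative
#' @return Named vector `(px, py)` (kg m / s).
#' @export
linear_momentum <- function(state, params) {
  k <- segment_kinematics(state, params)
  c(px = params$m1 * k$v1[1] + params$m2 * k$v2[1],
    py = params$m1 * k$v1[2] + params$m2 * k$v2[2])
}

#' Write a trajectory to CSV
#' @param traj A `moth_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Plot a simulated stroke
#'
#' Draws the joint path with body-segment renderings at regular intervals:
#' the head-thorax and abdomen axes as line segments, segment centroids as
#' black dots and the joint in red.
#'
#' @param traj A `moth_trajectory`.
#' @param params The [body_params()] used to simulate it.
#' @param every Draw the body at every `every`-th time point.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_trajectory <- function(traj, params, every = 5, ...) {
  graphics::plot(traj$x, traj$y, type = "l", col = "red", lty = 3,
                 xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  idx <- unique(c(seq(1, nrow(traj), by = every), nrow(traj)))
  for (i in idx) {
    s <- as.numeric(traj[i, state_names])
    names(s) <- state_names
    a <- params$L1 / 2; b <- params$L2 / 2
    tip1 <- c(s[["x"]] + params$L1 * cos(s[["theta"]]),
              s[["y"]] + params$L1 * sin(s[["theta"]]))
    tip2 <- c(s[["x"]] - params$L2 * cos(s[["phi"]]),
              s[["y"]] - params$L2 * sin(s[["phi"]]))
    graphics::segments(s[["x"]], s[["y"]], tip1[1], tip1[2], col = "grey30")
    graphics::segments(s[["x"]], s[["y"]], tip2[1], tip2[2], col = "grey60")
    k <- segment_kinematics(s, params)
    graphics::points(c(k$r1[1], k$r2[1]), c(k$r1[2], k$r2[2]),
                     pch = 16, cex = 0.5)
    graphics::points(s[["x"]], s[["y"]], pch = 16, cex = 0.4, col = "red")
  }
  invisible(traj)
}
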