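# shared fixtures, all generated in code

# randomized but physically valid body parameters for property tests
rand_body <- function(seed, ...) {
  set.seed(seed)
  args <- list(m1 = runif(1, 5e-4, 3e-3), m2 = runif(1, 5e-4, 3e-3),
               L1 = runif(1, 0.01, 0.04), L2 = runif(1, 0.01, 0.04),
               I1 = runif(1, 1e-8, 1e-7), I2 = runif(1, 1e-8, 1e-7),
               K = runif(1, 0, 2e-3), C = runif(1, 0, 2e-5),
               beta0 = runif(1, -0.3, 0.3),
               cd1 = runif(1, 0, 1e-2), cd2 = runif(1, 0, 1e-2))
  do.call(body_params, utils::modifyList(args, list(...)))
}

rand_state <- function(seed) {
  set.seed(seed)
  moth_state(x = runif(1, -0.01, 0.01), y = runif(1, -0.01, 0.01),
             theta = runif(1, 0, 2 * pi), phi = runif(1, 0, 2 * pi),
             xdot = runif(1, -0.5, 0.5), ydot = runif(1, -0.5, 0.5),
             thetadot = runif(1, -5, 5), phidot = runif(1, -5, 5))
}

rand_controls <- function(seed) {
  set.seed(seed)
  moth_controls(F = runif(1, 0, 0.05), alpha = runif(1, -pi, pi),
                tau = runif(1, -5e-4, 5e-4))
}

# centroid accelerations from a state + its derivative, for momentum oracles
segment_accels <- function(state, deriv, params) {
  a <- params$L1 / 2; b <- params$L2 / 2
  th <- state[["theta"]]; ph <- state[["phi"]]
  thd <- state[["thetadot"]]; phd <- state[["phidot"]]
  thdd <- deriv[["thetaddot"]]; phdd <- deriv[["phiddot"]]
  list(a1 = c(deriv[["xddot"]] - a * (sin(th) * thdd + cos(th) * thd^2),
              deriv[["yddot"]] + a * (cos(th) * thdd - sin(th) * thd^2)),
       a2 = c(deriv[["xddot"]] + b * (sin(ph) * phdd + cos(ph) * phd^2),
              deriv[["yddot"]] - b * (cos(ph) * phdd - sin(ph) * phd^2)))
}

# total external force on the body (thrust + gravity + drag)
external_force <- function(state, controls, params) {
  k <- mothprune:::segment_kinematics(state, params)
  drag <- function(v, cd) {
    if (params$drag == "quadratic") -cd * sqrt(sum(v^2)) * v else -cd * v
  }
  f <- controls[["F"]] * c(cos(state[["theta"]] + controls[["alpha"]]),
                           sin(state[["theta"]] + controls[["alpha"]]))
  f + drag(k$v1, params$cd1) + drag(k$v2, params$cd2) +
    c(0, -(params$m1 + params$m2) * params$g)
}

state_from_traj_row <- function(traj, i) {
  s <- as.numeric(traj[i, c("x", "y", "theta", "phi",
                            "xdot", "ydot", "thetadot", "phidot")])
  names(s) <- c("x", "y", "theta", "phi",
                "xdot", "ydot", "thetadot", "phidot")
  s
}

# small scaled training set shared by network/pruning tests
make_scaled <- function(n, seed, arch_widths = NULL) {
  ds <- generate_dataset(n, seed = seed)
  sc <- fit_scaler(ds)
  list(ds = ds, scaler = sc,
       data = list(inputs = apply_scaler(ds$inputs, sc, "input"),
                   targets = apply_scaler(ds$targets, sc, "target")))
}

# a network with hand-set weights (bypasses init) for frozen examples
hand_net <- function(widths, weights, biases = NULL) {
  arch <- moth_arch(widths)
  L <- length(widths) - 1
  if (is.null(biases))
    biases <- lapply(seq_len(L), function(l) numeric(widths[l + 1]))
  structure(list(arch = arch, weights = weights, biases = biases),
            class = "moth_net")
}
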