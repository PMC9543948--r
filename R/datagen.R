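#' Sampling ranges for initial conditions and controls
#'
#' Inclusive lower/upper bounds for the uniformly sampled initial state
#' variables and controls. Every simulated stroke starts at the origin, so
#' `x0 = y0 = 0` always and only velocities, angles, angular rates and the
#' three controls are sampled.
#'
#' The defaults are hawkmoth-scale stand-ins: translational velocities within
#' half a metre per second, body angles within a quadrant around vertical,
#' angular rates within 5 rad/s, thrust up to about twice body weight, thrust
#' vectoring within 45 degrees of the body midline, and abdominal torques
#' comparable to the joint spring torque at moderate flexion. All datagen
#' tests are range-independent.
#'
#' @param xdot0,ydot0 Initial joint velocity bounds (m/s).
#' @param theta0,phi0 Initial segment angle bounds (rad).
#' @param thetadot0,phidot0 Initial angular velocity bounds (rad/s).
#' @param F Wing force magnitude bounds (N); lower bound must be >= 0.
#' @param alpha Thrust direction bounds (rad, relative to the midline).
#' @param tau Abdominal torque bounds (N m).
#' @return An object of class `moth_ranges`.
#' @export
sample_ranges <- function(xdot0 = c(-0.5, 0.5), ydot0 = c(-0.5, 0.5),
                          theta0 = c(pi / 4, 3 * pi / 4),
                          phi0 = c(pi / 4, 3 * pi / 4),
                          thetadot0 = c(-5, 5), phidot0 = c(-5, 5),
                          F = c(0, 0.045),
                          alpha = c(-pi / 4, pi / 4),
                          tau = c(-5e-4, 5e-4)) {
  r <- list(xdot0 = xdot0, ydot0 = ydot0, theta0 = theta0, phi0 = phi0,
            thetadot0 = thetadot0, phidot0 = phidot0,
            F = F, alpha = alpha, tau = tau)
  for (nm in names(r)) {
    b <- r[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      stop(sprintf("range '%s' must be a finite pair with lower <= upper",
                   nm))
  }
  if (r$F[1] < 0) stop("lower bound of F must be non-negative")
  structure(r, class = "moth_ranges")
}

#' Sample random initial conditions and controls
#'
#' Draws `n` independent uniform samples per variable (in the fixed order
#' `xdot0, ydot0, theta0, phi0, thetadot0, phidot0, F, alpha, tau`), with
#' `x = y = 0` in every initial state. Reproducible under the seed.
#'
#' @param n Number of samples (>= 1).
#' @param ranges A [sample_ranges()] object.
#' @param seed Integer RNG seed.
#' @return List with `states` (`n x 8` matrix, columns as [moth_state()])
#'   and `controls` (`n x 3` matrix `F, alpha, tau`).
#' @export
sample_conditions <- function(n, ranges = sample_ranges(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  stopifnot(inherits(ranges, "moth_ranges"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(b) stats::runif(n, b[1], b[2])
  d <- lapply(ranges, draw)
  states <- cbind(x = 0, y = 0, theta = d$theta0, phi = d$phi0,
                  xdot = d$xdot0, ydot = d$ydot0,
                  thetadot = d$thetadot0, phidot = d$phidot0)
  controls <- cbind(F = d$F, alpha = d$alpha, tau = d$tau)
  list(states = states, controls = controls)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Convert polar controls to Cartesian force components
#'
#' `Fx = F cos(alpha)`, `Fy = F sin(alpha)`. The network is trained on the
#' Cartesian components rather than the polar pair.
#'
#' @param F Force magnitudes (N), `>= 0`.
#' @param alpha Thrust directions (rad).
#' @return Matrix with columns `Fx`, `Fy`.
#' @export
controls_to_cartesian <- function(F, alpha) {
  if (any(!is.finite(F)) || any(F < 0))
    stop("F must be finite and non-negative")
  cbind(Fx = F * cos(alpha), Fy = F * sin(alpha))
}

#' Recover polar controls from Cartesian force components
#' @param Fx,Fy Force components (N).
#' @return Matrix with columns `F`, `alpha` (`alpha` in `(-pi, pi]`).
#' @export
cartesian_to_controls <- function(Fx, Fy) {
  cbind(F = sqrt(Fx^2 + Fy^2), alpha = atan2(Fy, Fx))
}

dataset_input_names <- c("xdot_i", "ydot_i", "phi_i", "theta_i",
                         "phidot_i", "thetadot_i",
                         "x_f", "y_f", "phi_f", "theta_f")
dataset_target_names <- c("Fx", "Fy", "tau",
                          "xdot_f", "ydot_f", "phidot_f", "thetadot_f")

# stable non-cryptographic polynomial hash of an R object over its deparse
object_hash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate an inverse-dynamics training dataset
#'
#' Samples `n` random initial conditions and controls, integrates one 20 ms
#' constant-control stroke for each, and assembles paired records: the
#' inputs are the initial velocities, angles and angular rates together with
#' the achieved final `(x, y, phi, theta)`; the targets are the Cartesian
#' force components, the abdominal torque, and the achieved final
#' derivatives. The network, not the dataset, inverts the mapping: the data
#' are produced by the forward model.
#'
#' Samples whose integration fails are dropped with a warning and replaced
#' by fresh draws so the record count is preserved.
#'
#' @param n Number of records.
#' @param ranges A [sample_ranges()] object.
#' @param params A [body_params()] object.
#' @param seed Integer seed; together with `ranges` and `params` it fully
#'   determines the dataset.
#' @param duration Stroke duration (s).
#' @param rtol,atol Integration tolerances.
#' @return An object of class `moth_dataset`: list with `inputs` (`n x 10`),
#'   `targets` (`n x 7`) and `meta`.
#' @examples
#' ds <- generate_dataset(50, seed = 1)
#' dim(ds$inputs)
#' @export
generate_dataset <- function(n, ranges = sample_ranges(),
                             params = body_params(), seed = 1L,
                             duration = 0.02, rtol = 1e-8, atol = 1e-10) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cond <- sample_conditions(n, ranges, seed)
  pvec <- as_param_vector(params)
  res <- .integrate_segments_cpp(cond$states, cond$controls, pvec,
                                 duration, rtol, atol)
  states <- cond$states
  controls <- cond$controls
  finals <- res$final
  ok <- res$ok
  tries <- 0L
  while (any(!ok) && tries < 20L) {
    tries <- tries + 1L
    bad <- which(!ok)
    warning(sprintf("%d segment(s) failed to integrate; redrawing", length(bad)))
    repl <- sample_conditions(length(bad), ranges, seed + 100003L * tries)
    r2 <- .integrate_segments_cpp(repl$states, repl$controls, pvec,
                                  duration, rtol, atol)
    states[bad, ] <- repl$states
    controls[bad, ] <- repl$controls
    finals[bad, ] <- r2$final
    ok[bad] <- r2$ok
  }
  if (any(!ok)) stop("could not integrate all samples after redraws")

  fxy <- controls_to_cartesian(controls[, "F"], controls[, "alpha"])
  inputs <- cbind(states[, "xdot"], states[, "ydot"],
                  states[, "phi"], states[, "theta"],
                  states[, "phidot"], states[, "thetadot"],
                  finals[, 1], finals[, 2], finals[, 4], finals[, 3])
  colnames(inputs) <- dataset_input_names
  targets <- cbind(fxy[, "Fx"], fxy[, "Fy"], controls[, "tau"],
                   finals[, 5], finals[, 6], finals[, 8], finals[, 7])
  colnames(targets) <- dataset_target_names
  structure(list(
    inputs = inputs, targets = targets,
    meta = list(n = n, seed = as.integer(seed), duration = duration,
                rtol = rtol, atol = atol,
                ranges = unclass(ranges),
                params = unclass(params),
                params_hash = object_hash(unclass(params)))),
    class = "moth_dataset")
}

#' @export
print.moth_dataset <- function(x, ...) {
  cat(sprintf("moth_dataset: %d records (seed %d, body hash %s)\n",
              nrow(x$inputs), x$meta$seed, x$meta$params_hash))
  invisible(x)
}

#' Fit a min-max scaler on the training split
#'
#' Stores per-feature minima and maxima of the training inputs and targets
#' separately. [apply_scaler()] then maps the training minimum to -0.5 and
#' the training maximum to +0.5; values outside the training range
#' (e.g. in validation or test data) map outside that interval, which is
#' allowed. Constant features (min = max) map to 0.
#'
#' @param inputs Training input matrix, or a `moth_dataset` (in which case
#'   `targets` is ignored).
#' @param targets Training target matrix.
#' @return An object of class `moth_scaler`.
#' @export
fit_scaler <- function(inputs, targets = NULL) {
  if (inherits(inputs, "moth_dataset")) {
    targets <- inputs$targets
    inputs <- inputs$inputs
  }
  if (is.null(dim(inputs)) || is.null(dim(targets)))
    stop("inputs and targets must be matrices")
  if (nrow(inputs) < 2) stop("need at least 2 records to fit a scaler")
  structure(list(
    input = list(min = apply(inputs, 2, min), max = apply(inputs, 2, max)),
    target = list(min = apply(targets, 2, min), max = apply(targets, 2, max))),
    class = "moth_scaler")
}

scaler_half <- function(scaler, which) {
  stopifnot(inherits(scaler, "moth_scaler"))
  scaler[[match.arg(which, c("input", "target"))]]
}

#' Apply the min-max scaling `x' = (x - min) / (max - min) - 0.5`
#'
#' @param values Matrix (or vector treated as one row) of unscaled values.
#' @param scaler A [fit_scaler()] object.
#' @param which `"input"` or `"target"`: which feature block to scale.
#' @return Scaled values, same shape.
#' @export
apply_scaler <- function(values, scaler, which = "input") {
  h <- scaler_half(scaler, which)
  v <- if (is.null(dim(values))) matrix(values, nrow = 1) else values
  if (ncol(v) != length(h$min))
    stop("feature dimensionality does not match the scaler")
  span <- h$max - h$min
  out <- sweep(v, 2, h$min)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/") - 0.5
  out[, span == 0] <- 0
  if (is.null(dim(values))) out[1, ] else out
}

#' Invert the min-max scaling
#' @inheritParams apply_scaler
#' @param scaled Matrix (or vector) of scaled values.
#' @return Unscaled values, same shape.
#' @export
invert_scaler <- function(scaled, scaler, which = "input") {
  h <- scaler_half(scaler, which)
  v <- if (is.null(dim(scaled))) matrix(scaled, nrow = 1) else scaled
  if (ncol(v) != length(h$min))
    stop("feature dimensionality does not match the scaler")
  span <- h$max - h$min
  out <- sweep(sweep(v + 0.5, 2, ifelse(span > 0, span, 0), "*"), 2,
               h$min, "+")
  if (is.null(dim(scaled))) out[1, ] else out
}

#' Split a dataset into training and validation parts
#'
#' Seeded random disjoint partition with `floor(fraction * n)` training
#' records and the remainder for validation (the conventional 80:20 split by
#' default).
#'
#' @param dataset A `moth_dataset`.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `validation`, each a
#'   `moth_dataset`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "moth_dataset"))
  n <- nrow(dataset$inputs)
  if (n < 2) stop("need at least 2 records to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- floor(fraction * n)
  take <- function(rows) {
    d <- dataset
    d$inputs <- dataset$inputs[rows, , drop = FALSE]
    d$targets <- dataset$targets[rows, , drop = FALSE]
    d$meta$n <- length(rows)
    d
  }
  list(train = take(sort(idx[seq_len(ntr)])),
       validation = take(sort(idx[(ntr + 1):n])))
}
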