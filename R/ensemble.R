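#' Monte Carlo ensemble configuration
#'
#' Describes a population of identically configured networks differing only
#' in the random initialization of their weights: network `k` is initialized
#' with seed `base_seed + k` (k = 0, ..., count - 1); its mini-batch
#' shuffling is seeded independently (offset by a large constant) so data
#' order and weight draws do not alias.
#'
#' @param n_networks Number of networks (>= 1). The full-scale analysis
#'   uses 1320; desk-scale defaults are small.
#' @param base_seed Base integer seed.
#' @param arch A [moth_arch()].
#' @param dense_config [train_config()] for the initial dense training.
#' @param prune_config [train_config()] for the retraining between prunes
#'   (defaults to `dense_config`).
#' @param schedule Sparsity schedule, see [prune_schedule()].
#' @param threshold Performance threshold defining the optimally sparse
#'   network (default 1e-3, chosen near the loss of a trained
#'   fully-connected network).
#' @param scope Mask-selection scope, see [select_mask()].
#' @return An object of class `moth_ensemble_config`.
#' @export
ensemble_config <- function(n_networks = 12L, base_seed = 1L,
                            arch = moth_arch(),
                            dense_config = train_config(),
                            prune_config = dense_config,
                            schedule = prune_schedule(),
                            threshold = 1e-3, scope = "global") {
  if (n_networks < 1) stop("n_networks must be >= 1")
  if (threshold <= 0) stop("threshold must be positive")
  check_schedule(schedule)
  structure(list(n_networks = as.integer(n_networks),
                 base_seed = as.integer(base_seed), arch = arch,
                 dense_config = dense_config, prune_config = prune_config,
                 schedule = schedule, threshold = threshold, scope = scope),
            class = "moth_ensemble_config")
}

SHUFFLE_SEED_OFFSET <- 100000L

#' Train and prune a Monte Carlo ensemble of networks
#'
#' For each network: seeded initialization, dense training to the
#' early-stopping minimum, then a sequential masked pruning run over the
#' schedule. Networks are independent, so the result is invariant to
#' execution order; an individual failure is logged, marked, and excluded
#' from summaries.
#'
#' @param config An [ensemble_config()].
#' @param data Scaled training data.
#' @param val Optional scaled validation data (monitored when present).
#' @param test Optional scaled held-out data; when supplied, per-sparsity
#'   losses are measured on it (otherwise the monitored loss is used).
#' @param verbose Print one progress line per network.
#' @return An object of class `moth_ensemble`: per-network seeds, pre-prune
#'   losses, per-sparsity losses, prune records, masks by level, and the
#'   schedule/threshold used.
#' @export
run_ensemble <- function(config, data, val = NULL, test = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "moth_ensemble_config"))
  nets <- vector("list", config$n_networks)
  for (k in seq_len(config$n_networks) - 1L) {
    seed <- config$base_seed + k
    nets[[k + 1L]] <- tryCatch({
      net <- init_params(config$arch, seed)
      dcfg <- config$dense_config
      dcfg$seed <- seed + SHUFFLE_SEED_OFFSET
      dres <- train(net, data, dcfg, val = val)
      pre_loss <- if (!is.null(test)) evaluate(dres$net, test)
                  else dres$best_loss
      pcfg <- config$prune_config
      pcfg$seed <- seed + 2L * SHUFFLE_SEED_OFFSET
      prun <- masked_prune_run(dres$net, data, config$schedule, pcfg,
                               val = val, scope = config$scope,
                               eval_data = test)
      losses <- if (!is.null(test)) prun$records$loss_eval
                else prun$records$loss
      names(losses) <- as.character(config$schedule)
      if (verbose)
        message(sprintf("network seed %d: pre-prune %.3g, final %.3g",
                        seed, pre_loss, losses[length(losses)]))
      list(seed = seed, failed = FALSE, pre_loss = pre_loss,
           losses = losses, records = prun$records,
           masks_by_level = prun$masks_by_level, net = prun$net)
    }, error = function(e) {
      message(sprintf("network seed %d failed: %s", seed,
                      conditionMessage(e)))
      list(seed = seed, failed = TRUE, error = conditionMessage(e))
    })
  }
  structure(list(networks = nets, schedule = config$schedule,
                 threshold = config$threshold, arch = config$arch,
                 base_seed = config$base_seed),
            class = "moth_ensemble")
}

#' Optimal sparsity under a loss threshold
#'
#' The largest schedule sparsity whose post-retraining loss is below the
#' threshold -- the sparsest network that still performs. `NA` when no level
#' qualifies (some networks never perform below the threshold).
#'
#' @param losses Named numeric vector: post-retraining loss per schedule
#'   sparsity (names are the sparsity fractions).
#' @param threshold Positive loss threshold.
#' @return The optimal sparsity (numeric) or `NA_real_`.
#' @examples
#' optimal_sparsity(c(`0.85` = 8e-4, `0.93` = 9.5e-4, `0.94` = 5e-3), 1e-3)
#' @export
optimal_sparsity <- function(losses, threshold) {
  if (length(losses) == 0) stop("empty loss mapping")
  s <- as.numeric(names(losses))
  ok <- which(is.finite(losses) & losses < threshold)
  if (length(ok) == 0) return(NA_real_)
  max(s[ok])
}

#' Per-layer remaining-connection table for a mask set
#'
#' @param masks Binary mask list.
#' @return Data frame with columns `layer`, `remaining`, `size`,
#'   `fraction`.
#' @export
layer_sparsity_table <- function(masks) {
  data.frame(layer = seq_along(masks),
             remaining = vapply(masks, sum, 0),
             size = vapply(masks, length, 0),
             fraction = vapply(masks, mean, 0))
}

#' Aggregate per-layer sparsity across an ensemble
#'
#' Mean and variance of the per-layer remaining-connection counts across all
#' non-failed networks, at the queried schedule sparsity.
#'
#' @param result A `moth_ensemble`.
#' @param sparsity A schedule sparsity level.
#' @return Data frame with `layer`, `mean_remaining`, `var_remaining`,
#'   `size` and `mean_fraction`.
#' @export
aggregate_layer_sparsity <- function(result, sparsity) {
  key <- as.character(sparsity)
  tabs <- lapply(Filter(function(n) !n$failed, result$networks), function(n) {
    m <- n$masks_by_level[[key]]
    if (is.null(m)) stop("sparsity level not in the schedule")
    layer_sparsity_table(m)
  })
  rem <- sapply(tabs, function(t) t$remaining)
  if (is.null(dim(rem))) rem <- matrix(rem, nrow = 1)
  data.frame(layer = tabs[[1]]$layer,
             mean_remaining = rowMeans(rem),
             var_remaining = apply(rem, 1, stats::var),
             size = tabs[[1]]$size,
             mean_fraction = rowMeans(rem) / tabs[[1]]$size)
}

#' Remaining input connections in the first layer
#'
#' For each input variable, the number of surviving connections into the
#' first hidden layer (non-zero entries in its column of the layer-1 mask).
#' A count of zero means that input has been pruned entirely from the
#' network and has no influence on its output.
#'
#' @param mask1 The layer-1 binary mask (`hidden1 x inputs`).
#' @param input_names Optional column names for the inputs.
#' @return Named integer vector of per-input counts.
#' @export
input_connectivity <- function(mask1,
                               input_names = dataset_input_names) {
  counts <- colSums(mask1 != 0)
  if (!is.null(input_names) && length(input_names) == length(counts))
    names(counts) <- input_names
  counts
}

#' Aggregate input connectivity across an ensemble
#'
#' @inheritParams aggregate_layer_sparsity
#' @return Matrix: one row per non-failed network, one column per input.
#' @export
aggregate_input_connectivity <- function(result, sparsity) {
  key <- as.character(sparsity)
  rows <- lapply(Filter(function(n) !n$failed, result$networks), function(n)
    input_connectivity(n$masks_by_level[[key]][[1]]))
  do.call(rbind, rows)
}

#' Breakdown summary of an ensemble
#'
#' Per-sparsity box-plot statistics of the losses across networks, the
#' histogram of optimal sparsities (the number of networks that make it to
#' each level before exceeding the threshold), and the counts of networks
#' that never perform below the threshold or failed outright. The three
#' categories plus the histogram mass conserve the ensemble size.
#'
#' @param result A `moth_ensemble`.
#' @param threshold Loss threshold; defaults to the ensemble's.
#' @return List with `loss_stats` (per sparsity: quartiles, median,
#'   whiskers, outlier count), `optimal_counts`, `pre_prune_losses`,
#'   `n_never`, `n_failed` and `n_total`.
#' @export
breakdown_summary <- function(result, threshold = result$threshold) {
  stopifnot(inherits(result, "moth_ensemble"))
  ok <- Filter(function(n) !n$failed, result$networks)
  if (length(ok) == 0) stop("no successfully trained networks")
  n_failed <- sum(vapply(result$networks, function(n) n$failed, TRUE))
  loss_mat <- sapply(ok, function(n) n$losses)
  if (is.null(dim(loss_mat))) loss_mat <- matrix(loss_mat, nrow = 1)
  stats_one <- function(v) {
    bs <- grDevices::boxplot.stats(v)
    c(lower_whisker = bs$stats[1], q1 = bs$stats[2], median = bs$stats[3],
      q3 = bs$stats[4], upper_whisker = bs$stats[5],
      n_outliers = length(bs$out))
  }
  loss_stats <- data.frame(sparsity = result$schedule,
                           t(apply(loss_mat, 1, stats_one)))
  opt <- vapply(ok, function(n) optimal_sparsity(n$losses, threshold), 0)
  counts <- table(factor(opt[!is.na(opt)],
                         levels = as.character(result$schedule)))
  list(loss_stats = loss_stats,
       optimal_counts = as.data.frame(counts,
                                      responseName = "n_networks",
                                      stringsAsFactors = FALSE),
       optimal_sparsities = opt,
       pre_prune_losses = vapply(ok, function(n) n$pre_loss, 0),
       n_never = sum(is.na(opt)), n_failed = n_failed,
       n_total = length(result$networks))
}

#' Per-output residual statistics in unscaled units
#'
#' Residuals are `actual - prediction` per output, reported after inverting
#' the target scaler so the statistics carry physical units.
#'
#' @param net A trained `moth_net`.
#' @param data Scaled evaluation data.
#' @param scaler The [fit_scaler()] used to scale the data.
#' @param masks Optional binary masks.
#' @return Data frame with one row per output: mean, sd, median, min, max.
#' @export
residual_summary <- function(net, data, scaler, masks = NULL) {
  d <- as_data_pair(data)
  pred <- invert_scaler(forward(net, d$inputs, masks), scaler, "target")
  act <- invert_scaler(d$targets, scaler, "target")
  res <- act - pred
  data.frame(output = colnames(act) %||% paste0("y", seq_len(ncol(act))),
             mean = colMeans(res),
             sd = apply(res, 2, stats::sd),
             median = apply(res, 2, stats::median),
             min = apply(res, 2, min),
             max = apply(res, 2, max),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-loop rollout error of a learned controller
#'
#' For each test record: the network predicts the (scaled) controls linking
#' the record's initial state to its requested final state; the prediction
#' is unscaled, `(Fx, Fy)` is converted back to `(F, alpha)`, one 20 ms
#' stroke is simulated from the initial state with those controls, and the
#' Euclidean distance between the achieved and requested final
#' `(x, y, theta, phi)` is reported. With `use_true_controls = TRUE` the
#' dataset's own targets are used instead, which checks the data pipeline at
#' integrator-tolerance level.
#'
#' @param net A trained `moth_net` (ignored when `use_true_controls`).
#' @param dataset An unscaled `moth_dataset` providing the test cases.
#' @param scaler The [fit_scaler()] fitted on the training split.
#' @param params The [body_params()] the dataset was generated with.
#' @param masks Optional binary masks.
#' @param use_true_controls Use the dataset's stored targets as controls.
#' @param duration,rtol,atol Simulation settings.
#' @return List with `errors` (per-case distances), `failed` (count of
#'   simulation failures, excluded) and `summary` (median, mean, max).
#'   Zero-length input yields empty statistics without failure.
#' @export
rollout_error <- function(net, dataset, scaler, params = body_params(),
                          masks = NULL, use_true_controls = FALSE,
                          duration = 0.02, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(dataset, "moth_dataset"))
  ins <- dataset$inputs
  n <- nrow(ins)
  if (n == 0)
    return(list(errors = numeric(0), failed = 0L,
                summary = c(median = NA_real_, mean = NA_real_,
                            max = NA_real_)))
  if (use_true_controls) {
    tg <- dataset$targets
  } else {
    sc_in <- apply_scaler(ins, scaler, "input")
    tg <- invert_scaler(forward(net, sc_in, masks), scaler, "target")
    colnames(tg) <- dataset_target_names
  }
  pol <- cartesian_to_controls(tg[, "Fx"], tg[, "Fy"])
  controls <- cbind(F = pol[, "F"], alpha = pol[, "alpha"],
                    tau = tg[, "tau"])
  states0 <- cbind(x = 0, y = 0,
                   theta = ins[, "theta_i"], phi = ins[, "phi_i"],
                   xdot = ins[, "xdot_i"], ydot = ins[, "ydot_i"],
                   thetadot = ins[, "thetadot_i"],
                   phidot = ins[, "phidot_i"])
  res <- .integrate_segments_cpp(states0, controls, as_param_vector(params),
                                 duration, rtol, atol)
  ach <- res$final
  want <- ins[, c("x_f", "y_f", "theta_f", "phi_f"), drop = FALSE]
  got <- ach[, c(1, 2, 3, 4), drop = FALSE]
  err <- sqrt(rowSums((got - want[, c("x_f", "y_f", "theta_f", "phi_f"),
                                  drop = FALSE])^2))
  keep <- res$ok
  errors <- err[keep]
  list(errors = errors, failed = sum(!keep),
       summary = c(median = stats::median(errors), mean = mean(errors),
                   max = if (length(errors)) max(errors) else NA_real_))
}

#' Plot ensemble breakdown (losses per sparsity with optimal-count bars)
#'
#' @param summary A [breakdown_summary()] result.
#' @param threshold Threshold to draw as a dashed line.
#' @export
plot_breakdown <- function(summary, threshold = NULL) {
  ls <- summary$loss_stats
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  cnt <- summary$optimal_counts
  graphics::barplot(cnt$n_networks, names.arg = cnt$Var1,
                    ylab = "optimally sparse")
  graphics::plot(ls$sparsity, ls$median, log = "y", type = "b", pch = 16,
                 xlab = "sparsity", ylab = "loss",
                 ylim = range(c(ls$lower_whisker, ls$upper_whisker)))
  graphics::arrows(ls$sparsity, ls$q1, ls$sparsity, ls$q3, angle = 90,
                   code = 3, length = 0.02)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(summary)
}

#' Plot a pruning learning curve with sparsity markers
#'
#' @param records A `masked_prune_run()` records data frame.
#' @param threshold Optional threshold line.
#' @export
plot_prune_curve <- function(records, threshold = NULL) {
  graphics::plot(records$sparsity, records$loss, log = "y", type = "b",
                 pch = 16, xlab = "sparsity", ylab = "post-retraining loss")
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(records)
}

#' Plot per-input connectivity distributions across an ensemble
#'
#' @param conn Matrix from [aggregate_input_connectivity()].
#' @export
plot_input_connectivity <- function(conn) {
  graphics::boxplot(as.data.frame(conn), las = 2,
                    ylab = "connections into hidden layer 1")
  invisible(conn)
}
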