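#' Number of weights remaining at a sparsity level
#'
#' Convention: `remaining = floor((1 - s) * N)`; the pruned count is
#' `N - remaining`. This floor convention reproduces the published remaining
#' counts at both ends of the architecture sweep (23,135 of 330,512 at 93%
#' and 2,084 of 5,956 at 65%).
#'
#' @param N Total kernel weight count (>= 0).
#' @param s Sparsity fraction(s) in `[0, 1)`.
#' @return Integer vector of remaining counts.
#' @examples
#' remaining_count(330512, 0.93)
#' @export
remaining_count <- function(N, s) {
  if (any(N < 0)) stop("N must be non-negative")
  if (any(s < 0 | s >= 1)) stop("sparsity must lie in [0, 1)")
  as.integer(floor((1 - s) * N))
}

#' Default sequential-pruning schedule
#'
#' Strictly increasing sparsity fractions, stepping coarsely to 80% and
#' finely beyond 90% where the breakdown analyses discriminate between
#' adjacent levels.
#'
#' @return Numeric vector of sparsity fractions.
#' @export
prune_schedule <- function() {
  c(0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.80, 0.85, 0.90,
    0.91, 0.92, 0.93, 0.94, 0.95, 0.96, 0.97, 0.98)
}

check_schedule <- function(schedule) {
  if (length(schedule) < 1 || any(schedule < 0 | schedule >= 1))
    stop("schedule entries must lie in [0, 1)")
  if (any(diff(schedule) <= 0))
    stop("schedule must be strictly increasing")
  schedule
}

#' Fraction of kernel entries masked out
#' @param masks Binary mask list.
#' @return `1 - ones / total` over all kernel entries.
#' @export
achieved_sparsity <- function(masks) {
  ones <- sum(vapply(masks, sum, 0))
  total <- sum(vapply(masks, length, 0))
  1 - ones / total
}

#' Select a magnitude-based pruning mask
#'
#' Zeros exactly the `N - remaining_count(N, s)` smallest-magnitude kernel
#' entries. Entries already masked out in `current` count as magnitude zero
#' and are always re-selected, so masks are nested across an increasing
#' schedule. `scope = "global"` (default) ranks magnitudes across all layers
#' jointly; `scope = "per_layer"` applies the remaining-count convention
#' within each layer. Ties are broken deterministically by
#' (layer, row, column).
#'
#' @param net A `moth_net`.
#' @param s Target sparsity in `[0, 1)`; must not be smaller than the
#'   achieved sparsity of `current`.
#' @param scope `"global"` or `"per_layer"`.
#' @param current Optional existing mask list to nest within.
#' @return List of binary matrices congruent with the kernels.
#' @export
select_mask <- function(net, s, scope = c("global", "per_layer"),
                        current = NULL) {
  stopifnot(inherits(net, "moth_net"))
  scope <- match.arg(scope)
  if (s < 0 || s >= 1) stop("sparsity must lie in [0, 1)")
  if (!is.null(current)) {
    check_masks(net, current)
    if (s < achieved_sparsity(current) - 1e-12)
      stop("target sparsity is below the sparsity already achieved")
  }
  W <- net$weights
  masks <- lapply(W, function(w) matrix(1, nrow(w), ncol(w)))

  layer_entries <- function(l) {
    w <- W[[l]]
    mag <- abs(as.vector(w))
    if (!is.null(current)) mag[current[[l]] == 0] <- -1  # always re-pruned
    idx <- seq_along(mag)
    data.frame(mag = mag, layer = l,
               row = (idx - 1L) %% nrow(w) + 1L,
               col = (idx - 1L) %/% nrow(w) + 1L)
  }

  zero_entries <- function(ent, n_zero) {
    if (n_zero <= 0) return(NULL)
    ord <- order(ent$mag, ent$layer, ent$row, ent$col)[seq_len(n_zero)]
    ent[ord, c("layer", "row", "col")]
  }

  if (scope == "global") {
    ent <- do.call(rbind, lapply(seq_along(W), layer_entries))
    N <- nrow(ent)
    sel <- zero_entries(ent, N - remaining_count(N, s))
  } else {
    sel <- do.call(rbind, lapply(seq_along(W), function(l) {
      ent <- layer_entries(l)
      zero_entries(ent, nrow(ent) - remaining_count(nrow(ent), s))
    }))
  }
  if (!is.null(sel) && nrow(sel) > 0)
    for (l in unique(sel$layer)) {
      rows <- sel[sel$layer == l, ]
      masks[[l]][cbind(rows$row, rows$col)] <- 0
    }
  masks
}

#' Forward pass through a masked network
#'
#' Each kernel `A_i` is replaced by the Hadamard product `M_i * A_i`; biases
#' are never masked.
#'
#' @inheritParams forward
#' @param masks Binary mask list (required here).
#' @return Prediction matrix.
#' @export
masked_forward <- function(net, masks, x) {
  if (is.null(masks)) stop("masks are required; use forward() otherwise")
  forward(net, x, masks)
}

#' Hard-apply masks to a network's kernels
#' @param net A `moth_net`.
#' @param masks Binary mask list.
#' @return The network with `W_i <- M_i * W_i`.
#' @export
apply_masks <- function(net, masks) {
  check_masks(net, masks)
  net$weights <- Map(function(w, m) w * m, net$weights, masks)
  net
}

per_layer_nonzero <- function(weights) {
  vapply(weights, function(w) sum(w != 0), 0)
}

prune_record <- function(s, achieved, loss, batches, layer_remaining) {
  data.frame(sparsity = s, achieved = achieved, loss = loss,
             batches = batches,
             t(matrix(layer_remaining,
                      dimnames = list(paste0("layer", seq_along(layer_remaining)),
                                      NULL))))
}

#' Sequential manual pruning with fine-tuning
#'
#' For each sparsity level in the schedule: at every epoch the current
#' `n = N - remaining_count(N, s)` smallest-magnitude kernel weights are
#' re-zeroed and then one epoch of gradient steps is taken, repeating until
#' the early-stopping rule fires. Between zeroings, previously zeroed
#' weights may regrow -- this paradigm does not make pruning persistent,
#' which is exactly its documented limitation and the motivation for the
#' masked paradigm.
#'
#' @param net A trained `moth_net`.
#' @param data Training data (scaled).
#' @param schedule Strictly increasing sparsity fractions in `[0, 1)`.
#' @param config A [train_config()].
#' @param val Optional validation data.
#' @return List with `net` and `records` (one row per schedule step:
#'   target and achieved sparsity, post-retraining monitored loss, batch
#'   count and per-layer non-zero counts).
#' @export
manual_prune_run <- function(net, data, schedule = prune_schedule(),
                             config = train_config(), val = NULL) {
  check_schedule(schedule)
  N <- count_kernel_weights(net$arch)
  records <- NULL
  for (s in schedule) {
    n_zero <- N - remaining_count(N, s)
    res <- train(net, data, config, val = val, rezero_n = n_zero)
    net <- res$net
    nz <- per_layer_nonzero(net$weights)
    records <- rbind(records,
                     prune_record(s, 1 - sum(nz) / N, res$monitored_loss,
                                  res$batches, nz))
  }
  list(net = net, records = records)
}

#' Sequential masked pruning with fine-tuning
#'
#' For each sparsity level: a binary mask is selected by magnitude (nested
#' within the previous mask), the kernels are hard-zeroed, and the masked
#' network is retrained until the early-stopping rule fires. The masks are
#' non-trainable and bi-directional, so masked weights remain exactly zero
#' at all times after masking.
#'
#' @inheritParams manual_prune_run
#' @param scope Magnitude-ranking scope, `"global"` (default) or
#'   `"per_layer"`; see [select_mask()].
#' @param eval_data Optional held-out data; when supplied, each record also
#'   carries `loss_eval`, the post-retraining loss on this set.
#' @return List with `net`, `masks` (final), `masks_by_level` and `records`.
#' @export
masked_prune_run <- function(net, data, schedule = prune_schedule(),
                             config = train_config(), val = NULL,
                             scope = "global", eval_data = NULL) {
  check_schedule(schedule)
  N <- count_kernel_weights(net$arch)
  masks <- NULL
  records <- NULL
  masks_by_level <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    s <- schedule[i]
    masks <- select_mask(net, s, scope = scope, current = masks)
    net <- apply_masks(net, masks)
    res <- train(net, data, config, val = val, masks = masks)
    net <- res$net
    rec <- prune_record(s, achieved_sparsity(masks), res$monitored_loss,
                        res$batches, per_layer_nonzero(net$weights))
    if (!is.null(eval_data))
      rec$loss_eval <- evaluate(net, eval_data, masks)
    records <- rbind(records, rec)
    masks_by_level[[i]] <- masks
  }
  names(masks_by_level) <- as.character(schedule)
  list(net = net, masks = masks, masks_by_level = masks_by_level,
       records = records)
}
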