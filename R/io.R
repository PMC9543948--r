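#' Save a dataset as full-precision CSV with a JSON metadata sidecar
#'
#' Writes the paired input/target matrices as one CSV (17 significant
#' digits, lossless for doubles) and the generation metadata -- seed,
#' ranges, body parameters and their hash -- to `<path>.meta.json`, enough
#' to regenerate the dataset bit-identically.
#'
#' @param dataset A `moth_dataset`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "moth_dataset"))
  m <- cbind(dataset$inputs, dataset$targets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = ","), con)
  body <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  jsonlite::write_json(dataset$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dataset saved by [save_dataset()]
#' @param path CSV path (the `.meta.json` sidecar must sit next to it).
#' @return A `moth_dataset`.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  m <- as.matrix(utils::read.csv(path, colClasses = "numeric",
                                 check.names = FALSE))
  miss <- setdiff(c(dataset_input_names, dataset_target_names),
                  colnames(m))
  if (length(miss) > 0)
    stop("corrupt dataset: missing column(s) ", paste(miss, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(inputs = m[, dataset_input_names, drop = FALSE],
                 targets = m[, dataset_target_names, drop = FALSE],
                 meta = meta),
            class = "moth_dataset")
}

CHECKPOINT_VERSION <- 1L

#' Save a network checkpoint as JSON
#'
#' Stores the architecture, full-precision weights and biases, optional
#' masks, scaler parameters and training history, plus a format version and
#' a configuration hash that is verified on resume.
#'
#' @param net A `moth_net`.
#' @param path Output JSON path.
#' @param masks,scaler,history,config Optional components to persist.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, masks = NULL, scaler = NULL,
                            history = NULL, config = NULL) {
  stopifnot(inherits(net, "moth_net"))
  # kernels and masks flattened column-major; shapes recovered from widths
  obj <- list(format_version = CHECKPOINT_VERSION,
              widths = net$arch$widths,
              weights = lapply(net$weights, as.numeric),
              biases = lapply(net$biases, as.numeric),
              masks = if (!is.null(masks)) lapply(masks, as.numeric),
              scaler = if (!is.null(scaler)) unclass(scaler),
              history = history,
              config_hash = if (!is.null(config)) config_hash(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path JSON checkpoint path.
#' @param config Optional `moth_config`; when supplied its hash must match
#'   the stored one (resume safety).
#' @return List with `net`, `masks`, `scaler`, `history`.
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version > CHECKPOINT_VERSION)
    stop("unsupported checkpoint format version")
  if (!is.null(config)) {
    if (!identical(obj$config_hash, config_hash(config)))
      stop("checkpoint was produced under a different configuration ",
           "(config hash mismatch)")
  }
  widths <- as.integer(obj$widths)
  arch <- moth_arch(widths)
  fix <- function(x, l) {
    matrix(as.numeric(unlist(x)), nrow = widths[l + 1], ncol = widths[l])
  }
  L <- length(widths) - 1
  weights <- lapply(seq_len(L), function(l) fix(obj$weights[[l]], l))
  biases <- lapply(seq_len(L), function(l) as.numeric(obj$biases[[l]]))
  masks <- if (!is.null(obj$masks))
    lapply(seq_len(L), function(l) fix(obj$masks[[l]], l))
  scaler <- if (!is.null(obj$scaler)) {
    s <- obj$scaler
    structure(list(input = lapply(s$input, as.numeric),
                   target = lapply(s$target, as.numeric)),
              class = "moth_scaler")
  }
  net <- structure(list(arch = arch, weights = weights, biases = biases),
                   class = "moth_net")
  list(net = net, masks = masks, scaler = scaler, history = obj$history)
}

#' Export ensemble results to JSON and CSV tables
#'
#' Writes `summary.json` (breakdown summary: per-sparsity loss statistics,
#' optimal-sparsity counts, conservation counts), `losses.csv` (per-network
#' per-sparsity losses), and -- when a sparsity level is given --
#' `layer_sparsity.csv` and `input_connectivity.csv` for that level.
#'
#' @param result A `moth_ensemble`.
#' @param dir Output directory (created if needed).
#' @param at_sparsity Optional schedule level for the structural tables.
#' @return `dir`, invisibly.
#' @export
export_results <- function(result, dir, at_sparsity = NULL) {
  stopifnot(inherits(result, "moth_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- breakdown_summary(result)
  jsonlite::write_json(
    list(threshold = result$threshold, schedule = result$schedule,
         loss_stats = summ$loss_stats,
         optimal_counts = summ$optimal_counts,
         n_never = summ$n_never, n_failed = summ$n_failed,
         n_total = summ$n_total,
         median_pre_prune_loss = stats::median(summ$pre_prune_losses)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  ok <- Filter(function(n) !n$failed, result$networks)
  losses <- data.frame(seed = vapply(ok, function(n) n$seed, 0),
                       pre_prune = vapply(ok, function(n) n$pre_loss, 0),
                       t(sapply(ok, function(n) n$losses)),
                       check.names = FALSE)
  utils::write.csv(losses, file.path(dir, "losses.csv"), row.names = FALSE)
  if (!is.null(at_sparsity)) {
    utils::write.csv(aggregate_layer_sparsity(result, at_sparsity),
                     file.path(dir, "layer_sparsity.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregate_input_connectivity(result, at_sparsity),
                     file.path(dir, "input_connectivity.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
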