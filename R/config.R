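#' Default run configuration
#'
#' Nested configuration with every field defaulted: `body` (physical
#' parameters; `units: si` or `units: cgs` with explicit conversion),
#' `solver`, `ranges`, `dataset`, `architecture`, `training`, `pruning`,
#' `ensemble` and `output`. [load_config()] validates a YAML file against
#' this template: unknown keys are rejected and missing keys are filled from
#' the defaults.
#'
#' @return Nested named list (class `moth_config`).
#' @export
default_config <- function() {
  body <- unclass(body_params())
  structure(list(
    body = c(list(units = "si"), body[setdiff(names(body), "drag")],
             list(drag = body$drag)),
    solver = list(rtol = 1e-8, atol = 1e-10, dt = 1e-3, method = "lsoda"),
    ranges = lapply(unclass(sample_ranges()), as.numeric),
    dataset = list(n_train = 10000L, n_test = 2000L, seed = 1L,
                   test_seed = 90001L, split_fraction = 0.8,
                   split_seed = 7L),
    architecture = list(widths = c(10L, 400L, 400L, 400L, 16L, 7L)),
    training = list(optimizer = "adam", lr = 1e-3, batch_size = 128L,
                    max_epochs = 100L, min_delta = 1e-5, patience = 1000L,
                    eval_every = 100L, monitor_cap = 4096L, seed = 1L),
    pruning = list(schedule = prune_schedule(), scope = "global"),
    ensemble = list(n_networks = 12L, base_seed = 1L, threshold = 1e-3,
                    cluster_scale = FALSE),
    output = list(dir = "results")),
    class = "moth_config")
}

# multiplicative factors taking cgs-unit fields to SI
cgs_factors <- c(m1 = 1e-3, m2 = 1e-3,        # g -> kg
                 L1 = 1e-2, L2 = 1e-2, rF = 1e-2,  # cm -> m
                 I1 = 1e-7, I2 = 1e-7,        # g cm^2 -> kg m^2
                 K = 1e-7, C = 1e-7,          # dyn cm -> N m
                 cd1 = 1e-3, cd2 = 1e-3,      # dyn s / cm -> N s / m
                 g = 1e-2)                    # cm s^-2 -> m s^-2

merge_validate <- function(user, template, path = "") {
  if (!is.list(template)) return(user)
  extra <- setdiff(names(user), names(template))
  if (length(extra) > 0)
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  out <- template
  for (nm in names(user)) {
    out[[nm]] <- if (is.list(template[[nm]]))
      merge_validate(user[[nm]], template[[nm]],
                     paste0(path, nm, "$"))
    else user[[nm]]
  }
  out
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys raise a schema error naming the offending key; omitted keys
#' take their defaults. A `body` block with `units: cgs` is converted to SI
#' (masses g to kg, lengths cm to m, inertias g cm^2 to kg m^2, and so on)
#' before validation of the physical invariants.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `moth_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_validate(user, cfg)
    class(cfg) <- "moth_config"
  }
  if (identical(cfg$body$units, "cgs")) {
    for (nm in names(cgs_factors))
      cfg$body[[nm]] <- cfg$body[[nm]] * cgs_factors[[nm]]
    cfg$body$units <- "si"
  } else if (!identical(cfg$body$units, "si")) {
    stop("body$units must be 'si' or 'cgs'")
  }
  config_to_body(cfg)        # validates physical invariants
  config_to_ranges(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param config A `moth_config`.
#' @param path Output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname load_config
#' @param config A `moth_config`.
#' @export
config_to_body <- function(config) {
  b <- config$body
  do.call(body_params, b[setdiff(names(b), "units")])
}

#' @rdname load_config
#' @export
config_to_ranges <- function(config) {
  do.call(sample_ranges, lapply(config$ranges, as.numeric))
}

#' @rdname load_config
#' @export
config_to_arch <- function(config) moth_arch(config$architecture$widths)

#' @rdname load_config
#' @export
config_to_train_config <- function(config) {
  do.call(train_config, config$training)
}

#' @rdname load_config
#' @export
config_to_ensemble_config <- function(config) {
  ensemble_config(n_networks = config$ensemble$n_networks,
                  base_seed = config$ensemble$base_seed,
                  arch = config_to_arch(config),
                  dense_config = config_to_train_config(config),
                  schedule = as.numeric(config$pruning$schedule),
                  threshold = config$ensemble$threshold,
                  scope = config$pruning$scope)
}

# stable short hash of a configuration for checkpoint resume checks
config_hash <- function(config) object_hash(unclass(config))
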