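# YAML configuration with strict parsing: unknown keys are errors, so a
# typo cannot silently fall back to a default.

#' Default configuration
#'
#' The defaults mirror the protocol constants used throughout: patch 72,
#' batch 8, 50000 training iterations, equivariance weight 2, fine-tune
#' budget 5000.
#'
#' @return Nested named list of all recognised settings.
#' @export
default_config <- function() {
  list(
    simulate = list(shape = 48, n_shells = c(1, 2), n_rods = c(1, 3),
                    n_blobs = c(3, 8), contrast = 1, background = 0,
                    theta_min = -60, theta_max = 60, increment = 3,
                    noise = "gaussian", sigma_rel = 2, gain = 10,
                    pixel_size = 1),
    train = list(patch_size = 72, batch_size = 8, max_iterations = 50000,
                 learning_rate = 4e-4, mixed_precision = TRUE,
                 checkpoint_every = 1000,
                 lambda = 2, mask_original_wedge = TRUE, swap_augment = TRUE,
                 detach_plugin = FALSE,
                 depth = 3, base_channels = 16, activation = "leaky_relu",
                 residual = TRUE),
    finetune = list(max_iterations = 5000),
    prepare = list(z_fraction = 0.6, density_quantile = 0.5, window = 5),
    predict = list(patch_size = 72, overlap = 18, passes = 2),
    fsc = list(crop = 256, threshold = 0.143)
  )
}

merge_strict <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_strict(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Read a configuration file
#'
#' @param path YAML file; keys must be a subset of [default_config()]
#'   (strict parsing: unknown keys raise an error).
#' @return The defaults overridden by the file's settings.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_strict(default_config(), user)
}

# Order-independent 32-bit FNV-style hash of the resolved configuration,
# so logs can tell at a glance whether two runs shared settings.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

# Machine-readable provenance record for a run.
provenance_record <- function(command, config, seed) {
  list(command = command, seed = seed,
       config_hash = config_hash(config),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       r_version = R.version.string,
       package_version = as.character(utils::packageVersion("equitomo")),
       config = config)
}
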