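#' Assemble the full run configuration
#'
#' A run configuration merges the scene, noise, model, training and metric
#' parameter groups into one nested record that round-trips losslessly
#' through YAML. Every default is either the published setting or a
#' documented package convention; unknown keys in an override or a loaded
#' file are rejected so a typo fails fast instead of being silently
#' ignored.
#'
#' @param profile training profile passed to [train_config()].
#' @param overrides nested named list merged over the defaults.
#' @return nested list of class `hazegan_run_config`.
#' @export
run_config <- function(profile = "desk", overrides = list()) {
  defaults <- list(
    scene = unclass(scene_params()),
    noise = unclass(noise_config()),
    train = unclass(train_config(profile)),
    metrics = list(iou_threshold = 0.5, ap_interpolation = "all_points",
                   psnr_max = 255))
  defaults$train$weights <- unclass(defaults$train$weights)
  # named probabilities survive YAML as a map, not a bare sequence
  defaults$noise$form_probs <- as.list(defaults$noise$form_probs)
  merge_strict <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", path, nm)
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_strict(base[[nm]], over[[nm]],
                                   paste0(path, nm, "."))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_strict(defaults, overrides),
            class = "hazegan_run_config")
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file.
#' @param profile base profile the file's values override.
#' @return a `hazegan_run_config`.
#' @export
load_config <- function(path, profile = "desk") {
  if (!file.exists(path)) stop("config file not found: ", path)
  run_config(profile, overrides = yaml::read_yaml(path))
}

#' @rdname load_config
#' @param config a `hazegan_run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path, precision = 15)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
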