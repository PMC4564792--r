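# Run configuration: one YAML document mirroring every parameter group,
# validated strictly (unknown keys are rejected, values go through the same
# constructors the R API uses).

#' Default run configuration
#'
#' Nested list with one section per parameter group (`phantom`,
#' `threshold`, `grow`, `propagation`) plus `verbosity`. Field names and
#' defaults match [phantom_config()], [threshold_params()],
#' [grow_params()] and [propagation_params()].
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  ph <- unclass(phantom_config())
  ph["intensity_tooth"] <- list(NULL)   # derived: socket + contrast_gap
  list(phantom = ph,
       threshold = unclass(threshold_params()),
       grow = unclass(grow_params()),
       propagation = unclass(propagation_params()),
       verbosity = 0L)
}

#' Load and validate a run configuration
#'
#' Merges (in increasing priority) the package defaults, an optional YAML
#' file, and explicit overrides. Any key not present in the defaults is
#' rejected with an error naming it; all values are re-validated through
#' the parameter constructors.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional nested list of overriding values (e.g. parsed
#'   from command-line flags; flags win over the file).
#' @return Validated configuration list of class `run_config`, with
#'   materialised parameter objects in `$params`.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_config(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user %||% list(), "")
  }
  if (!is.null(overrides) && length(overrides))
    cfg <- merge_config(cfg, overrides, "")
  params <- tryCatch(list(
    phantom = do.call(phantom_config, cfg$phantom),
    threshold = do.call(threshold_params, cfg$threshold),
    grow = do.call(grow_params, cfg$grow),
    propagation = do.call(propagation_params, cfg$propagation)
  ), error = function(e) stop_config(conditionMessage(e)))
  structure(c(cfg, list(params = params)), class = "run_config")
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user))
    stop_config(sprintf("config section '%s' must be a mapping",
                        sub("^\\.", "", prefix)))
  for (key in names(user)) {
    full <- paste0(prefix, ".", key)
    if (!key %in% names(base))
      stop_config(sprintf("unknown config key '%s'", sub("^\\.", "", full)))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

stop_config <- function(msg) {
  stop(structure(class = c("toothprop_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
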