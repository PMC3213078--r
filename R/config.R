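#' Analysis configuration
#'
#' Bundles the geometric tracing parameters used by the dendrite tracer,
#' the spine detector and the classifier. The defaults reproduce the two
#' published parameter sets: `"fixed"` mode (fixed, mature neurons; minimum
#' spine end diameter 0.215 um, i.e. twice the in-plane pixel width, and
#' maximum spine length 5 um) and `"live"` mode (live imaging of younger
#' neurons; 0.3 um and 15 um, the longer bound admitting filopodia).
#'
#' @param mode `"fixed"` or `"live"`; selects the default
#'   `min_spine_end_diameter` / `max_spine_length` pair.
#' @param min_dendrite_end_diameter Minimum local diameter (um) for a
#'   skeleton voxel to belong to the dendrite path. Default 0.75.
#' @param min_spine_end_diameter Minimum local diameter (um) at a spine tip
#'   for the protrusion to be kept.
#' @param max_spine_length Maximum spine length (um); longer protrusions are
#'   discarded by the detector and classified `"excluded"`.
#' @param stubby_length_max Length bound (um) separating stubby from thin
#'   spines. Default 1.
#' @param class_ratio_threshold Head-width / neck-width ratio at or above
#'   which a spine is a mushroom. Default 1.5.
#' @param tracking_gate Maximum match cost (um) when linking spines between
#'   consecutive time points. Default 1.
#' @param threshold_method Automatic threshold used for segmentation;
#'   `"otsu"` or a numeric value to force a fixed threshold.
#' @param head_fraction Distal fraction of the spine path searched for the
#'   head width maximum. Default 0.5.
#' @param smooth_window Moving-average window (um) applied to the dendrite
#'   centerline. Default 0.5.
#' @param min_protrusion Minimum distance (um) a spine tip must protrude
#'   beyond the dendrite surface; suppresses sub-voxel skeleton twigs.
#'   Default 0.3.
#' @return An object of class `spine_config` (a named list).
#' @examples
#' analysis_config("fixed")$max_spine_length   # 5
#' analysis_config("live")$max_spine_length    # 15
#' @export
analysis_config <- function(mode = c("fixed", "live"),
                            min_dendrite_end_diameter = 0.75,
                            min_spine_end_diameter = NULL,
                            max_spine_length = NULL,
                            stubby_length_max = 1.0,
                            class_ratio_threshold = 1.5,
                            tracking_gate = 1.0,
                            threshold_method = "otsu",
                            head_fraction = 0.5,
                            smooth_window = 0.5,
                            min_protrusion = 0.3) {
  mode <- match.arg(mode)
  if (is.null(min_spine_end_diameter))
    min_spine_end_diameter <- if (mode == "fixed") 0.215 else 0.3
  if (is.null(max_spine_length))
    max_spine_length <- if (mode == "fixed") 5 else 15
  cfg <- list(mode = mode,
              min_dendrite_end_diameter = min_dendrite_end_diameter,
              min_spine_end_diameter = min_spine_end_diameter,
              max_spine_length = max_spine_length,
              stubby_length_max = stubby_length_max,
              class_ratio_threshold = class_ratio_threshold,
              tracking_gate = tracking_gate,
              threshold_method = threshold_method,
              head_fraction = head_fraction,
              smooth_window = smooth_window,
              min_protrusion = min_protrusion)
  lens <- c(cfg$min_dendrite_end_diameter, cfg$min_spine_end_diameter,
            cfg$max_spine_length, cfg$stubby_length_max, cfg$tracking_gate)
  if (any(lens <= 0)) stop("all length parameters must be positive")
  if (cfg$min_spine_end_diameter >= cfg$min_dendrite_end_diameter)
    stop("min_spine_end_diameter must be smaller than min_dendrite_end_diameter")
  if (cfg$stubby_length_max >= cfg$max_spine_length)
    stop("stubby_length_max must be smaller than max_spine_length")
  class(cfg) <- "spine_config"
  cfg
}

#' @export
print.spine_config <- function(x, ...) {
  cat("Spine analysis configuration (", x$mode, " mode)\n", sep = "")
  for (k in setdiff(names(x), "mode"))
    cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write an analysis configuration file
#'
#' Configurations are stored as YAML with one key per [analysis_config()]
#' argument; unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_config` returns a `spine_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @param config A `spine_config` object.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "spine_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
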