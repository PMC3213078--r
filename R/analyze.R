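#' Run the full spine morphometry pipeline on one volume
#'
#' Segments the volume, traces the dendrite from the starting point, detects
#' spine protrusions under the configured geometric constraints, measures
#' head width, neck width, length and head volume for each, classifies them
#' as stubby, mushroom or thin, and computes the spine density per 10 um of
#' dendrite.
#'
#' @param vol A [volume_image()].
#' @param start Dendrite starting point `(x, y, z)` in um at the edge of the
#'   region of interest.
#' @param config An [analysis_config()].
#' @return An object of class `spine_analysis`: `trace` (a
#'   `dendrite_trace`), `spines` (one measured, classified row per spine),
#'   `density` (spines per 10 um), `config`, `time_index`.
#' @examples
#' \donttest{
#' ph <- rasterize(phantom_spec(
#'   field_of_view = c(15, 7, 7), seed = 1,
#'   spines = list(spine_spec(7, 0, 1.5, 0.6, 0.25))))
#' fit <- analyze_spines(ph$volume, start = c(0.1, 3.5, 3.5))
#' summary(fit)
#' }
#' @export
analyze_spines <- function(vol, start, config = analysis_config()) {
  trace <- trace_dendrite(vol, start, config)
  rec <- detect_spines(trace, config)
  rec <- measure_spines(rec, trace, config)
  structure(list(trace = trace,
                 spines = rec,
                 density = spine_density(rec, trace),
                 config = config,
                 time_index = vol$time_index),
            class = "spine_analysis")
}

#' @export
print.spine_analysis <- function(x, ...) {
  cat(sprintf("spine_analysis: %d spines on %.1f um of dendrite (%.2f per 10 um)\n",
              nrow(x$spines), x$trace$length, x$density))
  if (nrow(x$spines) > 0) {
    tab <- table(factor(x$spines$class,
                        levels = c("stubby", "mushroom", "thin")))
    cat("  classes:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.spine_analysis <- function(object, ...) {
  print(object)
  if (nrow(object$spines) > 0) {
    for (v in c("head_width", "neck_width", "length", "head_volume")) {
      vals <- object$spines[[v]]
      vals <- vals[is.finite(vals)]
      if (length(vals))
        cat(sprintf("  %-12s median %.3f, mean %.3f, range [%.3f, %.3f]\n",
                    v, median(vals), mean(vals), min(vals), max(vals)))
    }
  }
  invisible(object)
}

#' @export
as.data.frame.spine_analysis <- function(x, ...) {
  df <- x$spines
  attr(df, "branches") <- NULL
  if (nrow(df) > 0) df$time <- x$time_index
  df
}

#' @export
plot.spine_analysis <- function(x, ...) {
  plot(x$trace, main = sprintf("%d spines, %.2f per 10 um",
                               nrow(x$spines), x$density), ...)
  if (nrow(x$spines) > 0) {
    cls <- factor(x$spines$class, levels = c("stubby", "mushroom", "thin"))
    cols <- c("gold", "green3", "dodgerblue")[as.integer(cls)]
    points(x$spines$tip_x, x$spines$tip_y, col = cols, pch = 19)
    legend("topright", legend = levels(cls), col = c("gold", "green3",
                                                     "dodgerblue"), pch = 19,
           bg = "white", cex = 0.8)
  }
  invisible(x)
}
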