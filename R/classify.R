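#' Classify spines as stubby, mushroom or thin
#'
#' Applies the standard three-class geometric scheme on the head-width /
#' neck-width ratio r and the spine length L (um):
#' * mushroom: r >= 1.5 and L <= max length;
#' * stubby:   r <  1.5 and L <= 1;
#' * thin:     r <  1.5 and 1 < L <= max length;
#' * excluded: L > max length (not a spine under the active mode).
#'
#' Boundary semantics are exact: L = 1 is stubby-side, r = 1.5 is
#' mushroom-side. The three classes partition the valid domain. The ratio is
#' oriented head over neck; published versions of this scheme sometimes print
#' the inverted ratio, which would make necks wider than heads a maturity
#' criterion and is inconsistent with the observed geometry (population
#' medians put heads at roughly four times the neck width, with mushroom the
#' majority class), so head/neck is used here.
#'
#' @param length Spine length(s) in um, > 0.
#' @param head_width Head width(s) in um, > 0.
#' @param neck_width Neck width(s) in um, > 0.
#' @param config A [analysis_config()]; supplies the 1 um stubby bound, the
#'   1.5 ratio threshold and the mode's maximum spine length.
#' @return Character vector in
#'   `c("stubby", "mushroom", "thin", "excluded")`.
#' @examples
#' classify_spines(0.8, 0.48, 0.40)   # ratio 1.2 -> "stubby"
#' classify_spines(1.33, 0.44, 0.11)  # ratio 4.0 -> "mushroom"
#' classify_spines(3.0, 0.30, 0.25)   # ratio 1.2 -> "thin"
#' @export
classify_spines <- function(length, head_width, neck_width,
                            config = analysis_config()) {
  n <- max(base::length(length), base::length(head_width), base::length(neck_width))
  length <- rep_len(length, n)
  head_width <- rep_len(head_width, n)
  neck_width <- rep_len(neck_width, n)
  if (any(!is.finite(length)) || any(!is.finite(head_width)) ||
      any(!is.finite(neck_width)) || any(length <= 0) ||
      any(head_width <= 0) || any(neck_width <= 0))
    stop("length, head_width and neck_width must all be positive and finite")
  r <- head_width / neck_width
  # a relative epsilon keeps the r = 1.5 boundary mushroom-side even when
  # the division is inexact (e.g. 0.3 / 0.2 < 1.5 in floating point)
  thr <- config$class_ratio_threshold * (1 - 1e-9)
  out <- rep("excluded", n)
  valid <- length <= config$max_spine_length
  out[valid & r >= thr] <- "mushroom"
  out[valid & r < thr & length <= config$stubby_length_max] <- "stubby"
  out[valid & r < thr & length > config$stubby_length_max] <- "thin"
  out
}

#' Spine density per 10 um of dendrite
#'
#' @param records Data frame of detected spines (one row per spine).
#' @param trace A [dendrite_trace] (or anything with a `$length` in um).
#' @return Spines per 10 um of dendrite.
#' @examples
#' # 18 spines on a 40 um dendrite -> 4.5 per 10 um
#' @export
spine_density <- function(records, trace) {
  len <- if (is.numeric(trace)) trace else trace$length
  if (!is.finite(len) || len <= 0) stop("dendrite trace length must be positive")
  10 * nrow(records) / len
}
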