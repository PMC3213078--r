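#' Track spines across a time-lapse series
#'
#' Links detected spines between consecutive time points by minimum-cost
#' one-to-one assignment on attachment position: the cost of pairing two
#' spines is `|delta arclength| + 0.5 um * |delta azimuth| / pi` (azimuth
#' wrapped to `[-pi, pi]`), and pairs with cost above the gate stay
#' unmatched. A spine unmatched at time t closes its track; one unmatched at
#' t + 1 opens a new track — presence intervals are contiguous by
#' construction. Fates: `stable` tracks span the first and last series time
#' point, `pruned` are present at the first but not the last, `new` absent
#' at the first but present at the last, and `transient` at neither end.
#'
#' @param analyses List of [analyze_spines()] results (or data frames with
#'   `arclength`, `azimuth` and geometry columns), one per time point, in
#'   time order and traced from the same starting point.
#' @param gate Maximum match cost in um; default from the first analysis'
#'   config, else 1.
#' @return An object of class `spine_tracks`: `tracks` (per-track summary
#'   with fate, initial and final class), `table` (long per-track, per-time
#'   table of geometry), `n_time`.
#' @export
track_spines <- function(analyses, gate = NULL) {
  stopifnot(length(analyses) >= 2)
  recs <- lapply(analyses, function(a) {
    if (inherits(a, "spine_analysis")) as.data.frame(a) else a
  })
  if (is.null(gate)) {
    gate <- if (inherits(analyses[[1]], "spine_analysis"))
      analyses[[1]]$config$tracking_gate else 1
  }
  tlen <- vapply(analyses, function(a)
    if (inherits(a, "spine_analysis")) a$trace$length else NA_real_, numeric(1))
  if (all(is.finite(tlen)) &&
      (max(tlen) - min(tlen)) / max(min(tlen), 1e-9) > 0.2)
    warning("dendrite trace length changes by more than 20% across the ",
            "series; drift suspected")

  n_time <- length(recs)
  # track bookkeeping: row index of each time point's records -> track id
  track_of <- lapply(recs, function(r) rep(NA_integer_, nrow(r)))
  n_tracks <- nrow(recs[[1]])
  if (n_tracks > 0) track_of[[1]] <- seq_len(n_tracks)

  for (t in seq_len(n_time - 1)) {
    a <- recs[[t]]; b <- recs[[t + 1]]
    if (nrow(a) > 0 && nrow(b) > 0) {
      darc <- abs(outer(a$arclength, b$arclength, "-"))
      dazi <- abs(outer(a$azimuth, b$azimuth, "-"))
      dazi <- pmin(dazi, 2 * pi - dazi)
      cost <- darc + 0.5 * dazi / pi
      mt <- gated_match(cost, gate)
    } else {
      mt <- list(pairs = matrix(integer(0), ncol = 2),
                 unmatched2 = seq_len(nrow(b)))
    }
    if (nrow(mt$pairs) > 0)
      track_of[[t + 1]][mt$pairs[, 2]] <- track_of[[t]][mt$pairs[, 1]]
    for (j in mt$unmatched2) {
      n_tracks <- n_tracks + 1L
      track_of[[t + 1]][j] <- n_tracks
    }
  }

  long <- NULL
  for (t in seq_len(n_time)) {
    r <- recs[[t]]
    if (nrow(r) == 0) next
    r$track <- track_of[[t]]
    r$t <- t - 1L
    attr(r, "branches") <- NULL
    long <- rbind(long, r[, c("track", "t",
                              setdiff(names(r), c("track", "t")))])
  }

  tracks <- data.frame(track = seq_len(n_tracks))
  tracks$first_t <- NA_integer_; tracks$last_t <- NA_integer_
  tracks$initial_class <- NA_character_; tracks$final_class <- NA_character_
  for (k in seq_len(n_tracks)) {
    sub <- long[long$track == k, , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    tracks$first_t[k] <- sub$t[1]
    tracks$last_t[k] <- sub$t[nrow(sub)]
    if ("class" %in% names(sub)) {
      tracks$initial_class[k] <- sub$class[1]
      tracks$final_class[k] <- sub$class[nrow(sub)]
    }
  }
  tracks$fate <- assign_fates(tracks$first_t, tracks$last_t, n_time)

  # accounting identities, asserted on every run
  n0 <- sum(tracks$first_t == 0)
  nE <- sum(tracks$last_t == n_time - 1)
  stopifnot(n0 == sum(tracks$fate %in% c("stable", "pruned")),
            nE == sum(tracks$fate %in% c("stable", "new")))

  structure(list(tracks = tracks, table = long, n_time = n_time, gate = gate),
            class = "spine_tracks")
}

#' Fate labels from presence intervals
#'
#' @param first_t,last_t First/last time point (0-based) of each track.
#' @param n_time Number of series time points.
#' @return Character vector: `stable`, `pruned`, `new` or `transient`
#'   (present at neither end; reported separately rather than folded into
#'   new or pruned).
#' @export
assign_fates <- function(first_t, last_t, n_time) {
  at0 <- first_t == 0
  atE <- last_t == n_time - 1
  out <- rep("transient", length(first_t))
  out[at0 & atE] <- "stable"
  out[at0 & !atE] <- "pruned"
  out[!at0 & atE] <- "new"
  out
}

#' @export
print.spine_tracks <- function(x, ...) {
  cat(sprintf("spine_tracks: %d tracks over %d time points\n",
              nrow(x$tracks), x$n_time))
  print(table(x$tracks$fate))
  invisible(x)
}

#' @export
summary.spine_tracks <- function(object, ...) {
  print(object)
  tr <- transitions(object)
  cat("\nPer-class transition fractions (rows: initial class at t = 0):\n")
  print(round(tr$by_class, 3))
  invisible(object)
}

#' @export
plot.spine_tracks <- function(x, ...) {
  tb <- x$table
  if (is.null(tb) || nrow(tb) == 0) return(invisible(x))
  plot(NULL, xlim = c(0, x$n_time - 1), ylim = range(tb$head_width, na.rm = TRUE),
       xlab = "time point", ylab = "head width (um)", ...)
  cols <- hcl.colors(max(tb$track), "Dark 3")
  for (k in unique(tb$track)) {
    sub <- tb[tb$track == k, ]
    lines(sub$t, sub$head_width, col = cols[k])
    points(sub$t, sub$head_width, col = cols[k], pch = 19, cex = 0.5)
  }
  invisible(x)
}

#' Class-transition fractions and remodeling incidence
#'
#' Restricted to protrusions present at the first time point (newly formed
#' spines are excluded from remodeling quantification). For each initial
#' class the fraction maintaining it, remodeling into each other class, or
#' pruned is computed, conditioned on the class' t = 0 count; the incidence
#' table expresses each (initial class, outcome) pair as a fraction of all
#' t = 0 protrusions. A class absent at t = 0 yields an undefined (NA) row,
#' not zeros.
#'
#' @param tracks A [track_spines()] result.
#' @return A list of class `transition_summary`: `by_class` (3 x 4 matrix;
#'   rows stubby/mushroom/thin, columns to_stubby/to_mushroom/to_thin/
#'   pruned), `incidence` (same shape, fractions of all t = 0 protrusions),
#'   `n0` (t = 0 counts per class).
#' @export
transitions <- function(tracks) {
  stopifnot(inherits(tracks, "spine_tracks"))
  tr <- tracks$tracks[tracks$tracks$first_t == 0, , drop = FALSE]
  classes <- c("stubby", "mushroom", "thin")
  outcome <- ifelse(tr$fate == "pruned", "pruned", tr$final_class)
  by_class <- matrix(NA_real_, 3, 4,
                     dimnames = list(classes,
                                     c("to_stubby", "to_mushroom", "to_thin",
                                       "pruned")))
  incidence <- matrix(0, 3, 4, dimnames = dimnames(by_class))
  n_total <- nrow(tr)
  n0 <- setNames(integer(3), classes)
  for (ci in classes) {
    sel <- tr$initial_class == ci
    n0[ci] <- sum(sel)
    if (n0[ci] == 0) next                     # undefined row, stays NA
    cnt <- c(sum(outcome[sel] == "stubby"), sum(outcome[sel] == "mushroom"),
             sum(outcome[sel] == "thin"), sum(outcome[sel] == "pruned"))
    by_class[ci, ] <- cnt / n0[ci]
    incidence[ci, ] <- cnt / n_total
  }
  structure(list(by_class = by_class, incidence = incidence, n0 = n0,
                 n_total = n_total),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Transition fractions by initial class (t = 0 protrusions only):\n")
  print(round(x$by_class, 3))
  cat("\nIncidence (fractions of all", x$n_total, "t = 0 protrusions):\n")
  print(round(x$incidence, 3))
  invisible(x)
}

#' Initial geometry of stable, remodeled and pruned spines
#'
#' For one initial class, partitions its t = 0 protrusions into stable
#' (class maintained at the series end), remodeled (present at the end with
#' a different class) and pruned groups, and reports the group means of
#' initial head width, neck width, length and head/neck ratio — the
#' fate-predictor analysis.
#'
#' @param tracks A [track_spines()] result.
#' @param initial_class `"stubby"`, `"mushroom"` or `"thin"`.
#' @return A data frame of class `fate_group_stats`, one row per non-empty
#'   group, with `n` and the four group means.
#' @export
fate_group_geometry <- function(tracks,
                                initial_class = c("mushroom", "stubby", "thin")) {
  stopifnot(inherits(tracks, "spine_tracks"))
  initial_class <- match.arg(initial_class)
  tr <- tracks$tracks
  sel <- tr$first_t == 0 & tr$initial_class == initial_class
  tr <- tr[sel, , drop = FALSE]
  grp <- ifelse(tr$fate == "pruned", "pruned",
                ifelse(tr$final_class == initial_class, "stable", "remodeled"))
  t0 <- tracks$table[tracks$table$t == 0, , drop = FALSE]
  g0 <- t0[match(tr$track, t0$track), , drop = FALSE]
  out <- NULL
  for (gname in c("stable", "remodeled", "pruned")) {
    idx <- grp == gname
    if (!any(idx)) next
    out <- rbind(out, data.frame(
      group = gname, n = sum(idx),
      head_width = mean(g0$head_width[idx]),
      neck_width = mean(g0$neck_width[idx]),
      length = mean(g0$length[idx]),
      head_neck_ratio = mean(g0$head_width[idx] / g0$neck_width[idx])))
  }
  if (is.null(out))
    out <- data.frame(group = character(0), n = integer(0),
                      head_width = numeric(0), neck_width = numeric(0),
                      length = numeric(0), head_neck_ratio = numeric(0))
  class(out) <- c("fate_group_stats", "data.frame")
  attr(out, "initial_class") <- initial_class
  out
}
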