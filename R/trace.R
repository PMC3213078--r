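#' Segment the labeled structure around a starting point
#'
#' Thresholds the volume with the configured automatic method (Otsu on the
#' ROI intensity histogram by default, or a fixed numeric threshold) and
#' keeps the connected foreground component containing the dendrite
#' starting point.
#'
#' @param vol A [volume_image()].
#' @param start Dendrite starting point, `(x, y, z)` in um, placed at the
#'   edge of the region of interest inside the dendrite.
#' @param config An [analysis_config()].
#' @return A list: `mask` (logical `[z, y, x]` array), `threshold`.
#' @export
segment_volume <- function(vol, start, config = analysis_config()) {
  stopifnot(inherits(vol, "volume_image"), length(start) == 3)
  thr <- if (is.numeric(config$threshold_method)) config$threshold_method
         else if (identical(config$threshold_method, "otsu"))
           otsu_threshold(vol$data)
         else stop("unknown threshold method: ", config$threshold_method)
  fg <- vol$data >= thr
  d <- dim(vol$data)
  idx <- phys_to_index(start, vol$voxel_size, d)
  lin <- (idx[3] - 1) * (d[1] * d[2]) + (idx[2] - 1) * d[1] + idx[1]
  if (!fg[lin])
    stop("starting point falls in background after thresholding (threshold = ",
         signif(thr, 4), "); consider a threshold override")
  mask <- label_from_seed_cpp(as.logical(fg), d, lin - 1)
  dim(mask) <- d
  list(mask = mask, threshold = thr)
}

#' Trace the dendrite centerline
#'
#' Segments the volume, resamples the mask to isotropic spacing (z is
#' interpolated to the in-plane pixel size, since anisotropic voxels bias
#' medial-axis thinning), extracts a 3D curve skeleton by topology-preserving
#' thinning, computes the local radius at every skeleton voxel from the
#' Euclidean distance transform, and returns the maximal geodesic path from
#' the starting point through skeleton voxels whose local diameter is at
#' least `min_dendrite_end_diameter`. The mask is replicate-padded before
#' thinning so a dendrite cut by the volume faces is skeletonized to the
#' face rather than retracting by one radius. The path is smoothed with a
#' moving average over `smooth_window` um. Ties between equal-length
#' geodesic paths are broken toward larger local radius (the dendrite is the
#' thickest structure).
#'
#' @inheritParams segment_volume
#' @return An object of class `dendrite_trace`: `points` (n x 3 um, xyz),
#'   `radius` (um per point), `arclength`, `length`, `start`, `mask`,
#'   `threshold`, plus the skeleton internals used by [detect_spines()].
#' @export
trace_dendrite <- function(vol, start, config = analysis_config()) {
  seg <- segment_volume(vol, start, config)
  # threshold on the isotropically resampled intensity (not the binary mask)
  # so partial-volume boundaries survive the z interpolation
  iso <- resample_isotropic(vol$data, vol$voxel_size)
  s <- iso$spacing
  maskI0 <- iso$data >= seg$threshold
  dI <- dim(maskI0)
  seed <- pmax(1L, pmin(dI, as.integer(round(rev(start) / s + 0.5))))
  if (!maskI0[seed[1], seed[2], seed[3]]) {
    nb <- which(maskI0[pmax(1, seed[1] - 2):pmin(dI[1], seed[1] + 2),
                       pmax(1, seed[2] - 2):pmin(dI[2], seed[2] + 2),
                       pmax(1, seed[3] - 2):pmin(dI[3], seed[3] + 2)],
                arr.ind = TRUE)
    if (nrow(nb) == 0)
      stop("starting point falls in background after resampling")
    seed <- nb[1, ] + pmax(1, seed - 2) - 1L
  }
  lin <- (seed[3] - 1) * (dI[1] * dI[2]) + (seed[2] - 1) * dI[1] + seed[1]
  maskI <- label_from_seed_cpp(as.logical(maskI0), dI, lin - 1)
  dim(maskI) <- dI

  k <- as.integer(ceiling(config$min_dendrite_end_diameter / s)) + 4L
  padded <- pad_replicate(maskI, k)
  edtP <- edt_cpp(as.logical(padded), dim(padded), rep(s, 3))
  skelP <- thin3d_cpp(as.logical(padded), dim(padded), edtP)
  core <- function(a) {
    dim(a) <- dim(padded)
    a[k + seq_len(dI[1]), k + seq_len(dI[2]), k + seq_len(dI[3])]
  }
  skel <- core(skelP)
  edt <- core(edtP)
  if (!any(skel)) stop("empty skeleton; segmentation failed")

  g <- voxel_graph(skel, s)
  vid <- as.integer(igraph::V(g)$name)      # linear indices into iso grid
  vpos <- arrayInd(vid, dI)
  vphys <- index_to_phys(vpos, rep(s, 3))
  vrad <- edt[vid]

  # tie-break toward thicker routes: infinitesimal radius-dependent penalty
  ends <- igraph::ends(g, igraph::E(g))
  rmean <- (vrad[match(ends[, 1], igraph::V(g)$name)] +
              vrad[match(ends[, 2], igraph::V(g)$name)]) / 2
  igraph::E(g)$weight <- igraph::E(g)$weight * (1 + 1e-6 / (1 + rmean))

  d2start <- sqrt(colSums((t(vphys) - start)^2))
  v0 <- which.min(d2start)
  if (d2start[v0] > 3 * s)
    stop("no skeleton voxel within 3 voxels of the starting point")

  thick <- which(2 * vrad >= config$min_dendrite_end_diameter)
  if (!(v0 %in% thick))
    thick <- sort(unique(c(thick, v0)))
  gd <- igraph::induced_subgraph(g, thick)
  dist0 <- igraph::distances(gd, v = match(v0, thick))[1, ]
  dist0[!is.finite(dist0)] <- -Inf
  vfar <- which.max(dist0)
  pathv <- igraph::shortest_paths(gd, from = match(v0, thick), to = vfar,
                                  output = "vpath")$vpath[[1]]
  path_ids <- as.integer(names(pathv))      # linear iso indices along path
  ppos <- arrayInd(path_ids, dI)
  pts_raw <- index_to_phys(ppos, rep(s, 3))
  # the thinned path can sit a voxel off the true medial axis, biasing the
  # plain EDT radius low; read the best value in each point's neighborhood
  radius <- neighborhood_max_edt(path_ids, edt, dI)

  kw <- max(3L, as.integer(round(config$smooth_window / s)))
  if (kw %% 2 == 0) kw <- kw + 1L
  pts <- smooth_polyline(pts_raw, kw)
  arclen <- cum_arc(pts)
  total <- arclen[length(arclen)]
  if (total < 5) warning("dendrite path shorter than 5 um; ROI may be mis-set")

  structure(list(points = pts, radius = radius, arclength = arclen,
                 length = total, start = start,
                 mask = seg$mask, threshold = seg$threshold,
                 voxel_size = vol$voxel_size,
                 internals = list(graph = g, skel = skel, edt = edt,
                                  spacing = s, dim = dI,
                                  vertex_ids = vid, vertex_phys = vphys,
                                  vertex_radius = vrad,
                                  path_ids = path_ids,
                                  mask_iso = maskI)),
            class = "dendrite_trace")
}

#' @export
print.dendrite_trace <- function(x, ...) {
  cat(sprintf("dendrite_trace: %.2f um centerline, %d points, mean radius %.3f um\n",
              x$length, nrow(x$points), mean(x$radius)))
  invisible(x)
}

#' @export
summary.dendrite_trace <- function(object, ...) {
  cat(sprintf("Dendrite trace\n  length:      %.2f um\n  points:      %d\n",
              object$length, nrow(object$points)))
  cat(sprintf("  radius (um): mean %.3f, range [%.3f, %.3f]\n",
              mean(object$radius), min(object$radius), max(object$radius)))
  cat(sprintf("  threshold:   %.4g\n", object$threshold))
  invisible(object)
}

#' @export
as.data.frame.dendrite_trace <- function(x, ...) {
  data.frame(x$points, radius = x$radius, arclength = x$arclength)
}

#' Export a dendrite trace as a CSV polyline
#'
#' @param trace A `dendrite_trace`.
#' @param path Output CSV path (columns x, y, z, radius, arclength; um).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.dendrite_trace <- function(x, ...) {
  mip <- apply(x$mask, c(3, 2), max)  # project over z -> (x, y)
  vs <- x$voxel_size
  image(x = (seq_len(nrow(mip)) - 0.5) * vs[1],
        y = (seq_len(ncol(mip)) - 0.5) * vs[2],
        z = mip, col = c("black", "grey40"),
        xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  lines(x$points[, 1], x$points[, 2], col = "red", lwd = 2)
  points(x$start[1], x$start[2], col = "yellow", pch = 4, cex = 1.5)
  invisible(x)
}
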