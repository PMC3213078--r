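#' Specify one synthetic spine
#'
#' A spine is attached to the dendrite surface at a given arclength along the
#' centerline and azimuth around the local dendrite axis, and is rendered as
#' a neck capsule of diameter `neck_diameter` capped by a spherical head of
#' diameter `head_diameter`, with the tip of the head `length` um from the
#' dendrite surface. With `head_diameter == neck_diameter` this degenerates
#' to a plain round-capped protrusion (thin spines and stubby bumps).
#'
#' @param attachment_arclength Arclength (um) along the dendrite centerline,
#'   measured from where the path enters the field of view.
#' @param azimuth Angle (radians) around the dendrite axis.
#' @param length Protrusion length (um) from dendrite surface to tip.
#' @param head_diameter,neck_diameter Diameters in um.
#' @param shape_class Optional declared class; checked for consistency
#'   against [classify_spines()] applied to the true geometry.
#' @return An object of class `spine_spec`.
#' @export
spine_spec <- function(attachment_arclength, azimuth, length,
                       head_diameter, neck_diameter, shape_class = NULL) {
  stopifnot(is.finite(attachment_arclength), is.finite(azimuth),
            length > 0, head_diameter > 0, neck_diameter > 0)
  if (head_diameter > 2 * length)
    stop("head_diameter larger than twice the protrusion length")
  cls <- classify_spines(length, head_diameter, neck_diameter,
                         analysis_config("live"))
  if (!is.null(shape_class) && !identical(shape_class, cls))
    stop(sprintf("declared class '%s' inconsistent with geometry (classifies as '%s')",
                 shape_class, cls))
  structure(list(attachment_arclength = attachment_arclength,
                 azimuth = azimuth, length = length,
                 head_diameter = head_diameter, neck_diameter = neck_diameter,
                 shape_class = cls),
            class = "spine_spec")
}

#' Specify a synthetic dendrite phantom
#'
#' Describes a 3D test volume: a bright tubular dendrite crossing the field
#' of view, bearing parameterized spines, rendered with partial-volume
#' antialiasing, optional Gaussian PSF blur and optional noise. The defaults
#' mirror the acquisition geometry of the method being emulated: in-plane
#' pixels of 0.1075 um and a 0.15 um z-step, and a dendrite diameter
#' comfortably above the 0.75 um minimum traceable dendrite width.
#'
#' @param field_of_view `(x, y, z)` extent in um.
#' @param voxel_size `(x, y, z)` voxel edges in um; default
#'   `c(0.1075, 0.1075, 0.15)`.
#' @param dendrite_radius Tube radius in um (default 0.6, diameter 1.2).
#' @param dendrite_path `list(type = "line")` for a straight tube along x at
#'   the y/z center, or `list(type = "sine", amplitude = A, period = P)` for
#'   a sine-perturbed tube (y displaced by `A * sin(2 * pi * x / P)`). The
#'   tube extends 2 um beyond the x faces so that it is cut by the volume,
#'   not capped inside it.
#' @param spines List of [spine_spec()] objects.
#' @param psf_sigma Gaussian PSF sigma, `(x, y, z)` um; 0 disables blur.
#' @param noise `list(type = "none")`, `list(type = "gaussian", sd = s)`
#'   (additive, intensity units) or `list(type = "poisson", scale = k)`
#'   (shot noise, counts per intensity unit).
#' @param background,foreground Intensity levels before noise; the default
#'   10/100 gives the 10x contrast of a well-expressing labeled neuron after
#'   deconvolution.
#' @param seed Integer RNG seed for the noise realization, or `NULL`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(field_of_view = c(20, 8, 8),
                         voxel_size = c(0.1075, 0.1075, 0.15),
                         dendrite_radius = 0.6,
                         dendrite_path = list(type = "line"),
                         spines = list(),
                         psf_sigma = c(0, 0, 0),
                         noise = list(type = "none"),
                         background = 10, foreground = 100,
                         seed = NULL) {
  stopifnot(length(field_of_view) == 3, all(field_of_view > 0),
            length(voxel_size) == 3, all(voxel_size > 0),
            dendrite_radius > 0, background >= 0,
            foreground > background)
  if (2 * dendrite_radius < 0.75)
    stop("dendrite diameter below 0.75 um cannot satisfy the minimum ",
         "dendrite end diameter constraint")
  if (length(psf_sigma) == 1) psf_sigma <- rep(psf_sigma, 3)
  if (is.list(spines) && inherits(spines, "spine_spec")) spines <- list(spines)
  stopifnot(all(vapply(spines, inherits, logical(1), "spine_spec")))
  structure(list(field_of_view = as.numeric(field_of_view),
                 voxel_size = as.numeric(voxel_size),
                 dendrite_radius = dendrite_radius,
                 dendrite_path = dendrite_path,
                 spines = spines,
                 psf_sigma = as.numeric(psf_sigma),
                 noise = noise,
                 background = background, foreground = foreground,
                 seed = seed),
            class = "phantom_spec")
}

# Finely sampled centerline polyline (xyz um) with arclength 0 at the point
# where the path enters the field of view (x = 0).
phantom_path <- function(spec, step = 0.05) {
  fov <- spec$field_of_view
  xs <- seq(-2, fov[1] + 2, by = step)
  yc <- fov[2] / 2; zc <- fov[3] / 2
  y <- rep(yc, length(xs))
  if (identical(spec$dendrite_path$type, "sine")) {
    A <- spec$dendrite_path$amplitude
    P <- spec$dendrite_path$period
    y <- yc + A * sin(2 * pi * xs / P)
  } else if (!identical(spec$dendrite_path$type, "line")) {
    stop("unknown dendrite_path type: ", spec$dendrite_path$type)
  }
  pts <- cbind(x = xs, y = y, z = rep(zc, length(xs)))
  arc <- cum_arc(pts)
  entry <- which(xs >= 0)[1]
  list(points = pts, arc = arc - arc[entry])
}

# point + unit tangent at a given arclength (linear interpolation)
path_at <- function(path, s) {
  i <- findInterval(s, path$arc, all.inside = TRUE)
  f <- (s - path$arc[i]) / max(path$arc[i + 1] - path$arc[i], 1e-12)
  p <- path$points[i, ] + f * (path$points[i + 1, ] - path$points[i, ])
  t <- path$points[i + 1, ] - path$points[i, ]
  list(point = as.numeric(p), tangent = t / sqrt(sum(t^2)))
}

# Geometry of one spine in world coordinates; returns the primitives and the
# analytically exact truth row.
spine_solids <- function(sp, path, R) {
  at <- path_at(path, sp$attachment_arclength)
  fr <- normal_frame(at$tangent)
  u <- cos(sp$azimuth) * fr$n1 + sin(sp$azimuth) * fr$n2
  B <- at$point
  C <- B + (R + sp$length - sp$head_diameter / 2) * u
  tip <- B + (R + sp$length) * u
  attach <- B + R * u
  list(sphere = c(C, sp$head_diameter / 2),
       capsule = c(B, C, sp$neck_diameter / 2),
       tip = tip, attach = attach,
       truth = data.frame(
         length = sp$length, head_width = sp$head_diameter,
         neck_width = sp$neck_diameter,
         head_volume = if (sp$shape_class == "mushroom")
           (4 / 3) * pi * (sp$head_diameter / 2)^3 else NA_real_,
         class = sp$shape_class,
         attach_x = attach[1], attach_y = attach[2], attach_z = attach[3],
         tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
         arclength = sp$attachment_arclength, azimuth = sp$azimuth))
}

# world xyz -> (z,y,x) rows for the rasterizer
zyx <- function(p) p[c(3, 2, 1)]

#' Render a phantom volume with ground truth
#'
#' Rasterizes the union of the dendrite tube and all spine solids onto the
#' voxel grid (boundary voxels supersampled 8x for partial-volume accuracy),
#' then applies optional PSF blur and noise. The returned truth table holds
#' the analytically exact geometry of every spine (e.g. a mushroom's true
#' head width is its head-sphere diameter); blur and noise never alter it.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `spine_phantom`: `volume` (a [volume_image()]),
#'   `truth` (one row per spine), `solid` (the noise-free logical solid at
#'   coverage >= 0.5), `spec`.
#' @export
rasterize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fov <- spec$field_of_view
  vs <- spec$voxel_size
  if (max(vs) / min(vs) > 5)
    warning("voxel anisotropy exceeds 5x; skeletonization accuracy degrades")
  path <- phantom_path(spec)

  # decimated centerline for the capsule chain (~0.5 um chords)
  keep <- unique(c(seq(1, nrow(path$points), by = 10), nrow(path$points)))
  cp <- path$points[keep, , drop = FALSE]
  capsules <- cbind(t(apply(cp[-nrow(cp), , drop = FALSE], 1, zyx)),
                    t(apply(cp[-1, , drop = FALSE], 1, zyx)),
                    spec$dendrite_radius)
  spheres <- matrix(numeric(0), ncol = 4)

  truth <- NULL
  for (i in seq_along(spec$spines)) {
    so <- spine_solids(spec$spines[[i]], path, spec$dendrite_radius)
    ext <- so$sphere[4]
    lo <- pmin(so$tip, so$sphere[1:3] - ext)
    hi <- pmax(so$tip, so$sphere[1:3] + ext)
    if (any(lo < 0) || any(hi > fov))
      stop("spine ", i, " extends outside the field of view")
    spheres <- rbind(spheres, zyx4 <- c(zyx(so$sphere[1:3]), so$sphere[4]))
    capsules <- rbind(capsules, c(zyx(so$capsule[1:3]), zyx(so$capsule[4:6]),
                                  so$capsule[7]))
    truth <- rbind(truth, cbind(data.frame(id = i), so$truth))
  }
  if (is.null(truth))
    truth <- data.frame(id = integer(0), length = numeric(0),
                        head_width = numeric(0), neck_width = numeric(0),
                        head_volume = numeric(0), class = character(0),
                        attach_x = numeric(0), attach_y = numeric(0),
                        attach_z = numeric(0), tip_x = numeric(0),
                        tip_y = numeric(0), tip_z = numeric(0),
                        arclength = numeric(0), azimuth = numeric(0))

  dim_zyx <- as.integer(round(fov[c(3, 2, 1)] / vs[c(3, 2, 1)]))
  cov <- rasterize_scene_cpp(dim_zyx, vs[c(3, 2, 1)],
                             spheres, capsules)
  solid <- array(cov >= 0.5, dim = dim_zyx)
  img <- spec$background + (spec$foreground - spec$background) * cov

  if (any(spec$psf_sigma > 0)) {
    sig_vox <- spec$psf_sigma[c(3, 2, 1)] / vs[c(3, 2, 1)]
    img <- gaussian_blur3d(img, sig_vox)
  }
  img <- with_seed(spec$seed, apply_noise(img, spec$noise))

  structure(list(volume = volume_image(img, vs, 0L),
                 truth = truth, solid = solid, spec = spec),
            class = "spine_phantom")
}

apply_noise <- function(img, noise) {
  type <- noise$type %||% "none"
  if (type == "none") return(img)
  if (type == "gaussian") {
    out <- img + rnorm(length(img), sd = noise$sd)
    out[out < 0] <- 0
    dim(out) <- dim(img)
    return(out)
  }
  if (type == "poisson") {
    k <- noise$scale
    out <- rpois(length(img), lambda = as.vector(img) * k) / k
    dim(out) <- dim(img)
    return(out)
  }
  stop("unknown noise type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spine_phantom <- function(x, ...) {
  cat("spine_phantom:", nrow(x$truth), "spines;")
  print(x$volume)
  invisible(x)
}

#' Script remodeling events for a 4D phantom series
#'
#' Defines a time-lapse design (by default 13 time points at 5 min
#' intervals, i.e. one hour of imaging) plus scripted per-spine events:
#' `ev_appear(id, t)`, `ev_prune(id, t)` and
#' `ev_morph(id, t, length, head_diameter, neck_diameter)`. Between time
#' points each spine's attachment is perturbed by isotropic jitter of the
#' stated amplitude (decomposed into arclength and azimuthal displacement on
#' the dendrite surface).
#'
#' @param n_time Number of time points (default 13).
#' @param interval_min Minutes between time points (default 5).
#' @param events List of event objects built by the `ev_*` helpers.
#' @param jitter_amplitude Per-time-point positional jitter in um
#'   (default 0.1, below the tracking gate so identity is well posed).
#' @return An object of class `remodel_script`.
#' @export
remodel_script <- function(n_time = 13, interval_min = 5,
                           events = list(), jitter_amplitude = 0.1) {
  stopifnot(n_time >= 1, interval_min > 0, jitter_amplitude >= 0)
  for (ev in events) {
    stopifnot(inherits(ev, "remodel_event"))
    if (ev$t < 0 || ev$t > n_time - 1)
      stop("event time ", ev$t, " outside the series (0..", n_time - 1, ")")
  }
  structure(list(n_time = as.integer(n_time), interval_min = interval_min,
                 events = events, jitter_amplitude = jitter_amplitude),
            class = "remodel_script")
}

#' @rdname remodel_script
#' @param id Spine index in the phantom's spine list.
#' @param t Time point (0-based) at which the event takes effect.
#' @export
ev_prune <- function(id, t)
  structure(list(type = "prune", id = id, t = t), class = "remodel_event")

#' @rdname remodel_script
#' @export
ev_appear <- function(id, t)
  structure(list(type = "appear", id = id, t = t), class = "remodel_event")

#' @rdname remodel_script
#' @param length,head_diameter,neck_diameter New geometry after the morph.
#' @export
ev_morph <- function(id, t, length, head_diameter, neck_diameter)
  structure(list(type = "morph", id = id, t = t, length = length,
                 head_diameter = head_diameter, neck_diameter = neck_diameter),
            class = "remodel_event")

#' Render a 4D phantom series with scripted remodeling
#'
#' One volume per time point. Scripted appearance, pruning and morphing
#' events are applied (a spine is present from its appear time, if any,
#' until its prune time, exclusive; morphs change geometry from their time
#' onward and the truth class is recomputed from the new geometry). The
#' truth log has one row per spine per time point with a presence flag.
#'
#' @param spec A [phantom_spec()]; its spines are the t = 0 population
#'   unless an `ev_appear` delays them.
#' @param script A [remodel_script()].
#' @return A list of class `spine_phantom_series`: `volumes` (list of
#'   [volume_image()]), `truth` (long table with `t` and `present`),
#'   `solids`, `spec`, `script`.
#' @export
rasterize_series <- function(spec, script) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(script, "remodel_script"))
  ns <- length(spec$spines)
  appear_t <- rep(0L, ns); prune_t <- rep(script$n_time, ns)
  morphs <- vector("list", ns)
  for (ev in script$events) {
    if (ev$id < 1 || ev$id > ns) stop("event references unknown spine id ", ev$id)
    if (ev$type == "appear") appear_t[ev$id] <- ev$t
    if (ev$type == "prune") prune_t[ev$id] <- ev$t
    if (ev$type == "morph") morphs[[ev$id]] <- c(morphs[[ev$id]], list(ev))
  }
  if (any(appear_t >= prune_t & prune_t < script$n_time))
    stop("inconsistent events: a spine appears at or after its pruning time")

  volumes <- vector("list", script$n_time)
  solids <- vector("list", script$n_time)
  truth <- NULL
  for (t in 0:(script$n_time - 1)) {
    sp_t <- spec
    sp_t$seed <- if (is.null(spec$seed)) NULL else spec$seed + 7919L * t
    active <- which(appear_t <= t & t < prune_t)
    spines_t <- list()
    rng_seed <- if (is.null(spec$seed)) NULL else spec$seed + 104729L + t
    jit <- with_seed(rng_seed, {
      if (script$jitter_amplitude > 0 && t > 0 && ns > 0) {
        v <- matrix(rnorm(3 * ns), ncol = 3)
        v <- v / sqrt(rowSums(v^2)) * script$jitter_amplitude
        v
      } else matrix(0, nrow = max(ns, 1), ncol = 3)
    })
    for (i in active) {
      s <- spec$spines[[i]]
      for (m in (morphs[[i]] %||% list())) {
        if (t >= m$t) {
          s2 <- try(spine_spec(s$attachment_arclength, s$azimuth,
                               m$length, m$head_diameter, m$neck_diameter),
                    silent = TRUE)
          if (inherits(s2, "try-error"))
            stop("morph event for spine ", i, " at t = ", m$t,
                 " produces invalid geometry")
          s <- s2
        }
      }
      # isotropic jitter projected onto the dendrite surface coordinates
      s$attachment_arclength <- s$attachment_arclength + jit[i, 1]
      s$azimuth <- s$azimuth + jit[i, 2] / spec$dendrite_radius
      spines_t[[length(spines_t) + 1]] <- s
      attr(spines_t[[length(spines_t)]], "orig_id") <- i
    }
    sp_t$spines <- spines_t
    ph <- rasterize(sp_t)
    ph$volume$time_index <- t
    volumes[[t + 1]] <- ph$volume
    solids[[t + 1]] <- ph$solid

    # truth rows: one per spine (original id) per time point
    rows <- data.frame(id = seq_len(ns), t = t,
                       present = appear_t <= t & t < prune_t)
    geom_cols <- c("length", "head_width", "neck_width", "head_volume",
                   "class", "attach_x", "attach_y", "attach_z",
                   "tip_x", "tip_y", "tip_z", "arclength", "azimuth")
    for (cc in geom_cols) rows[[cc]] <- NA
    rows$class <- NA_character_
    if (length(active)) {
      orig <- vapply(sp_t$spines, function(s) attr(s, "orig_id"), integer(1))
      rows[orig, geom_cols] <- ph$truth[, geom_cols]
    }
    truth <- rbind(truth, rows)
  }
  structure(list(volumes = volumes, truth = truth, solids = solids,
                 spec = spec, script = script),
            class = "spine_phantom_series")
}

#' Standard mixed-population phantom
#'
#' Convenience constructor for the benchmark condition used throughout the
#' validation suite: a straight dendrite of the requested visible length
#' carrying `n_spines` spines cycling through the three classes, evenly
#' spaced along the shaft (well above 1 um spacing at the default sizes)
#' with azimuths stepped by the golden angle so neighbors point in
#' different directions. Class-typical geometry is drawn uniformly from
#' ranges consistent with published population statistics for cultured
#' hippocampal neurons: mushroom heads 0.5-0.7 um on 0.18-0.28 um necks,
#' thin protrusions 1.5-3.5 um long and 0.24-0.3 um wide, stubby bumps
#' 0.5-0.95 um long.
#'
#' @param n_spines Number of spines (default 20).
#' @param dendrite_length Visible dendrite length in um (default 50).
#' @param seed RNG seed for the geometry draw and the noise realization.
#' @param noise Noise model passed to [phantom_spec()].
#' @param classes Optional explicit class sequence recycled to `n_spines`.
#' @return A [phantom_spec()].
#' @export
standard_phantom <- function(n_spines = 20, dendrite_length = 50, seed = 1,
                             noise = list(type = "none"),
                             classes = c("stubby", "mushroom", "thin")) {
  classes <- rep_len(classes, n_spines)
  arcs <- seq(2, dendrite_length - 2, length.out = max(n_spines, 2))[seq_len(n_spines)]
  azis <- (seq_len(n_spines) - 1) * 2.39996
  spines <- with_seed(seed, lapply(seq_len(n_spines), function(i) {
    cl <- classes[i]
    if (cl == "mushroom") {
      head <- runif(1, 0.5, 0.7); neck <- runif(1, 0.18, 0.28)
      len <- runif(1, max(1.2, head), 2.2)
    } else if (cl == "thin") {
      neck <- runif(1, 0.24, 0.3); head <- neck * runif(1, 1.0, 1.3)
      len <- runif(1, 1.5, 3.5)
    } else {
      head <- runif(1, 0.4, 0.5); neck <- head / runif(1, 1.0, 1.3)
      len <- runif(1, 0.5, 0.95)
    }
    spine_spec(arcs[i], azis[i], len, head, neck, shape_class = cl)
  }))
  fov_yz <- 2 * (0.6 + 3.5) + 1.8
  phantom_spec(field_of_view = c(dendrite_length, fov_yz, fov_yz),
               spines = spines, seed = seed, noise = noise)
}

#' Read / write a phantom description file
#'
#' Phantom specifications (and an optional remodeling script) are stored as
#' YAML: top-level [phantom_spec()] fields, a `spines` list with one map per
#' [spine_spec()], and an optional `script` map with `n_time`,
#' `interval_min`, `jitter_amplitude` and an `events` list
#' (`type`/`id`/`t` plus morph geometry).
#'
#' @param path YAML file path.
#' @return `read_phantom_config` returns
#'   `list(spec = phantom_spec, script = remodel_script or NULL)`.
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  spines <- lapply(y$spines, function(s)
    spine_spec(s$attachment_arclength, s$azimuth, s$length,
               s$head_diameter, s$neck_diameter, s$shape_class))
  args <- y[intersect(names(y), setdiff(names(formals(phantom_spec)), "spines"))]
  spec <- do.call(phantom_spec, c(args, list(spines = spines)))
  script <- NULL
  if (!is.null(y$script)) {
    evs <- lapply(y$script$events, function(e) {
      switch(e$type,
             prune = ev_prune(e$id, e$t),
             appear = ev_appear(e$id, e$t),
             morph = ev_morph(e$id, e$t, e$length, e$head_diameter,
                              e$neck_diameter),
             stop("unknown event type: ", e$type))
    })
    script <- remodel_script(
      n_time = y$script$n_time %||% 13,
      interval_min = y$script$interval_min %||% 5,
      events = evs,
      jitter_amplitude = y$script$jitter_amplitude %||% 0.1)
  }
  list(spec = spec, script = script)
}

#' @param spec A [phantom_spec()].
#' @param script Optional [remodel_script()].
#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(spec, path, script = NULL) {
  y <- unclass(spec)
  y$spines <- lapply(spec$spines, unclass)
  if (!is.null(script)) {
    y$script <- list(n_time = script$n_time, interval_min = script$interval_min,
                     jitter_amplitude = script$jitter_amplitude,
                     events = lapply(script$events, unclass))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a phantom (or series) to disk
#'
#' Volumes go to multi-page TIFF (`volume_t000.tif`, ...) and the truth
#' table to `truth.csv`.
#'
#' @param ph A `spine_phantom` or `spine_phantom_series`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- if (inherits(ph, "spine_phantom_series")) ph$volumes else list(ph$volume)
  for (i in seq_along(vols))
    write_volume(vols[[i]], file.path(dir, sprintf("volume_t%03d.tif", i - 1)))
  write.csv(ph$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
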