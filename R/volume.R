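#' Image volume container
#'
#' A `volume_image` holds one 3D fluorescence z-stack: a nonnegative
#' intensity array indexed `[z, y, x]`, the physical voxel size, and a time
#' index for 4D series. Voxel centers sit at `(i - 0.5) * voxel_size` so the
#' physical origin is the volume corner; all exported coordinates are in
#' micrometers.
#'
#' @param data Numeric 3D array indexed `[z, y, x]`.
#' @param voxel_size Numeric length-3 `(x, y, z)` voxel edge lengths in um.
#' @param time_index Integer >= 0, position in a time series.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size, time_index = 0L) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3D array indexed [z, y, x]")
  if (any(dim(data) < 1)) stop("empty image grid")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (x, y, z) in um")
  if (min(data) < 0) stop("intensities must be nonnegative")
  if (max(voxel_size) / min(voxel_size) > 5)
    warning("voxel anisotropy exceeds 5x; skeletonization accuracy degrades")
  structure(list(data = data, voxel_size = voxel_size,
                 time_index = as.integer(time_index)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image: %d x %d x %d voxels (z,y,x), voxel %.4g x %.4g x %.4g um (x,y,z), t = %d\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$time_index))
  cat(sprintf("  extent %.1f x %.1f x %.1f um; intensity range [%.3g, %.3g]\n",
              d[3] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[1] * x$voxel_size[3], min(x$data), max(x$data)))
  invisible(x)
}

# Voxel-size metadata travels in a sidecar YAML file next to the TIFF
# (<file>.meta.yaml): baseline TIFF writers differ in which tags they
# support, and a plain-text sidecar keeps the metadata inspectable while the
# TIFF itself stays readable by any viewer.
meta_path <- function(path) paste0(path, ".meta.yaml")

write_meta <- function(vol, scale, path) {
  yaml::write_yaml(list(voxel_size_um = as.numeric(vol$voxel_size),
                        time_index = as.integer(vol$time_index),
                        scale = scale),
                   meta_path(path))
}

read_meta <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) return(NULL)
  yaml::read_yaml(mp)
}

#' Write a volume to a multi-page TIFF
#'
#' One TIFF page per z-slice, stored as 32-bit float with intensities scaled
#' into `[0, 1]`; the voxel size, time index and intensity scale travel in a
#' plain-text sidecar (`<file>.meta.yaml`), so [read_volume()] restores
#' physical units.
#' Storage is 32-bit, so a first round trip is exact to float precision
#' (better than 1e-6 relative) and every later round trip is exact.
#'
#' @param vol A [volume_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  mx <- max(vol$data)
  # scaling by a power of two is exact in binary floating point, so writing
  # an already-written volume again is bit-identical
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  # 32-bit integer storage: the codec stores floor(v * (2^32 - 1)) and reads
  # back k / 2^32. Choosing the code k from the read normalization and
  # feeding the writer a mid-bin value makes write/read cycles bit-stable.
  pages <- lapply(seq_len(dim(vol$data)[1]), function(z) {
    k <- pmin(round(vol$data[z, , ] / scale * 2^32), 2^32 - 1)
    pmin((k + 0.5) / (2^32 - 1), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  write_meta(vol, scale, path)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' Pages are stacked in file order as z-slices. The voxel size is taken from
#' the sidecar metadata written by [write_volume()]; a `voxel_size_override`
#' always wins (with a notice). A file with no usable metadata and no
#' override is an error.
#'
#' @param path TIFF file path.
#' @param voxel_size_override Optional `(x, y, z)` voxel size in um.
#' @param time_index Optional time index override.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_override = NULL, time_index = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1) stop("no pages in TIFF file: ", path)
  meta <- read_meta(path)
  d2 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d2), logical(1))))
    stop("TIFF pages differ in shape; page order is not a monotone z-series")
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  vs <- meta$voxel_size_um
  if (!is.null(voxel_size_override)) {
    if (!is.null(vs) && any(abs(vs - voxel_size_override) > 1e-12))
      message("voxel size override ", paste(voxel_size_override, collapse = "x"),
              " um replaces file metadata ", paste(vs, collapse = "x"), " um")
    vs <- voxel_size_override
  }
  if (is.null(vs))
    stop("no voxel size metadata in ", path, " and no override given")
  ti <- if (!is.null(time_index)) time_index
        else if (!is.null(meta$time_index)) meta$time_index else 0L
  volume_image(arr, vs, ti)
}

#' Export spine records or tracks as CSV
#'
#' Writes one row per spine (or per spine and time point for tracked data)
#' with coordinates in physical micrometers. An empty record set yields a
#' header-only file. [read_spine_table()] reads the table back.
#'
#' @param records A data frame of spine records (from [detect_spines()] /
#'   [analyze_spines()]) or a per-time track table (from [track_spines()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spine_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spine_table
#' @export
read_spine_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
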