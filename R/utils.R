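# Shared internal helpers.
#
# Conventions used throughout the package:
#  * image arrays are indexed [z, y, x] (z fastest);
#  * user-facing coordinates and voxel sizes are (x, y, z) in micrometers;
#  * voxel centers sit at (i - 0.5) * voxel_size for 1-based index i, so the
#    physical origin is the volume corner.

# Run expr with a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# physical (x, y, z) um -> 1-based array index (z, y, x)
phys_to_index <- function(p, voxel_xyz, dim_zyx) {
  idx_xyz <- pmax(1L, pmin(rev(dim_zyx), as.integer(ceiling(p / voxel_xyz))))
  rev(idx_xyz)
}

# 1-based (z, y, x) index matrix -> physical (x, y, z) um matrix
index_to_phys <- function(idx_zyx, voxel_xyz) {
  idx <- if (is.matrix(idx_zyx)) idx_zyx else matrix(idx_zyx, nrow = 1)
  cbind(x = (idx[, 3] - 0.5) * voxel_xyz[1],
        y = (idx[, 2] - 0.5) * voxel_xyz[2],
        z = (idx[, 1] - 0.5) * voxel_xyz[3])
}

# Otsu's threshold on an intensity array (256-bin histogram).
otsu_threshold <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("intensity image is constant; cannot threshold")
  nb <- 256L
  br <- seq(r[1], r[2], length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Linearly resample array along z so all three axes share the in-plane spacing.
# Returns list(data, spacing, nz). voxel_xyz must have voxel x == voxel y.
resample_isotropic <- function(arr, voxel_xyz) {
  s <- voxel_xyz[1]
  if (abs(voxel_xyz[2] - voxel_xyz[1]) > 1e-9)
    stop("in-plane voxel size must be isotropic (x == y)")
  d <- dim(arr)
  nz <- d[1]
  nz_iso <- max(2L, as.integer(round(nz * voxel_xyz[3] / s)))
  # target slice centers in source fractional index units
  zc <- ((seq_len(nz_iso) - 0.5) * (nz * voxel_xyz[3] / nz_iso)) / voxel_xyz[3] + 0.5
  lo <- pmax(1L, pmin(nz - 1L, floor(zc)))
  fr <- pmin(1, pmax(0, zc - lo))
  out <- array(0, dim = c(nz_iso, d[2], d[3]))
  for (k in seq_len(nz_iso)) {
    out[k, , ] <- (1 - fr[k]) * arr[lo[k], , ] + fr[k] * arr[lo[k] + 1L, , ]
  }
  list(data = out, spacing = s, nz = nz_iso)
}

# Replicate-pad an array by k voxels on every face (continues boundary
# structures, e.g. a dendrite leaving the field of view, straight outward).
pad_replicate <- function(arr, k) {
  d <- dim(arr)
  arr[c(rep(1L, k), seq_len(d[1]), rep(d[1], k)),
      c(rep(1L, k), seq_len(d[2]), rep(d[2], k)),
      c(rep(1L, k), seq_len(d[3]), rep(d[3], k)), drop = FALSE]
}

# The 13 positive half-space neighbor offsets of 26-connectivity.
half_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

# Build an igraph over the TRUE voxels of a logical (z,y,x) array; vertices
# are named by linear index, edges join 26-neighbors weighted by physical
# distance (isotropic spacing s).
voxel_graph <- function(mask, s) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask")
  pos <- arrayInd(idx, d)
  off <- half_offsets_26()
  from <- integer(0); to <- integer(0); w <- numeric(0)
  inmask <- logical(prod(d)); inmask[idx] <- TRUE
  for (k in seq_len(nrow(off))) {
    nz <- pos[, 1] + off[k, 1]; ny <- pos[, 2] + off[k, 2]; nx <- pos[, 3] + off[k, 3]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    nidx <- (nx[ok] - 1L) * (d[1] * d[2]) + (ny[ok] - 1L) * d[1] + nz[ok]
    hit <- inmask[nidx]
    from <- c(from, idx[ok][hit])
    to <- c(to, nidx[hit])
    w <- c(w, rep(s * sqrt(sum(off[k, ]^2)), sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  igraph::E(g)$weight <- w
  g
}

# Orthonormal frame (n1, n2) perpendicular to a unit tangent t (xyz).
# The frame is a fixed function of t so that generator and detector agree.
normal_frame <- function(t) {
  t <- t / sqrt(sum(t^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  n1 <- c(ref[2] * t[3] - ref[3] * t[2],
          ref[3] * t[1] - ref[1] * t[3],
          ref[1] * t[2] - ref[2] * t[1])
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t[2] * n1[3] - t[3] * n1[2],
          t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

# Moving-average smoothing of an n x 3 polyline with a window of k points
# (k odd); endpoints use shrinking symmetric windows so they are preserved
# less aggressively but remain anchored.
smooth_polyline <- function(pts, k) {
  n <- nrow(pts)
  if (k < 3 || n < 3) return(pts)
  half <- (k - 1) %/% 2
  out <- pts
  for (i in seq_len(n)) {
    w <- min(half, i - 1, n - i)
    if (w > 0) out[i, ] <- colMeans(pts[(i - w):(i + w), , drop = FALSE])
  }
  out
}

arc_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

cum_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE])^2))))
}

# Separable Gaussian blur with per-axis sigma in voxel units.
gaussian_blur3d <- function(arr, sigma_vox) {
  blur_axis <- function(a, axis, sg) {
    if (sg <= 0) return(a)
    r <- max(1L, ceiling(3 * sg))
    k <- exp(-((-r:r)^2) / (2 * sg^2)); k <- k / sum(k)
    d <- dim(a)
    out <- array(0, d)
    n <- d[axis]
    for (j in -r:r) {
      src <- pmax(1L, pmin(n, seq_len(n) + j))
      if (axis == 1) out <- out + k[j + r + 1] * a[src, , , drop = FALSE]
      if (axis == 2) out <- out + k[j + r + 1] * a[, src, , drop = FALSE]
      if (axis == 3) out <- out + k[j + r + 1] * a[, , src, drop = FALSE]
    }
    out
  }
  a <- blur_axis(arr, 1, sigma_vox[1])
  a <- blur_axis(a, 2, sigma_vox[2])
  blur_axis(a, 3, sigma_vox[3])
}
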