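#' Construct a 3D attenuation volume
#'
#' A volume is a plain 3D numeric array of non-negative attenuation values
#' plus a physical voxel size. The rotation axis of the virtual beamline
#' passes vertically through the volume center `(dim + 1) / 2` (1-based
#' voxel coordinates).
#'
#' @param voxels 3D numeric array, finite and non-negative.
#' @param voxel_size physical length per voxel (arbitrary units; the virtual
#'   beamline maps 1 voxel to 1 detector pixel).
#' @return An object of class `tomo_volume`.
#' @export
new_volume <- function(voxels, voxel_size = 1) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_bad("`voxels` must be a 3D array", "volume_error")
  if (any(dim(voxels) < 1L))
    stop_bad("all volume dimensions must be >= 1", "volume_error")
  if (!all(is.finite(voxels)))
    stop_bad("volume values must all be finite", "volume_error")
  if (any(voxels < 0))
    stop_bad("volume values must be non-negative", "volume_error")
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels (voxel_size = %g)\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  nonzero: %.1f%%  max: %.4g\n",
              100 * mean(x$voxels > 0), max(x$voxels)))
  invisible(x)
}

#' @export
dim.tomo_volume <- function(x) dim(x$voxels)

#' Specify a synthetic phantom
#'
#' Three phantom kinds cover the alignment experiments: `particle_only` (a
#' single strongly absorbing fiducial sphere, the rotation-axis calibration
#' object), `blob_with_particle` (a lumpy walnut-like specimen carrying one
#' fiducial on its surface) and `lowres_blob` (a blocky, low-resolution
#' specimen standing in for scanning-probe data).
#'
#' @param kind one of `"particle_only"`, `"blob_with_particle"`,
#'   `"lowres_blob"`.
#' @param grid_shape integer vector `(nx, ny, nz)` of voxel counts.
#' @param particle_position voxel coordinates (1-based, may be fractional)
#'   of the fiducial; required for `particle_only`, ignored for
#'   `lowres_blob`, auto-placed on the body surface for
#'   `blob_with_particle` when `NULL`.
#' @param particle_value attenuation of the fiducial. Must exceed the
#'   maximum background attenuation so a single grayscale threshold isolates
#'   the particle; defaults to 5x the background maximum.
#' @param rng_seed integer seed; identical specs produce identical volumes.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("particle_only", "blob_with_particle",
                                  "lowres_blob"),
                         grid_shape = c(96L, 96L, 96L),
                         particle_position = NULL,
                         particle_value = NULL,
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_bad("`grid_shape` must be three positive integers", "phantom_error")
  if (!is.null(particle_position)) {
    particle_position <- as.numeric(particle_position)
    if (length(particle_position) != 3L)
      stop_bad("`particle_position` must have three coordinates",
               "phantom_error")
  }
  structure(list(kind = kind, grid_shape = grid_shape,
                 particle_position = particle_position,
                 particle_value = particle_value,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

check_inside_grid <- function(pos, grid_shape) {
  if (any(pos < 1) || any(pos > grid_shape))
    stop_bad(sprintf(
      "particle position [%s] lies outside the grid [%s]",
      paste(pos, collapse = ", "), paste(grid_shape, collapse = ", ")),
      "phantom_error")
}

# Rasterise a small solid sphere into `vox` (modified copy returned). The
# center voxel carries the full value and the shell 95% of it, so the
# particle has a well-defined intensity peak at its nominal position.
add_sphere <- function(vox, center, radius, value) {
  lo <- pmax(1L, floor(center - radius))
  hi <- pmin(dim(vox), ceiling(center + radius))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- expand.grid(x = ix, y = iy, z = iz)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  sel <- d2 <= radius^2
  vox[cbind(g$x, g$y, g$z)[sel, , drop = FALSE]] <- 0.95 * value
  ctr <- pmin(pmax(round(center), 1L), dim(vox))
  vox[ctr[1], ctr[2], ctr[3]] <- value
  vox
}

#' Generate the fiducial-particle calibration phantom
#'
#' The calibration object used for rotation-axis alignment: an empty volume
#' containing one small high-attenuation sphere (radius ~1.5 voxels), as a
#' stand-in for a gold particle on a needle tip.
#'
#' @param spec a [phantom_spec()] with `kind = "particle_only"`.
#' @return A [new_volume()] object whose only nonzero voxels form the
#'   fiducial sphere.
#' @export
make_particle_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$kind != "particle_only")
    stop_bad("spec$kind must be 'particle_only'", "phantom_error")
  pos <- spec$particle_position
  if (is.null(pos))
    stop_bad("`particle_position` is required for the particle phantom",
             "phantom_error")
  check_inside_grid(pos, spec$grid_shape)
  value <- if (is.null(spec$particle_value)) 10 else spec$particle_value
  vox <- array(0, dim = spec$grid_shape)
  vox <- add_sphere(vox, pos, radius = 1.5, value = value)
  new_volume(vox)
}

# Sum of anisotropically placed Gaussian lumps, evaluated separably.
gaussian_lump_field <- function(grid_shape, n_lumps, center_spread,
                                sigma_range, seed) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ctr <- (grid_shape + 1) / 2
  f <- array(0, dim = grid_shape)
  withr::with_seed(seed, {
    for (k in seq_len(n_lumps)) {
      mu <- ctr + runif(3, -center_spread, center_spread) * grid_shape
      sg <- runif(3, sigma_range[1], sigma_range[2]) * grid_shape
      amp <- runif(1, 0.4, 1)
      gx <- exp(-((seq_len(nx) - mu[1])^2) / (2 * sg[1]^2))
      gy <- exp(-((seq_len(ny) - mu[2])^2) / (2 * sg[2]^2))
      gz <- exp(-((seq_len(nz) - mu[3])^2) / (2 * sg[3]^2))
      f <- f + amp * (gx %o% gy %o% gz)
    }
  })
  f
}

# Shift a volume by a (fractional) voxel offset with trilinear weights.
# Linear-interpolation shifts preserve total mass and move the centroid by
# exactly the requested offset (for support away from the array edge).
shift_volume <- function(vox, delta) {
  k <- floor(delta)
  f <- delta - k
  out <- array(0, dim = dim(vox))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    out <- out + w * shift_int(vox, k + c(cx, cy, cz))
  }
  out
}

shift_int <- function(vox, k) {
  d <- dim(vox)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (k[a] >= 0) {
      src[[a]] <- seq_len(d[a] - k[a])
      dst[[a]] <- src[[a]] + k[a]
    } else {
      src[[a]] <- (1 - k[a]):d[a]
      dst[[a]] <- seq_len(d[a] + k[a])
    }
    if (length(src[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vox[src[[1]], src[[2]], src[[3]]]
  out
}

volume_centroid <- function(vox) {
  m <- sum(vox)
  d <- dim(vox)
  idx <- function(a) {
    per <- switch(a, apply(vox, 1, sum), apply(vox, 2, sum),
                  apply(vox, 3, sum))
    sum(per * seq_len(d[a])) / m
  }
  c(idx(1), idx(2), idx(3))
}

#' Generate a lumpy blob phantom (with optional surface fiducial)
#'
#' A connected, asymmetric body built from a seeded sum of Gaussian lumps,
#' thresholded to compact support. It emulates a walnut-like full-field
#' specimen (`blob_with_particle`, carrying one strongly absorbing fiducial
#' on its surface) or a blocky low-resolution scanning specimen
#' (`lowres_blob`). The body is recentered (sub-voxel trilinear shift) so
#' its attenuation centroid coincides exactly with the volume center: motor
#' offsets are then the only displacement between sample and rotation axis.
#'
#' @param spec a [phantom_spec()] with `kind` `"blob_with_particle"` or
#'   `"lowres_blob"`.
#' @return A [new_volume()] object; deterministic for a fixed spec.
#' @export
make_blob_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$kind %in% c("blob_with_particle", "lowres_blob"))
    stop_bad("spec$kind must be 'blob_with_particle' or 'lowres_blob'",
             "phantom_error")
  gs <- spec$grid_shape
  lowres <- spec$kind == "lowres_blob"
  f <- gaussian_lump_field(
    gs,
    n_lumps = if (lowres) 6L else 8L,
    center_spread = if (lowres) 0.08 else 0.12,
    sigma_range = if (lowres) c(0.09, 0.14) else c(0.06, 0.11),
    seed = spec$rng_seed)
  thr <- 0.25 * max(f)
  vox <- ifelse(f > thr, f - thr, 0)   # smooth body, compact support
  if (lowres) {
    # block-average to emulate the coarse pixelation of scanning data
    vox <- block_pixelate(vox, 4L)
  }
  # recenter attenuation centroid onto the volume center
  ctr <- (gs + 1) / 2
  vox <- shift_volume(vox, ctr - volume_centroid(vox))
  vox[vox < 0] <- 0
  if (spec$kind == "blob_with_particle") {
    bg_max <- max(vox)
    value <- if (is.null(spec$particle_value)) 5 * bg_max
             else spec$particle_value
    if (value <= bg_max)
      stop_bad("particle_value must exceed the background maximum",
               "phantom_error")
    pos <- spec$particle_position
    if (is.null(pos))
      pos <- surface_point(vox, thr = 0.05 * bg_max, seed = spec$rng_seed)
    check_inside_grid(pos, gs)
    # shift the body (not the particle, which must stay crisp for
    # single-threshold extraction) so the combined centroid lands exactly
    # on the volume center
    delta <- c(0, 0, 0)
    final <- add_sphere(vox, pos, radius = 1.5, value = value)
    for (it in 1:3) {
      err <- ctr - volume_centroid(final)
      if (max(abs(err)) < 1e-3) break
      delta <- delta + err
      body <- shift_volume(vox, delta)
      body[body < 0] <- 0
      final <- add_sphere(body, pos, radius = 1.5, value = value)
    }
    vox <- final
  }
  new_volume(vox)
}

# Replace each b x b x b block by its mean (pixelated low-resolution look).
block_pixelate <- function(vox, b) {
  d <- dim(vox)
  dc <- floor(d / b)
  v <- vox[seq_len(dc[1] * b), seq_len(dc[2] * b), seq_len(dc[3] * b)]
  dim(v) <- c(b, dc[1], b, dc[2], b, dc[3])
  coarse <- apply(v, c(2, 4, 6), mean)
  out <- array(0, dim = d)
  out[seq_len(dc[1] * b), seq_len(dc[2] * b), seq_len(dc[3] * b)] <-
    coarse[rep(seq_len(dc[1]), each = b),
           rep(seq_len(dc[2]), each = b),
           rep(seq_len(dc[3]), each = b)]
  out
}

# First background voxel just outside the body along a seeded random ray
# from the volume center ("on the surface" placement).
surface_point <- function(vox, thr, seed) {
  d <- dim(vox)
  ctr <- (d + 1) / 2
  withr::with_seed(seed + 1L, {
    dir <- rnorm(3)
  })
  dir <- dir / sqrt(sum(dir^2))
  last_inside <- ctr
  for (t in seq(0, max(d), by = 0.5)) {
    p <- ctr + t * dir
    ip <- round(p)
    if (any(ip < 1) || any(ip > d)) break
    if (vox[ip[1], ip[2], ip[3]] > thr) last_inside <- p else if (t > 0) {
      return(pmin(pmax(round(p), 2), d - 1))
    }
  }
  pmin(pmax(round(last_inside), 2), d - 1)
}
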