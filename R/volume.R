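# Density-volume primitives. Grids are cubic 3D arrays stored in R's native
# column-major [x, y, z] layout (x fastest, matching the MRC on-disk order);
# the z axis is the rotation / symmetry axis and the tomogram normal.

#' Construct a density volume
#'
#' @param grid Cubic 3D numeric array indexed `[x, y, z]`; all values finite.
#' @param voxel Voxel size in Angstrom (> 0).
#' @param origin Length-3 origin offset in Angstrom.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3) {
    stop("`grid` must be a 3D array", call. = FALSE)
  }
  d <- dim(grid)
  if (d[1] != d[2] || d[2] != d[3]) stop("grid must be cubic", call. = FALSE)
  if (!is.numeric(voxel) || length(voxel) != 1 || !is.finite(voxel) || voxel <= 0) {
    stop("`voxel` must be a positive scalar (Angstrom)", call. = FALSE)
  }
  if (any(!is.finite(grid))) stop("grid values must be finite", call. = FALSE)
  structure(list(grid = grid, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_volume: %d x %d x %d voxels, %.3g A/voxel (%.4g A extent)\n",
              d[1], d[2], d[3], x$voxel, d[1] * x$voxel))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' Write a density volume as MRC (mode 2, float32)
#'
#' Writes a little-endian MRC2014 file with voxel size and origin recorded in
#' the header. Volumes containing non-finite values are refused.
#'
#' @param v A [density_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(v, path) {
  if (!inherits(v, "density_volume")) stop("`v` must be a density_volume", call. = FALSE)
  g <- v$grid
  if (any(!is.finite(g))) {
    stop("volume contains non-finite values; refusing to write", call. = FALSE)
  }
  n <- dim(g)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                         # nx ny nz
  wi(2L)                        # mode 2 = float32
  wi(c(0L, 0L, 0L))             # nxstart nystart nzstart
  wi(n)                         # mx my mz
  wf(n * v$voxel)               # cella
  wf(c(90, 90, 90))             # cellb
  wi(c(1L, 2L, 3L))             # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))
  wi(1L)                        # ispg (volume)
  wi(0L)                        # nsymbt
  wi(rep(0L, 25))               # extra
  wf(v$origin)                  # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(stats::sd(as.numeric(g)))
  wi(0L)                        # nlabl
  writeBin(raw(800), con)
  wf(as.numeric(g))
  invisible(path)
}

#' Read a density volume from MRC
#'
#' Accepts little-endian mode-2 (float32) MRC with the default axis order
#' (`mapc, mapr, maps = 1, 2, 3`); any other axis permutation is rejected
#' rather than silently reinterpreted. The voxel size is `cella / mx`.
#'
#' @param path Path to an MRC file.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (length(n) < 3 || any(!is.finite(n)) || any(n <= 0)) {
    stop("malformed MRC header: non-positive dimensions nx/ny/nz", call. = FALSE)
  }
  if (!identical(mode, 2L)) {
    stop("unsupported MRC mode ", mode, " (only mode 2, float32)", call. = FALSE)
  }
  ri(3)                          # nxstart..
  m <- ri(3)                     # mx my mz
  cella <- rf(3)
  rf(3)                          # cellb
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) {
    stop("malformed MRC header: axis permutation mapc/mapr/maps = ",
         paste(axes, collapse = ","), " is not supported", call. = FALSE)
  }
  rf(3)                          # dmin dmax dmean
  ri(1)                          # ispg
  nsymbt <- ri(1)
  ri(25)                         # extra
  origin <- rf(3)
  readBin(con, "raw", 8)         # MAP + machst
  rf(1)                          # rms
  ri(1)                          # nlabl
  readBin(con, "raw", 800)
  if (any(m <= 0) || any(cella <= 0)) {
    stop("malformed MRC header: zero cell dimensions mx/cella", call. = FALSE)
  }
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  dat <- rf(prod(n))
  if (length(dat) < prod(n)) stop("truncated MRC data block", call. = FALSE)
  density_volume(array(dat, dim = n), voxel = cella[1] / m[1], origin = origin)
}

# Catmull-Rom cubic weights for fractional offsets t in [0, 1)
cr_weights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  list(0.5 * (-t3 + 2 * t2 - t),
       0.5 * (3 * t3 - 5 * t2 + 2),
       0.5 * (-3 * t3 + 4 * t2 + t),
       0.5 * (t3 - t2))
}

# core z-rotation of a cubic grid; separable Catmull-Rom bicubic in (x, y)
# per z slice (z unchanged), fill = grid mean outside the sampled footprint.
# Cubic rather than linear interpolation keeps exact rotational symmetries
# of smooth maps at similarity ~0.999, which the symmetry-imposition scan
# relies on.
rotate_grid_z <- function(g, angle) {
  n <- dim(g)[1]
  th <- deg2rad(angle)
  ctr <- (n + 1) / 2
  dx <- rep(seq_len(n) - ctr, times = n)
  dy <- rep(seq_len(n) - ctr, each = n)
  xs <- cos(th) * dx + sin(th) * dy + ctr
  ys <- -sin(th) * dx + cos(th) * dy + ctr
  x0 <- floor(xs); y0 <- floor(ys)
  wx <- cr_weights(xs - x0)
  wy <- cr_weights(ys - y0)
  fill <- mean(g)
  M <- matrix(g, nrow = n * n)
  res <- matrix(0, n * n, n)
  for (i in 0:3) {
    xi <- x0 - 1 + i
    acc <- matrix(0, n * n, n)
    for (j in 0:3) {
      yj <- y0 - 1 + j
      ok <- xi >= 1 & xi <= n & yj >= 1 & yj <= n
      G <- matrix(fill, nrow = n * n, ncol = n)
      if (any(ok)) G[ok, ] <- M[xi[ok] + (yj[ok] - 1) * n, ]
      acc <- acc + wy[[j + 1]] * G
    }
    res <- res + wx[[i + 1]] * acc
  }
  array(res, dim = dim(g))
}

#' Rotate a volume about the grid-centre z axis
#'
#' Bilinear (per-slice trilinear degenerate) interpolation; samples falling
#' outside the grid are filled with the grid mean so that correlations are
#' not biased by zero padding. Positive angles are clockwise viewed from the
#' matrix (F1) side down the z axis.
#'
#' @param v A [density_volume()] with a cubic grid.
#' @param angle Rotation angle in degrees.
#' @return The rotated [density_volume()].
#' @export
rotate_about_z <- function(v, angle) {
  if (!inherits(v, "density_volume")) stop("`v` must be a density_volume", call. = FALSE)
  if (angle %% 360 == 0) return(v)
  density_volume(rotate_grid_z(v$grid, angle), v$voxel, v$origin)
}

#' Masked Pearson similarity of two volumes
#'
#' Pearson correlation over voxels, optionally weighted by a soft mask in
#' `[0, 1]` (a [mask_spec()] or a numeric array of matching shape).
#'
#' @param a,b [density_volume()] objects on identical grids and voxel sizes.
#' @param mask Optional [mask_spec()] or numeric weight array.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b, mask = NULL) {
  if (!inherits(a, "density_volume") || !inherits(b, "density_volume")) {
    stop("inputs must be density_volume objects", call. = FALSE)
  }
  if (!identical(dim(a$grid), dim(b$grid))) {
    stop("volume grids have mismatched shapes", call. = FALSE)
  }
  if (abs(a$voxel - b$voxel) > 1e-6 * a$voxel) {
    stop("volume voxel sizes differ", call. = FALSE)
  }
  w <- resolve_mask(mask, a)
  weighted_pearson(as.numeric(a$grid), as.numeric(b$grid), w)
}

resolve_mask <- function(mask, v) {
  if (is.null(mask)) return(NULL)
  if (inherits(mask, "mask_spec")) return(as.numeric(mask_array(mask, v)))
  if (is.array(mask)) {
    if (!identical(dim(mask), dim(v$grid))) {
      stop("mask array shape does not match the volume", call. = FALSE)
    }
    return(as.numeric(mask))
  }
  stop("`mask` must be NULL, a mask_spec, or a numeric array", call. = FALSE)
}

weighted_pearson <- function(x, y, w = NULL) {
  if (is.null(w)) {
    vx <- stats::var(x); vy <- stats::var(y)
    if (vx <= 0 || vy <= 0) {
      stop("similarity undefined: zero variance under the mask", call. = FALSE)
    }
    return(stats::cor(x, y))
  }
  sw <- sum(w)
  if (sw <= 0) stop("mask has zero total weight", call. = FALSE)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    stop("similarity undefined: zero variance under the mask", call. = FALSE)
  }
  cxy / sqrt(vx * vy)
}

#' Impose n-fold rotational symmetry about z
#'
#' Averages the volume over rotations by `360k/n` degrees, `k = 0..n-1`.
#' `n = 1` is the identity.
#'
#' @param v A [density_volume()].
#' @param n Symmetry order (integer >= 1).
#' @return The symmetrised [density_volume()].
#' @export
impose_symmetry <- function(v, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 1L) return(v)
  acc <- v$grid
  for (k in seq_len(n - 1L)) {
    acc <- acc + rotate_grid_z(v$grid, 360 * k / n)
  }
  density_volume(acc / n, v$voxel, v$origin)
}

#' Geometric soft mask specification
#'
#' Describes a spherical, cylindrical or z-slab region in Angstrom relative
#' to the grid centre, with an optional cosine-ramp soft edge of width
#' `soft` Angstrom. Realised on a grid by [mask_array()]; values in `[0, 1]`.
#'
#' @param kind One of `"sphere"`, `"cylinder"`, `"zslab"`.
#' @param radius Radius in Angstrom (sphere, cylinder).
#' @param half_height Half-height in z, Angstrom (cylinder; `Inf` = full).
#' @param zmin,zmax Slab bounds in Angstrom relative to the grid centre.
#' @param soft Soft-edge width in Angstrom (>= 0).
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(kind = c("sphere", "cylinder", "zslab"),
                      radius = NULL, half_height = Inf,
                      zmin = NULL, zmax = NULL, soft = 0) {
  kind <- match.arg(kind)
  if (soft < 0) stop("`soft` must be >= 0", call. = FALSE)
  if (kind %in% c("sphere", "cylinder")) {
    if (is.null(radius) || radius <= 0) {
      stop("`radius` (Angstrom) required for ", kind, call. = FALSE)
    }
  }
  if (kind == "zslab" && (is.null(zmin) || is.null(zmax) || zmin >= zmax)) {
    stop("`zmin` < `zmax` (Angstrom) required for zslab", call. = FALSE)
  }
  structure(list(kind = kind, radius = radius, half_height = half_height,
                 zmin = zmin, zmax = zmax, soft = soft),
            class = "mask_spec")
}

#' Realise a mask specification on a volume grid
#'
#' @param spec A [mask_spec()].
#' @param v The [density_volume()] providing grid geometry.
#' @return A numeric array in `[0, 1]` of the grid's shape.
#' @export
mask_array <- function(spec, v) {
  if (!inherits(spec, "mask_spec")) stop("`spec` must be a mask_spec", call. = FALSE)
  n <- dim(v$grid)[1]
  ax <- (seq_len(n) - (n + 1) / 2) * v$voxel
  d <- switch(spec$kind,
    sphere = {
      r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
      sqrt(r2) - spec$radius
    },
    cylinder = {
      rxy <- sqrt(outer(ax^2, ax^2, `+`))
      dr <- array(rxy, dim = c(n, n, n)) - spec$radius
      if (is.finite(spec$half_height)) {
        dz <- array(rep(abs(ax) - spec$half_height, each = n * n), dim = c(n, n, n))
        pmax(dr, dz)
      } else dr
    },
    zslab = {
      dz <- pmax(spec$zmin - ax, ax - spec$zmax)
      array(rep(dz, each = n * n), dim = c(n, n, n))
    }
  )
  if (spec$soft <= 0) {
    m <- (d <= 0) * 1.0
  } else {
    u <- pmin(pmax(d / spec$soft, 0), 1)
    m <- 0.5 * (1 + cos(pi * u))
    m[d <= 0] <- 1
  }
  array(m, dim = dim(v$grid))
}
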