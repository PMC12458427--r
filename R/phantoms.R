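# Phantom volumes: Gaussian-blob c-rings (for symmetry-order inference) and
# textured slabs (for ice-thickness estimation). Direct 3D densities; no
# tilt-series image formation, CTF or missing wedge.

#' Gaussian-blob c-ring phantom
#'
#' Places `n_sub` Gaussian blobs equally spaced on a circle of the given
#' radius, centred on the z axis at mid-height, plus optional white noise.
#' The default blob width (4 Angstrom sd) keeps neighbouring subunits of a
#' 10-fold ring at radius 30 A individually resolved (centre spacing
#' `2 r sin(pi/n)` ~ 18.5 A).
#'
#' @param n_sub Number of subunits (>= 1).
#' @param radius Ring radius in Angstrom.
#' @param blob_sd Gaussian blob sd in Angstrom.
#' @param box Cubic box size in voxels.
#' @param voxel Voxel size in Angstrom.
#' @param noise_sd White-noise sd in density units (blob peak = 1).
#' @param seed Optional integer seed for the noise.
#' @return A [density_volume()].
#' @export
make_cring_phantom <- function(n_sub = 10, radius = 30, blob_sd = 4,
                               box = 64, voxel = 2, noise_sd = 0,
                               seed = NULL) {
  if (n_sub < 1 || n_sub != round(n_sub)) {
    stop("`n_sub` must be an integer >= 1", call. = FALSE)
  }
  if (2 * radius + 4 * blob_sd >= box * voxel) {
    stop("ring exceeds the box: need 2*radius + 4*blob_sd < box*voxel",
         call. = FALSE)
  }
  set_local_seed(seed)
  ax <- (seq_len(box) - (box + 1) / 2) * voxel
  ang <- 2 * pi * (seq_len(n_sub) - 1) / n_sub
  g <- array(0, dim = c(box, box, box))
  gz <- exp(-ax^2 / (2 * blob_sd^2))
  for (k in seq_len(n_sub)) {
    gx <- exp(-(ax - radius * cos(ang[k]))^2 / (2 * blob_sd^2))
    gy <- exp(-(ax - radius * sin(ang[k]))^2 / (2 * blob_sd^2))
    g <- g + outer(outer(gx, gy), gz)
  }
  if (noise_sd > 0) g <- g + rnorm(length(g), 0, noise_sd)
  density_volume(g, voxel)
}

#' Cylindrical soft mask enclosing a c-ring
#'
#' Convenience mask for ring analyses: a soft-edged cylinder of radius
#' `radius + 3*blob_sd` and half-height `3*blob_sd` centred on the ring,
#' focusing similarity scores on the ring region (a global correlation over
#' a mostly empty box would be dominated by background noise).
#'
#' @param radius Ring radius in Angstrom.
#' @param blob_sd Subunit blob sd in Angstrom.
#' @param soft Soft-edge width in Angstrom.
#' @return A [mask_spec()].
#' @export
ring_mask <- function(radius = 30, blob_sd = 4, soft = 4) {
  mask_spec("cylinder", radius = radius + 3 * blob_sd,
            half_height = 3 * blob_sd, soft = soft)
}

#' Textured slab phantom for ice-thickness estimation
#'
#' A noise-textured slab of the requested z extent centred in the box, with a
#' flat zero background elsewhere — emulating the contrast profile of an ice
#' layer along the tomogram normal.
#'
#' @param thickness Slab thickness in nm.
#' @param box Cubic box size in voxels.
#' @param voxel Voxel size in Angstrom.
#' @param contrast Within-slab texture sd (density units).
#' @param seed Optional integer seed.
#' @return A [density_volume()].
#' @export
make_slab_volume <- function(thickness, box = 64, voxel = 10, contrast = 1,
                             seed = NULL) {
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0) {
    stop("`thickness` (nm) must be positive", call. = FALSE)
  }
  if (thickness > box * voxel / 10) {
    stop("`thickness` exceeds the box extent", call. = FALSE)
  }
  set_local_seed(seed)
  n_slices <- max(1L, round(thickness * 10 / voxel))
  lo <- floor((box - n_slices) / 2) + 1L
  hi <- lo + n_slices - 1L
  g <- array(0, dim = c(box, box, box))
  g[, , lo:hi] <- rnorm(box * box * n_slices, 0, contrast)
  density_volume(g, voxel)
}
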