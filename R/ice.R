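# Ice-thickness estimation from the contrast distribution along z, used to
# rank tomograms and keep only the thinnest (< 150 nm) for particle picking.

#' Per-slice contrast profile along z
#'
#' Robust spread (scaled median absolute deviation) of the intensities of
#' each z slice. Invariant to a global intensity offset; scales linearly
#' with a global intensity factor.
#'
#' @param v A [density_volume()].
#' @return Numeric vector of length `dim(v$grid)[3]`.
#' @export
z_contrast_profile <- function(v) {
  if (!inherits(v, "density_volume")) stop("`v` must be a density_volume", call. = FALSE)
  apply(v$grid, 3, stats::mad)
}

#' Estimate ice thickness from a z-contrast profile
#'
#' The background contrast baseline is the median of the outer 10% of slices
#' at each end; slices whose contrast exceeds the half-prominence threshold
#' `baseline + 0.5 * (peak - baseline)` count as ice. When the profile shows
#' no distinct background (peak - baseline below 25% of the peak) but real
#' contrast, the slab is taken to fill the whole extent; a zero-contrast
#' profile yields zero thickness with a `flat` flag.
#'
#' @param profile Per-slice contrast values from [z_contrast_profile()].
#' @param voxel Voxel (slice) size in Angstrom.
#' @return A list with `thickness_nm`, `n_slices` (slices counted as ice) and
#'   logical `flat`.
#' @export
estimate_ice_thickness <- function(profile, voxel) {
  if (!length(profile)) stop("profile must be non-empty", call. = FALSE)
  if (any(!is.finite(profile))) stop("profile must be finite", call. = FALSE)
  n <- length(profile)
  peak <- max(profile)
  if (peak <= 0) {
    return(list(thickness_nm = 0, n_slices = 0L, flat = TRUE))
  }
  k <- max(1L, floor(0.1 * n))
  baseline <- stats::median(c(profile[seq_len(k)], profile[n + 1 - seq_len(k)]))
  if ((peak - baseline) < 0.25 * peak) {
    # contrast everywhere: no resolvable background within the box
    return(list(thickness_nm = n * voxel / 10, n_slices = n, flat = FALSE))
  }
  thr <- baseline + 0.5 * (peak - baseline)
  cnt <- sum(profile > thr)
  list(thickness_nm = cnt * voxel / 10, n_slices = as.integer(cnt), flat = FALSE)
}
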