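# Shared fixtures: built in code at test time, no stored binaries.

# master seed for all Monte Carlo suites
MC_SEED <- 42L

# default ring-focused mask matching the default phantom geometry
default_ring_mask <- function() ring_mask(radius = 30, blob_sd = 4)

# small rotationally asymmetric reference for angle-assignment tests:
# a c3 blob ring plus an off-centre bump that breaks all rotational symmetry
make_asym_ref <- function(box = 32, voxel = 4) {
  v <- make_cring_phantom(n_sub = 3, radius = 24, blob_sd = 5,
                          box = box, voxel = voxel, noise_sd = 0)
  ax <- (seq_len(box) - (box + 1) / 2) * voxel
  bump <- outer(outer(exp(-(ax - 30)^2 / (2 * 6^2)),
                      exp(-ax^2 / (2 * 10^2))),
                exp(-ax^2 / (2 * 10^2)))
  v$grid <- v$grid + 0.8 * bump
  v
}

# signal sd of a volume inside a mask (for SNR-controlled noise levels)
masked_sd <- function(v, mask) {
  w <- mask_array(mask, v)
  x <- as.numeric(v$grid)[w > 0.5]
  stats::sd(x)
}

# brute-force 1-degree exhaustive rotation search (independent oracle for
# the coarse-to-fine estimator)
brute_force_angle <- function(particle, reference, mask = NULL) {
  angles <- 0:359
  scores <- vapply(angles, function(a) {
    pearson_similarity(rotate_about_z(reference, a), particle, mask)
  }, numeric(1))
  wrap_deg(angles[which.max(scores)])
}
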