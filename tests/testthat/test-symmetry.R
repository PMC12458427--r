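test_that("self-rotation curve starts at 1 and resolves ring periodicity", {
  v <- make_cring_phantom(10, 30, 4, 48, 2, noise_sd = 0.05, seed = 1)
  m <- default_ring_mask()
  curve <- self_rotation_curve(v, mask = m, step = 2)
  expect_equal(curve$scores[1], 1, tolerance = 1e-6)
  expect_length(curve$scores, 180)
  expect_error(self_rotation_curve(v, step = 7), "divide 360")

  mx <- count_evenly_spaced_maxima(curve)
  expect_equal(mx$count, 10)
  expect_true(all(abs(wrap_deg(mx$maxima_deg - round(mx$maxima_deg / 36) * 36)) <= 2))
})

test_that("minima counting finds the subunit count and nothing on flat curves", {
  m <- default_ring_mask()
  v6 <- make_cring_phantom(6, 30, 4, 48, 2, noise_sd = 0.05, seed = 2)
  mn <- count_evenly_spaced_minima(self_rotation_curve(v6, mask = m, step = 2))
  expect_equal(mn$count, 6)
  expect_lt(mn$spacing_cv, 0.1)

  const <- structure(list(step = 1, angles = 0:359, scores = rep(0.5, 360)),
                     class = "rotation_curve")
  expect_equal(count_evenly_spaced_minima(const)$count, 0)
})

test_that("minima count is invariant to intensity scaling and rigid rotation", {
  m <- default_ring_mask()
  v <- make_cring_phantom(6, 30, 4, 48, 2, noise_sd = 0.02, seed = 3)
  base <- count_evenly_spaced_minima(self_rotation_curve(v, mask = m, step = 2))

  scaled <- v; scaled$grid <- 5 * v$grid
  sc <- count_evenly_spaced_minima(self_rotation_curve(scaled, mask = m, step = 2))
  expect_equal(sc$count, base$count)

  rot <- rotate_about_z(v, 13)
  rc <- count_evenly_spaced_minima(self_rotation_curve(rot, mask = m, step = 2))
  expect_equal(rc$count, base$count)
})

test_that("noiseless divisors score highly yet the largest-order rule returns N", {
  m <- default_ring_mask()
  for (N in c(3, 5, 6, 10)) {
    v <- make_cring_phantom(N, 30, 4, 48, 2, noise_sd = 0)
    scan <- symmetry_order_scan(v, mask = m)
    expect_equal(scan$scores[1], 1, tolerance = 1e-6)
    divisors <- setdiff(which(N %% seq_len(15) == 0), 1)
    expect_true(all(scan$scores[divisors] >= 0.99))
    expect_equal(scan$best, N)
    inf <- infer_order(scan, self_rotation_curve(v, mask = m, step = 2))
    expect_true(inf$agreement)
    expect_equal(inf$order, N)
  }
})

test_that("the inferred order of a 10-fold ring survives noise at SNR >= 5", {
  m <- default_ring_mask()
  clean <- make_cring_phantom(10, 30, 4, 48, 2, noise_sd = 0)
  noise_sd <- masked_sd(clean, m) / 5
  for (s in MC_SEED + seq_len(10)) {
    v <- make_cring_phantom(10, 30, 4, 48, 2, noise_sd = noise_sd, seed = s)
    inf <- infer_order(symmetry_order_scan(v, mask = m),
                       self_rotation_curve(v, mask = m, step = 2))
    expect_equal(inf$order, 10)
  }
})

test_that("an asymmetric single blob triggers the disagreement flag", {
  v <- make_cring_phantom(1, 30, 4, 48, 2, noise_sd = 0.02, seed = 4)
  m <- default_ring_mask()
  inf <- infer_order(symmetry_order_scan(v, mask = m),
                     self_rotation_curve(v, mask = m, step = 2))
  expect_false(inf$agreement)
  expect_true(is.na(inf$order))
})
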