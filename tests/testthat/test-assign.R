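test_that("rotation estimate recovers known angles and matches the 1-degree oracle", {
  ref <- make_asym_ref()
  expect_lt(abs(estimate_rotation_cc(ref, ref)$angle), 1)   # self at 0

  for (a in c(37, -77.2, 123.4)) {
    p <- rotate_about_z(ref, a)
    est <- estimate_rotation_cc(p, ref)
    expect_lt(abs(wrap_deg(est$angle - a)), 1)
    oracle <- brute_force_angle(p, ref)
    expect_lte(abs(wrap_deg(est$angle - oracle)), 1)
  }
})

test_that("the estimator is equivariant under rigid rotation of the particle", {
  ref <- make_asym_ref()
  p <- rotate_about_z(ref, 37)
  base <- estimate_rotation_cc(p, ref)$angle
  for (delta in c(10, 90, 200)) {
    shifted <- estimate_rotation_cc(rotate_about_z(p, delta), ref)$angle
    expect_lt(abs(wrap_deg(shifted - base - delta)), 1.5)
  }
})

test_that("parabolic refinement stays within one coarse step of the grid peak", {
  ref <- make_asym_ref()
  for (a in c(11.3, 200.8)) {
    p <- rotate_about_z(ref, a)
    coarse <- estimate_rotation_cc(p, ref, refine = FALSE)
    fine <- estimate_rotation_cc(p, ref, refine = TRUE)
    expect_lte(abs(wrap_deg(fine$angle - coarse$angle)), 2)
    expect_lte(abs(wrap_deg(coarse$angle - a)), 1 + 1e-9)   # bounded by step/2
  }
})

test_that("flat correlation input yields an undefined-angle error", {
  flat <- density_volume(array(1, c(16, 16, 16)), 4)
  ref <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 4)
  expect_error(estimate_rotation_cc(flat, ref), "zero variance|flat")
})

test_that("ensemble assignment recovers construction angles within 2 degrees", {
  ref <- make_asym_ref()
  truth <- c(-150, -60, -10, 0, 25, 90, 170)
  particles <- lapply(truth, function(a) rotate_about_z(ref, a))
  names(particles) <- paste0("p", seq_along(truth))
  masks <- list(f1 = mask_spec("cylinder", radius = 60, soft = 4),
                stalk = mask_spec("cylinder", radius = 60, soft = 4))
  tab <- assign_ensemble(particles, ref, masks)
  expect_equal(nrow(tab), length(truth))
  expect_true(all(abs(wrap_deg(tab$theta_f1 - truth)) <= 2))
  expect_true(all(tab$flag == ""))

  expect_error(assign_ensemble(list(), ref, masks), "empty")
  dup <- particles[c(1, 1)]
  names(dup) <- c("a", "a")
  expect_error(assign_ensemble(dup, ref, masks), "duplicate")
})

test_that("angular error stays below 10 degrees at SNR 1", {
  ref <- make_asym_ref()
  mask <- mask_spec("cylinder", radius = 60, soft = 4)
  sig <- masked_sd(ref, mask)
  set.seed(MC_SEED)
  truth <- runif(40, -180, 180)
  particles <- lapply(truth, function(a) {
    p <- rotate_about_z(ref, a)
    p$grid <- p$grid + array(rnorm(length(p$grid), 0, sig), dim(p$grid))
    p
  })
  names(particles) <- paste0("p", seq_along(truth))
  tab <- assign_ensemble(particles, ref, list(f1 = mask, stalk = mask))
  err <- wrap_deg(tab$theta_f1 - truth)
  expect_lte(sd(err), 10)
})
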