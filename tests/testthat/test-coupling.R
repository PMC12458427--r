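test_that("stalk binning produces the 18-degree grid and conserves particles", {
  tab <- make_particle_table(500, seed = 1)
  bins <- bin_by_stalk(tab, 20)
  expect_true(all(diff(bins$bin_edges) == 18))
  expect_equal(sum(bins$bin_n), nrow(tab))

  one <- bin_by_stalk(tab, 1)
  expect_equal(one$bin_n, nrow(tab))
  expect_error(bin_by_stalk(tab, 7), "divide 360")

  # boundary particles land in left-closed bins; 180 goes to the last bin
  edge <- data.frame(theta_stalk = c(-180 + 1e-9, 0, 180), theta_f1 = c(1, 2, 3))
  b <- bin_by_stalk(edge, 20)
  expect_equal(b$bin_index, c(1, 11, 20))
})

test_that("KS of a sample against itself gives D = 0, p = 1 exactly", {
  x <- sample_f1_angles(2000, seed = 2)
  p <- ks_bins_vs_reference(list(x), x)
  expect_identical(p, 1)
  expect_true(is.na(ks_bins_vs_reference(list(numeric()), x)))
  expect_error(ks_bins_vs_reference(list(x), numeric()), "non-empty")
})

test_that("sinusoid fit is exact on noiseless data and degenerate-safe", {
  th <- sample_stalk_angles(500, seed = 2)
  fit <- fit_sinusoid(th, couple_f1_to_stalk(th, 10, 40), n_perm = 0)
  expect_lt(abs(fit$a - 10), 1e-9)
  expect_lt(abs(fit$b - 40), 1e-9)

  flatfit <- fit_sinusoid(th, rep(2, length(th)), n_perm = 0)
  expect_lt(flatfit$a, 1e-9)

  expect_error(fit_sinusoid(rep(10, 50), rnorm(50), n_perm = 0), "degenerate")
  expect_error(fit_sinusoid(1:5, 1:4), "equal length")
})

test_that("amplitude and phase are recovered within 1 degree under noise", {
  set.seed(MC_SEED)
  errs <- sapply(c(10, 20, 30), function(a) {
    est <- replicate(10, {
      th <- sample_stalk_angles(19262)
      f1 <- wrap_deg(couple_f1_to_stalk(th, a, 40) + rnorm(19262, 0, 8.07))
      fit_sinusoid(th, f1, n_perm = 0)$a
    })
    abs(mean(est) - a)
  })
  expect_true(all(errs <= 1))
})

test_that("chord angular resolution matches its closed form", {
  expect_equal(angular_resolution_deg(10, 30), 2 * asin(10 / 60) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(round(angular_resolution_deg(10, 30)), 19)
  expect_equal(angular_resolution_deg(20, 10), 180, tolerance = 1e-9)
  expect_equal(angular_resolution_deg(15, 15), 60, tolerance = 1e-9)
  expect_error(angular_resolution_deg(25, 10), "geometry")
  expect_error(angular_resolution_deg(-1, 10), "positive")
})

test_that("detection power is monotone in the coupling amplitude", {
  pw <- detection_power(c(0, 2, 20), bin_sizes = rep(100L, 20), reps = 100,
                        n_perm = 99, seed = MC_SEED)
  expect_true(all(diff(pw$power) >= 0))
  expect_lte(pw$power[1], 0.1)
  expect_gte(pw$power[3], 0.95)
  expect_error(detection_power(10, reps = 50), "at least 100")
})

test_that("the combined coupling test detects strong coupling and not the null", {
  coupled_cfg <- generator_config(coupling_a = 25)
  tab_c <- make_particle_table(2000, coupled_cfg, seed = 11)
  res_c <- coupling_test(tab_c, n_perm = 199, seed = 12)
  expect_equal(res_c$decision, "coupled")
  expect_lt(res_c$sinusoid$permutation_p, 0.05)
  expect_lt(abs(res_c$sinusoid$a - 25), 3)

  tab_0 <- make_particle_table(2000, seed = 13)
  res_0 <- coupling_test(tab_0, n_perm = 199, seed = 14)
  expect_equal(res_0$decision, "not_detected")
  expect_equal(sum(res_0$bin_n), nrow(tab_0))
})
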