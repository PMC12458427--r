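test_that("F1-head angle generator matches its 95%-interval calibration", {
  th <- sample_f1_angles(22630, seed = 1)
  q <- quantile(th, c(0.025, 0.975), names = FALSE)
  half <- mean(abs(q))
  expect_lt(abs(half - 19), 0.5)
  expect_equal(round(half), 19)

  expect_equal(sample_f1_angles(5, sd = 0), rep(0, 5))
  expect_error(sample_f1_angles(-1), "non-negative")
  expect_error(sample_f1_angles(10, sd = -2), "non-negative")
})

test_that("central-stalk mixture places its modes at -120, 0, 120", {
  st <- sample_stalk_angles(22630, seed = 1)
  modes <- find_angle_modes(st, bin_width = 5)
  expect_length(modes, 3)
  expect_true(all(abs(wrap_deg(modes - c(-120, 0, 120))) < 5))

  exact <- sample_stalk_angles(200, sds = c(0, 0, 0), seed = 2)
  expect_true(all(exact %in% c(0, 120, -120)))

  one <- sample_stalk_angles(1000, weights = c(1, 0, 0), seed = MC_SEED)
  expect_true(all(abs(one) <= 4 * 3.75))
  expect_lt(abs(circ_mean_deg(one)), 0.5)

  expect_error(sample_stalk_angles(10, modes = c(0, 10), sds = 1,
                                   weights = c(0.5, 0.5)), "equal length")
  expect_error(sample_stalk_angles(10, weights = c(1, 1, 1)), "sum to 1")
})

test_that("tri-periodic coupling offset is analytic and 120-degree periodic", {
  expect_equal(couple_f1_to_stalk(c(-50, 0, 90), a = 0), c(0, 0, 0))
  expect_equal(couple_f1_to_stalk(30, a = 10, b = 0), 10)
  th <- seq(-180, 180, by = 7.5)
  expect_equal(couple_f1_to_stalk(th, 10, 25),
               couple_f1_to_stalk(th + 120, 10, 25), tolerance = 1e-12)
})

test_that("wrapped measurement noise respects the wrap contract and its sd", {
  x <- c(-179.5, 0, 90, 179)
  expect_equal(add_wrapped_noise(x, sd = 0), x)
  y <- add_wrapped_noise(rep(179, 5000), sd = 30, seed = MC_SEED)
  expect_true(all(y > -180 & y <= 180))

  base <- rep(0, 200000)
  noisy <- add_wrapped_noise(base, sd = 8.07, seed = MC_SEED)
  expect_lt(abs(circ_sd_deg(noisy) - 8.07) / 8.07, 0.02)
})

test_that("UPS ensemble reproduces both displacement/rotation anchors", {
  u <- sample_ups_ensemble(22630, seed = 1)
  span <- max(u$ups_disp) - min(u$ups_disp)
  expect_gte(span, 6.8)
  expect_lte(span, 7.0)

  # truncated-normal quantile oracle for the middle-95% span
  cfg <- generator_config()
  lo <- pnorm(-cfg$ups_trunc, 0, cfg$ups_sd)
  oracle <- 2 * qnorm(0.975 * (1 - 2 * lo) + lo, 0, cfg$ups_sd)
  q <- quantile(u$ups_disp, c(0.025, 0.975), names = FALSE)
  expect_lt(abs((q[2] - q[1]) - oracle), 0.1)
  expect_gte(q[2] - q[1], 4.8)
  expect_lte(q[2] - q[1], 5.2)

  expect_equal(ups_coupling_g(0), 0)
  expect_equal(ups_coupling_g(c(-2, 2)), c(-2.4, 2.4))      # odd, inner slope
  expect_equal(ups_coupling_g(c(2.5, 3.5)), c(3.0, 3.25))   # knee and bound
})

test_that("dimer tables pair independent monomers and are reproducible", {
  t100 <- make_particle_table(100, seed = 3)
  expect_equal(nrow(t100), 200)
  expect_true(all(table(t100$dimer_id) == 2))

  big <- make_particle_table(10000, seed = 6)
  m0 <- big[big$monomer_index == 0, ]
  m1 <- big[big$monomer_index == 1, ]
  expect_lt(abs(cor(m0$theta_f1, m1$theta_f1)), 0.03)

  copy <- make_particle_table(50, generator_config(intradimer_correlation = 1),
                              seed = 4)
  c0 <- copy[copy$monomer_index == 0, ]
  c1 <- copy[copy$monomer_index == 1, ]
  expect_equal(c0$theta_f1, c1$theta_f1)
  expect_equal(c0$theta_stalk, c1$theta_stalk)

  expect_identical(make_particle_table(200, seed = 9),
                   make_particle_table(200, seed = 9))
})

test_that("generator configuration enforces its invariants", {
  expect_error(generator_config(stalk_weights = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(generator_config(stalk_weights = c(-0.2, 0.6, 0.6)),
               "non-negative")
  expect_error(generator_config(f1_sd = -1), "non-negative")
  expect_error(generator_config(stalk_sds = c(1, 2)), "equal length")
})

test_that("particle tables survive a TSV round trip and reject bad rows", {
  tab <- make_particle_table(40, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_particle_table(tab, path)
  back <- read_particle_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  bad <- as.data.frame(tab)
  bad$theta_f1[1] <- 270
  expect_error(particle_table(bad), "-180, 180")
  bad2 <- as.data.frame(tab)
  bad2$particle_id[2] <- bad2$particle_id[1]
  expect_error(particle_table(bad2), "duplicate")
  bad3 <- as.data.frame(tab)
  bad3$monomer_index[2] <- 0L
  expect_error(particle_table(bad3), "monomer_index")
})
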