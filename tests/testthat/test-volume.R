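test_that("MRC write/read round trip preserves grid, voxel and origin", {
  v <- make_cring_phantom(6, 30, 4, 32, 4, noise_sd = 0.1, seed = 3)
  v$origin <- c(-12.5, 4, 0)
  path <- tempfile(fileext = ".mrc")
  write_mrc(v, path)
  back <- read_mrc(path)
  expect_equal(back$grid, v$grid, tolerance = 1e-6)
  expect_equal(back$voxel, 4)
  expect_equal(back$origin, v$origin, tolerance = 1e-6)

  # after one float32 pass the data are exactly representable
  write_mrc(back, path)
  again <- read_mrc(path)
  expect_identical(again$grid, back$grid)
})

test_that("MRC I/O rejects missing files, bad values and foreign headers", {
  expect_error(read_mrc(tempfile()), "not found")

  v <- make_cring_phantom(4, 20, 4, 16, 4)
  v$grid[1] <- NaN
  expect_error(write_mrc(v, tempfile()), "non-finite")

  good <- make_cring_phantom(4, 20, 4, 16, 4)
  path <- tempfile(fileext = ".mrc")
  write_mrc(good, path)
  raw_bytes <- readBin(path, "raw", file.size(path))

  mode1 <- raw_bytes
  mode1[13:16] <- writeBin(1L, raw(), size = 4, endian = "little")
  p1 <- tempfile(); writeBin(mode1, p1)
  expect_error(read_mrc(p1), "mode")

  perm <- raw_bytes                          # mapc at header word 17
  perm[65:68] <- writeBin(2L, raw(), size = 4, endian = "little")
  p2 <- tempfile(); writeBin(perm, p2)
  expect_error(read_mrc(p2), "axis permutation")
})

test_that("z rotation is exact at 0/90 degrees and invertible elsewhere", {
  v <- make_cring_phantom(6, 30, 6, 32, 4, noise_sd = 0)
  expect_identical(rotate_about_z(v, 0)$grid, v$grid)

  r <- v
  for (k in 1:4) r <- rotate_about_z(r, 90)
  expect_gt(pearson_similarity(r, v), 0.999)

  expect_gt(pearson_similarity(rotate_about_z(v, 60), v), 0.99)  # c6 symmetry

  for (a in c(30, 137, 180)) {
    back <- rotate_about_z(rotate_about_z(v, a), -a)
    expect_gt(pearson_similarity(back, v), 0.995)
  }
})

test_that("pearson similarity obeys its fixed points and null level", {
  v <- make_cring_phantom(5, 28, 4, 32, 4, noise_sd = 0.02, seed = 6)
  expect_equal(pearson_similarity(v, v), 1)
  neg <- v; neg$grid <- -v$grid
  expect_equal(pearson_similarity(v, neg), -1)

  set.seed(MC_SEED)
  n1 <- density_volume(array(rnorm(64^3), c(64, 64, 64)), 2)
  n2 <- density_volume(array(rnorm(64^3), c(64, 64, 64)), 2)
  expect_lt(abs(pearson_similarity(n1, n2)), 0.02)

  small <- density_volume(array(0, c(8, 8, 8)) + 1, 2)
  expect_error(pearson_similarity(small, small), "zero variance")
  other <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 2)
  expect_error(pearson_similarity(other, n1), "mismatched shapes")
})

test_that("symmetry imposition symmetrises, is idempotent, favours the true order", {
  v <- make_cring_phantom(10, 30, 4, 48, 2, noise_sd = 0.02, seed = 7)
  m <- default_ring_mask()
  expect_identical(impose_symmetry(v, 1)$grid, v$grid)
  expect_error(impose_symmetry(v, 0), ">= 1")

  s5 <- impose_symmetry(v, 5)
  expect_gt(pearson_similarity(rotate_about_z(s5, 72), s5, m), 0.999)

  twice <- impose_symmetry(s5, 5)
  expect_gt(pearson_similarity(twice, s5, m), 0.999)

  expect_gt(pearson_similarity(impose_symmetry(v, 10), v, m),
            pearson_similarity(impose_symmetry(v, 7), v, m))
})

test_that("geometric masks stay within [0, 1] and match their geometry", {
  v <- make_cring_phantom(3, 20, 4, 32, 4)
  for (spec in list(mask_spec("sphere", radius = 40, soft = 8),
                    mask_spec("cylinder", radius = 30, half_height = 20, soft = 6),
                    mask_spec("zslab", zmin = -20, zmax = 20, soft = 4))) {
    m <- mask_array(spec, v)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m[17, 17, 17], 1)      # grid centre inside every region
  }
  hard <- mask_array(mask_spec("sphere", radius = 24), v)
  expect_true(all(hard %in% c(0, 1)))
  expect_error(mask_spec("zslab", zmin = 5, zmax = -5), "zmin")
})
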