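test_that("NIfTI round-trip preserves data, spacing and affine", {
  a <- array(rnorm(16 * 20 * 24, 0, 100), c(16, 20, 24))
  v <- ct_volume(a, spacing = c(2.5, 0.8, 0.8))
  f <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(f))
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, a, tolerance = 1e-6)
  expect_equal(v2$spacing, c(2.5, 0.8, 0.8), tolerance = 1e-6)
  expect_error(read_volume(tempfile()), "no such file")
})

test_that("labeled-range cropping keeps exactly the annotated slab", {
  a <- array(0, c(30, 8, 8))
  lab <- array(0L, c(30, 8, 8))
  lab[11:21, 4, 4] <- 1L
  cr <- crop_to_labeled_range(ct_volume(a), lab)
  expect_identical(dim(cr$labels)[1], 11L)
  expect_identical(sum(cr$labels != 0), sum(lab != 0))

  lab_all <- array(1L, c(30, 8, 8))
  cr2 <- crop_to_labeled_range(ct_volume(a), lab_all)
  expect_identical(dim(cr2$labels), dim(lab_all))

  expect_error(crop_to_labeled_range(ct_volume(a), array(0L, c(30, 8, 8))),
               "no nonzero")
})

test_that("windowing clips to the configured HU range and is idempotent", {
  w <- window_spec()
  v <- ct_volume(array(c(-1000, 0, 100, 1000, rep(50, 12)), c(4, 2, 2)))
  out <- apply_window(v, w)
  expect_equal(out$data[1:4], c(-30, 0, 100, 170))
  expect_true(all(out$data >= -30 & out$data <= 170))
  expect_equal(apply_window(out, w)$data, out$data)
  # monotone
  x <- sort(rnorm(100, 0, 300))
  wx <- apply_window(ct_volume(array(x, c(100, 1, 1))), w)$data
  expect_true(all(diff(as.numeric(wx)) >= 0))
  expect_error(window_spec(10, 10))
})

test_that("normalization maps the window to [0, 1] linearly", {
  w <- window_spec()
  v <- ct_volume(array(c(-30, 70, 170, rep(20, 5)), c(8, 1, 1)))
  nz <- normalize01(v, w)
  expect_equal(nz$data[1:3], c(0, 0.5, 1))
  con <- normalize01(ct_volume(array(50, c(4, 4, 4))), w)
  expect_equal(max(con$data) - min(con$data), 0)
})

test_that("in-plane resizing respects label value sets and identity", {
  cs <- tiny_case()
  v <- ct_volume(cs$image)
  r <- resize_inplane(v, 16)
  expect_identical(dim(r$data), c(16L, 16L, 16L))
  expect_equal(r$spacing[2], v$spacing[2] * dim(v$data)[2] / 16)
  # labels: nearest neighbor preserves the value set
  rl <- resize_inplane(cs$labels, 16, is_label = TRUE)
  expect_true(all(rl %in% cs$labels))
  # identity when already at the target size
  same <- resize_inplane(v, dim(v$data)[2])
  expect_identical(same$data, v$data)
})

test_that("depth padding reaches a multiple of 16 and un-pads exactly", {
  for (d in c(5L, 16L, 23L, 33L)) {
    a <- array(rnorm(d * 4 * 4), c(d, 4, 4))
    p <- pad_depth(a)
    expect_identical(dim(p)[1] %% 16L, 0L)
    expect_gte(dim(p)[1], d)
    expect_identical(unpad_depth(p), a)
  }
})

test_that("the full preprocessing pipeline yields [0,1] arrays of the target shape", {
  for (seed in c(1L, 2L)) {
    ph <- make_phantom(phantom_config(shape = c(20L, 32L, 32L),
                                      liver_axes = c(6, 11, 11),
                                      tumor_radius_range = c(2, 3.5),
                                      seed = seed))
    pp <- preprocess_case(ph$volume, ph$labels, target = 16)
    expect_true(all(is.finite(pp$volume$data)))
    expect_true(all(pp$volume$data >= 0 & pp$volume$data <= 1))
    expect_identical(dim(pp$volume$data)[2:3], c(16L, 16L))
    expect_identical(dim(pp$volume$data), dim(pp$labels))
  }
})
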