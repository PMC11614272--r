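test_that("projection K = Max + Mean has the documented shape and algebra", {
  set.seed(1)
  x <- array(rnorm(3 * 5 * 6 * 7), c(3, 5, 6, 7))
  expect_identical(dim(project_kq(x, "axial")), c(3L, 6L, 7L))
  expect_identical(dim(project_kq(x, "sagittal")), c(3L, 5L, 6L))
  expect_identical(dim(project_kq(x, "coronal")), c(3L, 5L, 7L))

  # constant input: max = mean = c, so K = 2c
  xc <- array(2.5, c(2, 4, 4, 4))
  expect_equal(unname(project_kq(xc, "axial")[1, 1, 1]), 5)

  # K - mean-reduction = max-reduction >= mean-reduction, elementwise
  mean_red <- apply(x, c(1, 3, 4), mean)
  max_red <- apply(x, c(1, 3, 4), max)
  K <- project_kq(x, "axial")
  expect_equal(K, max_red + mean_red, tolerance = 1e-12)
  expect_true(all(K - mean_red >= mean_red))
})

test_that("FP block with zeroed parameters equals the per-channel spatial mean", {
  set.seed(2)
  x <- array(rnorm(4 * 6 * 8 * 8), c(4, 6, 8, 8))
  for (axis in c("axial", "sagittal", "coronal")) {
    blk <- fp_block(4, axis)
    for (s in cganseg:::module_parameters(blk))
      s$env$params[[s$name]][] <- 0
    g <- fp_forward(x, blk)
    expect_identical(dim(g), c(4L, 1L, 1L, 1L))
    brute <- sapply(1:4, function(c) mean(x[c, , , ]))
    expect_equal(as.numeric(g), brute, tolerance = 1e-12)
    # linearity of the zero-weight path
    g2 <- fp_forward(2 * x, blk)
    expect_equal(as.numeric(g2), 2 * brute, tolerance = 1e-12)
  }
})

test_that("fusion weights live on the probability simplex", {
  fw <- normalize_fusion_weights(c(0, 0, 0))
  expect_equal(fw$weights, rep(1 / 3, 3))
  fw2 <- normalize_fusion_weights(c(10, -30, -30))
  expect_gt(fw2$weights[1], 1 - 1e-6)
  for (i in 1:20) {
    w <- normalize_fusion_weights(rnorm(3, 0, 5))$weights
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-6)
  }
  expect_error(normalize_fusion_weights(c(NaN, 0, 0)), "finite")
})

test_that("MA fusion preserves shape and obeys the simplex identity", {
  set.seed(3)
  for (i in 1:4) {
    dims <- c(sample(2:4, 1), sample(c(4L, 6L), 1), sample(c(4L, 8L), 1),
              sample(c(4L, 6L), 1))
    x <- array(rnorm(prod(dims)), dims)
    blk <- ma_block(dims[1])
    y <- ma_forward(x, blk)
    expect_identical(dim(y), dims)
  }
  # x = 0 maps to 0
  blk <- ma_block(2)
  expect_equal(ma_forward(array(0, c(2, 4, 4, 4)), blk),
               array(0, c(2, 4, 4, 4)))
  # all-one gates make y = x for any beta on the simplex: force them by
  # zeroing FP parameters and adding 1 - mean(x) per channel is awkward, so
  # check the algebraic identity directly at the fusion level
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  beta <- normalize_fusion_weights(rnorm(3))$weights
  gates <- list(rep(1, 2), rep(1, 2), rep(1, 2))
  y <- 0
  for (i in 1:3) y <- y + beta[i] * gates[[i]] * x
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("simplex constraint survives optimizer updates and gradients flow", {
  set.seed(4)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  blk <- ma_block(2)
  opt <- optim_adamw(blk, lr = 1e-2)
  target <- array(rnorm(prod(dim(x))), dim(x))
  for (step in 1:5) {
    cganseg:::zero_grad(blk)
    y <- nn_forward(blk, x, train = TRUE)
    nn_backward(blk, 2 * (y - target))
    optim_step(opt)
    w <- fusion_weights(blk)$weights
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
  # gradient flow: every parameter of the block received a nonzero gradient
  cganseg:::zero_grad(blk)
  y <- nn_forward(blk, x, train = TRUE)
  nn_backward(blk, 2 * (y - target))
  gr <- vapply(cganseg:::module_parameters(blk),
               function(s) max(abs(s$env$grads[[s$name]])), numeric(1))
  expect_true(all(is.finite(gr)))
  expect_true(all(gr > 0))
})
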