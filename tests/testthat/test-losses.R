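test_that("Tversky index matches hand-computed cases and the loop oracle", {
  p <- tversky_params(0.7, 0.3)
  # perfect binary prediction
  y <- c(1, 1, 0, 0)
  expect_equal(tversky_index(y, y, p), 1, tolerance = 1e-6)
  # TP=1, FP=1, FN=1 at alpha 0.7 / beta 0.3: 1 / (1 + 0.7 + 0.3) = 0.5
  g <- c(1, 0, 1, 0)
  expect_equal(tversky_index(y, g, p), 0.5, tolerance = 1e-6)
  expect_equal(tversky_loss(y, g, p), 0.5, tolerance = 1e-6)
  expect_equal(tversky_loss(y, y, p), 0, tolerance = 1e-6)

  # loop oracle on 100 random soft predictions
  set.seed(10)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    yy <- as.numeric(runif(n) < 0.4)
    gg <- runif(n)
    a <- runif(1); b <- runif(1)
    expect_equal(tversky_index(yy, gg, tversky_params(a, b)),
                 oracle_tversky(yy, gg, a, b), tolerance = 1e-10)
  }
})

test_that("alpha = beta = 0.5 reduces Tversky to soft Dice", {
  set.seed(11)
  soft_dice <- function(y, g) {
    tp <- sum(y * g); fp <- sum((1 - y) * g); fn <- sum(y * (1 - g))
    2 * tp / (2 * tp + fp + fn)
  }
  for (i in 1:20) {
    y <- as.numeric(runif(50) < 0.5)
    g <- runif(50)
    expect_equal(tversky_index(y, g, tversky_params(0.5, 0.5, smooth = 1e-12)),
                 soft_dice(y, g), tolerance = 1e-8)
  }
})

test_that("Tversky is permutation-invariant, duplication-invariant and monotone", {
  set.seed(12)
  p <- tversky_params()
  y <- as.numeric(runif(40) < 0.4)
  g <- runif(40)
  o <- sample(40)
  expect_equal(tversky_index(y[o], g[o], p), tversky_index(y, g, p))
  expect_equal(tversky_index(rep(y, 2), rep(g, 2), p),
               tversky_index(y, g, p), tolerance = 1e-6)
  # raising g on a true-foreground voxel never lowers the index
  i1 <- which(y == 1)[1]
  g_up <- g; g_up[i1] <- min(1, g[i1] + 0.2)
  expect_gte(tversky_index(y, g_up, p), tversky_index(y, g, p))
  # raising g on a background voxel never raises it
  i0 <- which(y == 0)[1]
  g_bg <- g; g_bg[i0] <- min(1, g[i0] + 0.2)
  expect_lte(tversky_index(y, g_bg, p), tversky_index(y, g, p))
})

test_that("tversky_loss gradient matches finite differences", {
  set.seed(13)
  p <- tversky_params()
  y <- as.numeric(runif(30) < 0.4)
  g <- runif(30, 0.05, 0.95)
  an <- cganseg:::tversky_loss_grad(y, g, p)
  h <- 1e-6
  for (i in sample(30, 6)) {
    gp <- g; gp[i] <- gp[i] + h
    gm <- g; gm[i] <- gm[i] - h
    num <- (tversky_loss(y, gp, p) - tversky_loss(y, gm, p)) / (2 * h)
    expect_equal(an[i], num, tolerance = 1e-5)
  }
})

test_that("adversarial losses match their closed forms in both modes", {
  # no-log mode: optimum and indifference points
  expect_equal(discriminator_loss(1, 0, "nolog"), -1)
  expect_equal(discriminator_loss(0.37, 0.37, "nolog"), 0)
  # bce at 0.5/0.5 scores 2 ln 2 per sample
  expect_equal(discriminator_loss(0.5, 0.5, "bce"), 2 * log(2),
               tolerance = 1e-6)
  expect_error(discriminator_loss(numeric(0), 0.5), "empty")

  # generator: perfect prediction and fooled discriminator
  y <- c(1, 0, 1, 1)
  expect_equal(generator_loss(1, y, y, mode = "nolog"), -1, tolerance = 1e-5)
  # lambda = 0 leaves the pure adversarial term
  expect_equal(generator_loss(0.8, y, runif(4), mode = "nolog", lambda = 0),
               -0.8)
  expect_error(generator_loss(0.8, y, y, lambda = -1), "lambda")
  # loss decreases as d_fake rises (nolog, fixed g)
  g <- runif(4)
  l1 <- generator_loss(0.2, y, g, mode = "nolog")
  l2 <- generator_loss(0.9, y, g, mode = "nolog")
  expect_lt(l2, l1)
})
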