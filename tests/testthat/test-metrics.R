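test_that("Dice and Jaccard match their defining formulas and identities", {
  d3 <- c(6L, 6L, 6L)
  S <- blob_mask(d3, c(3, 3, 3), 2)
  expect_equal(dice(S, S), 1)
  expect_equal(jaccard(S, S), 1)
  G <- blob_mask(d3, c(5, 5, 5), 1)
  G <- G & !S  # force disjoint
  expect_equal(dice(S, G), 0)
  expect_equal(jaccard(S, G), 0)

  # |S| = |G| = 4, overlap 2 -> dice 0.5; jaccard = 2/6
  S2 <- array(FALSE, d3); G2 <- array(FALSE, d3)
  S2[1:4] <- TRUE; G2[3:6] <- TRUE
  expect_equal(dice(S2, G2), 0.5)
  expect_equal(jaccard(S2, G2), 1 / 3)

  # dice/jaccard identities on random masks, against loop oracles
  set.seed(20)
  for (i in 1:30) {
    A <- random_mask(c(5, 5, 5), 0.4)
    B <- random_mask(c(5, 5, 5), 0.4)
    if (sum(A | B) == 0) next
    dd <- dice(A, B); jj <- jaccard(A, B)
    expect_equal(dd, oracle_dice(A, B), tolerance = 1e-12)
    expect_equal(jj, oracle_jaccard(A, B), tolerance = 1e-12)
    expect_equal(jj, dd / (2 - dd), tolerance = 1e-12)
    expect_lte(jj, dd + 1e-12)
  }
})

test_that("surface extraction matches a brute-force neighbor scan", {
  cube <- array(FALSE, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  sp <- surface_points(cube)
  expect_identical(nrow(sp), 26L)  # all but the center voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_identical(unname(surface_points(single)[1, ]), c(2L, 2L, 2L))
  set.seed(21)
  for (i in 1:5) {
    m <- random_mask(c(6, 6, 6), 0.5)
    if (!any(m)) next
    got <- unname(surface_points(m))
    want <- unname(oracle_surface(m))
    storage.mode(want) <- "integer"
    expect_identical(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                     want[order(want[, 1], want[, 2], want[, 3]), ,
                          drop = FALSE])
    # surface is a subset of the mask
    expect_true(all(m[got]))
  }
})

test_that("single-point HD95/ASD equal the unique pairwise distance", {
  S <- array(FALSE, c(4, 4, 6)); S[1, 1, 1] <- TRUE
  G <- array(FALSE, c(4, 4, 6)); G[1, 1, 4] <- TRUE
  expect_equal(hd95(S, G), 3)
  expect_equal(asd(S, G), 3)
  expect_equal(hd95(S, S), 0)
  expect_equal(asd(S, S), 0)
  # spacing scales distances
  expect_equal(hd95(S, G, spacing = c(1, 1, 2)), 6)
})

test_that("HD95/ASD match all-pairs oracles on random masks", {
  set.seed(22)
  for (i in 1:12) {
    S <- random_mask(c(6, 6, 6), 0.35)
    G <- random_mask(c(6, 6, 6), 0.35)
    if (!any(S) || !any(G)) next
    sp <- c(1, 1, 1)
    expect_equal(hd95(S, G, sp), oracle_hd(S, G, sp), tolerance = 1e-9)
    expect_equal(asd(S, G, sp), oracle_asd(S, G, sp), tolerance = 1e-9)
    # symmetry
    expect_equal(hd95(S, G, sp), hd95(G, S, sp), tolerance = 1e-12)
    expect_equal(asd(S, G, sp), asd(G, S, sp), tolerance = 1e-12)
    expect_equal(dice(S, G), dice(G, S))
    expect_equal(jaccard(S, G), jaccard(G, S))
    # ASD never exceeds the exact (100th percentile) Hausdorff distance
    expect_lte(asd(S, G, sp), hd95(S, G, sp, percentile = 100) + 1e-12)
  }
})

test_that("metrics are invariant under joint translation", {
  set.seed(23)
  S <- blob_mask(c(10, 10, 10), c(4, 4, 4), 2.2)
  G <- blob_mask(c(10, 10, 10), c(5, 5, 4), 1.8)
  shift_mask <- function(m, by) {
    out <- array(FALSE, dim(m))
    d <- dim(m)
    out[(1 + by):d[1], (1 + by):d[2], (1 + by):d[3]] <-
      m[1:(d[1] - by), 1:(d[2] - by), 1:(d[3] - by)]
    out
  }
  S2 <- shift_mask(S, 2); G2 <- shift_mask(G, 2)
  expect_equal(dice(S2, G2), dice(S, G))
  expect_equal(jaccard(S2, G2), jaccard(S, G))
  expect_equal(hd95(S2, G2), hd95(S, G), tolerance = 1e-12)
  expect_equal(asd(S2, G2), asd(S, G), tolerance = 1e-12)
})

test_that("empty-mask conventions are honored", {
  E <- array(FALSE, c(4, 4, 4))
  S <- blob_mask(c(4, 4, 4), c(2, 2, 2), 1)
  expect_equal(dice(E, E), 1)
  expect_equal(jaccard(E, E), 1)
  expect_equal(hd95(E, E), 0)
  expect_equal(asd(E, E), 0)
  expect_equal(dice(S, E), 0)
  expect_true(is.na(hd95(S, E)))
  expect_equal(hd95(S, E, empty_value = Inf), Inf)
})

test_that("per-case report covers both classes with consistent fields", {
  cs <- tiny_case()
  ref <- cs$labels
  rep0 <- evaluate_case(ref, ref)
  expect_identical(rep0$class, c("liver", "tumor"))
  expect_equal(rep0$dice, c(1, 1))
  expect_equal(rep0$hd95, c(0, 0))
  # drop the tumor from the prediction
  pred <- ref; pred[pred == 2L] <- 1L
  rep1 <- evaluate_case(pred, ref)
  expect_equal(rep1$dice[rep1$class == "liver"], 1)
  expect_equal(rep1$dice[rep1$class == "tumor"], 0)
  # dice/jaccard identity holds in the report
  pred2 <- ref; pred2[1:2, , ] <- 0L
  rep2 <- evaluate_case(pred2, ref)
  expect_equal(rep2$jaccard, rep2$dice / (2 - rep2$dice), tolerance = 1e-12)
})
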