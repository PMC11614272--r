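# Overlap and surface-distance metrics for 3D binary masks. Conventions:
# both masks empty means a perfectly predicted absent structure (dice =
# jaccard = 1, distances 0); exactly one empty mask gives dice = jaccard =
# 0 and undefined distances (a configurable sentinel, NA by default).
# Percentiles use linear interpolation between order statistics (R type 7);
# published HD95 values differ across toolkits on exactly this convention.

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  x != 0
}

#' Dice coefficient
#'
#' `2|S n G| / (|S| + |G|)`: 1 is perfect overlap, 0 none.
#'
#' @param S,G binary masks of identical shape (logical or 0/1).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(S, G) {
  S <- as_mask(S); G <- as_mask(G)
  check_pair(S, G)
  s <- sum(S); g <- sum(G)
  if (s + g == 0) return(1)
  2 * sum(S & G) / (s + g)
}

#' Jaccard index
#'
#' `|S n G| / |S u G|`; related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(S, G) {
  S <- as_mask(S); G <- as_mask(G)
  check_pair(S, G)
  i <- sum(S & G)
  u <- sum(S | G)
  if (u == 0) return(1)
  i / u
}

#' Boundary voxels of a mask
#'
#' Foreground voxels with at least one background face-neighbor
#' (6-neighborhood); voxels on the array border count as boundary.
#'
#' @param mask nonempty binary rank-3 array.
#' @return integer matrix, one row per surface voxel (1-based indices).
#' @export
surface_points <- function(mask) {
  mask <- as_mask(mask)
  if (length(dim(mask)) != 3L) abort_cfg("mask must be rank-3")
  if (!any(mask)) abort_cfg("mask is empty")
  interior <- array(TRUE, dim(mask))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & shift3(mask, axis, by, fill = 0)
  }
  which(mask & !interior, arr.ind = TRUE)
}

# For each row of A (points x 3, already in mm), the distance to the
# nearest row of B. Chunked exact nearest-neighbor; memory stays bounded.
nearest_dists <- function(A, B, chunk = 512L) {
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = chunk)) {
    idx <- s:min(nrow(A), s + chunk - 1L)
    Ac <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, `+`) - 2 * Ac %*% t(B)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

surface_dists <- function(S, G, spacing) {
  ps <- surface_points(S); pg <- surface_points(G)
  sp <- matrix(spacing, nrow(ps), 3, byrow = TRUE)
  A <- ps * sp
  B <- pg * matrix(spacing, nrow(pg), 3, byrow = TRUE)
  list(s_to_g = nearest_dists(A, B), g_to_s = nearest_dists(B, A))
}

#' 95th-percentile Hausdorff distance
#'
#' Maximum of the two directed 95th-percentile surface distances; the
#' truncation makes the Hausdorff distance robust to boundary outliers.
#' `percentile = 100` gives the exact Hausdorff distance.
#'
#' @inheritParams dice
#' @param spacing voxel spacing (mm); distances are in the same units.
#' @param percentile directed distance percentile (default 95).
#' @param empty_value returned when exactly one mask is empty.
#' @return nonnegative scalar (0 when both masks are empty).
#' @export
hd95 <- function(S, G, spacing = c(1, 1, 1), percentile = 95,
                 empty_value = NA_real_) {
  S <- as_mask(S); G <- as_mask(G)
  check_pair(S, G)
  if (!any(S) && !any(G)) return(0)
  if (!any(S) || !any(G)) return(empty_value)
  d <- surface_dists(S, G, spacing)
  max(quantile(d$s_to_g, percentile / 100, names = FALSE, type = 7),
      quantile(d$g_to_s, percentile / 100, names = FALSE, type = 7))
}

#' Average symmetric surface distance
#'
#' Mean of the two directed mean boundary distances.
#'
#' @inheritParams hd95
#' @return nonnegative scalar (0 when both masks are empty).
#' @export
asd <- function(S, G, spacing = c(1, 1, 1), empty_value = NA_real_) {
  S <- as_mask(S); G <- as_mask(G)
  check_pair(S, G)
  if (!any(S) && !any(G)) return(0)
  if (!any(S) || !any(G)) return(empty_value)
  d <- surface_dists(S, G, spacing)
  (mean(d$s_to_g) + mean(d$g_to_s)) / 2
}

#' Per-class metrics report for a 3-class prediction
#'
#' Evaluates liver (labels 1 and 2 merged) and tumor (label 2) masks with
#' all four metrics.
#'
#' @param pred,ref integer label maps with values in `{0, 1, 2}`.
#' @param spacing voxel spacing (mm).
#' @return a tibble with one row per class and columns `class`, `dice`,
#'   `jaccard`, `hd95`, `asd`.
#' @export
evaluate_case <- function(pred, ref, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(ref)))
    abort_cfg("prediction and reference must share a shape")
  rows <- lapply(c(liver = "liver", tumor = "tumor"), function(cl) {
    sel <- if (cl == "liver") function(x) x >= 1 else function(x) x == 2
    S <- sel(pred); G <- sel(ref)
    tibble::tibble(class = cl, dice = dice(S, G), jaccard = jaccard(S, G),
                   hd95 = hd95(S, G, spacing), asd = asd(S, G, spacing))
  })
  do.call(rbind, rows)
}
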