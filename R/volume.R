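#' CT volume container
#'
#' A light container for a 3D CT volume: a `[D, H, W]` array of intensities
#' in Hounsfield units plus voxel spacing (mm) and a 4x4 affine carrying the
#' scanner geometry. Arrays are indexed `[depth, height, width]`, 0-based
#' depth slice 1 first; an "axial plane" is a fixed-depth slice.
#'
#' @param data numeric rank-3 array `[D, H, W]`, finite.
#' @param spacing numeric length-3 voxel spacing in mm, all `> 0`.
#' @param affine 4x4 orientation matrix; defaults to a diagonal affine built
#'   from `spacing`.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L) abort_cfg("volume data must be a rank-3 array")
  if (!all(is.finite(data))) abort_cfg("volume data must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    abort_cfg("spacing must be 3 positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

as_volume <- function(x) {
  if (inherits(x, "ct_volume")) x else ct_volume(x)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' round-trip the voxel array, spacing and affine.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a [ct_volume]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort_cfg("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) < 3L) abort_cfg("expected a 3D NIfTI image: ", path)
  a <- array(as.numeric(a), dim(a)[1:3])  # plain array, nifti attrs dropped
  ct_volume(a, spacing = RNifti::pixdim(img)[1:3],
            affine = unclass(RNifti::xform(img)))
}

#' @param v a [ct_volume].
#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::`qform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop a volume to its labeled depth range
#'
#' Finds the first and last depth slice containing any nonzero label and
#' drops all slices outside that range, the standard step that removes
#' image content irrelevant to the segmentation target.
#'
#' @param v a [ct_volume] or rank-3 array.
#' @param labels integer rank-3 array aligned with `v`.
#' @return list with the cropped `volume` and `labels`.
#' @export
crop_to_labeled_range <- function(v, labels) {
  v <- as_volume(v)
  if (!identical(dim(v$data), dim(labels)))
    abort_cfg("volume and labels must share a shape")
  nz <- which(apply(labels != 0, 1, any))
  if (length(nz) == 0L) abort_cfg("labels contain no nonzero voxel")
  keep <- min(nz):max(nz)
  list(volume = ct_volume(v$data[keep, , , drop = FALSE], v$spacing, v$affine),
       labels = labels[keep, , , drop = FALSE])
}

#' Hounsfield windowing specification
#'
#' The analysis window used throughout the pipeline: intensities are clipped
#' to `[lower, upper]` HU. The default `[-30, 170]` is the soft-tissue
#' window that gives liver and (hypodense) tumor tissue most of the dynamic
#' range.
#'
#' @param lower,upper window bounds in HU, `lower < upper`.
#' @export
window_spec <- function(lower = -30, upper = 170) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    abort_cfg("window requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "window_spec")
}

#' Apply an HU window (clip) to a volume
#'
#' @param v a [ct_volume] or array.
#' @param w a [window_spec].
#' @return volume of the same shape with every voxel in `[w$lower, w$upper]`.
#' @export
apply_window <- function(v, w = window_spec()) {
  v <- as_volume(v)
  v$data <- pmin(pmax(v$data, w$lower), w$upper)
  v
}

#' Rescale a windowed volume to `[0, 1]`
#'
#' Fixed min-max mapping `(x - lower) / (upper - lower)` over the window
#' (not per-volume), so intensities stay comparable across cases.
#'
#' @inheritParams apply_window
#' @export
normalize01 <- function(v, w = window_spec()) {
  v <- as_volume(v)
  v$data <- (v$data - w$lower) / (w$upper - w$lower)
  v
}

#' Resize the in-plane (H, W) resolution
#'
#' Bilinear interpolation for images, nearest-neighbor for label maps (so
#' the label value set is preserved). Depth is never resampled; in-plane
#' spacing is rescaled accordingly.
#'
#' @param v a [ct_volume] or rank-3 array.
#' @param target side length of the output plane (>= 16).
#' @param is_label resize as a label map?
#' @export
resize_inplane <- function(v, target, is_label = FALSE) {
  if (target < 16) abort_cfg("target side length must be >= 16")
  raw_array <- !inherits(v, "ct_volume")
  v <- as_volume(v)
  d <- dim(v$data)
  if (d[2] == target && d[3] == target) {
    return(if (raw_array) v$data else v)
  }
  # EBImage resizes the first two dims; put (H, W) in front
  perm <- aperm(v$data, c(2, 3, 1))
  out <- EBImage::resize(perm, w = target, h = target,
                         filter = if (is_label) "none" else "bilinear")
  out <- aperm(array(out, c(target, target, d[1])), c(3, 1, 2))
  if (is_label) out <- array(as.integer(round(out)), dim(out))
  sp <- v$spacing * c(1, d[2] / target, d[3] / target)
  res <- ct_volume(out, spacing = sp, affine = v$affine)
  if (raw_array) res$data else res
}

#' Pad depth to a multiple of `m` (reflect), and undo it
#'
#' The encoder halves depth four times, so network input depth must be
#' divisible by 16. `pad_depth()` reflect-pads at the end and records the
#' original depth; `unpad_depth()` restores it on a prediction.
#'
#' @param x rank-3 array `[D, H, W]`.
#' @param m required multiple (default 16).
#' @return padded array with attribute `orig_depth`.
#' @export
pad_depth <- function(x, m = 16L) {
  d <- dim(x)[1]
  need <- (m - d %% m) %% m
  if (need > 0) {
    p <- d + seq_len(need)
    if (d == 1L) {
      reps <- rep(1L, need)
    } else {
      q <- (p - 1L) %% (2L * d - 2L)  # reflect without repeating the edge
      reps <- ifelse(q < d, q + 1L, 2L * d - 1L - q)
    }
    out <- array(0, c(d + need, dim(x)[2], dim(x)[3]))
    out[seq_len(d), , ] <- x
    out[d + seq_len(need), , ] <- x[reps, , , drop = FALSE]
    x <- out
  }
  attr(x, "orig_depth") <- d
  x
}

#' @param xp output of [pad_depth()] (or any array plus `orig_depth`).
#' @param orig_depth depth to restore; defaults to the recorded attribute.
#' @rdname pad_depth
#' @export
unpad_depth <- function(xp, orig_depth = attr(xp, "orig_depth")) {
  if (is.null(orig_depth)) return(xp)
  out <- xp[seq_len(orig_depth), , , drop = FALSE]
  attr(out, "orig_depth") <- NULL
  out
}

#' Full CT preprocessing pipeline
#'
#' crop to the labeled depth range, window, rescale to `[0, 1]`, and resize
#' the plane — the standard preparation before network input.
#'
#' @param v a [ct_volume].
#' @param labels aligned integer label array (used for cropping); optional.
#' @param w a [window_spec].
#' @param target in-plane side length, or `NULL` to keep the native plane.
#' @return list with `volume` (normalized) and `labels` (possibly `NULL`).
#' @export
preprocess_case <- function(v, labels = NULL, w = window_spec(),
                            target = NULL) {
  v <- as_volume(v)
  if (!is.null(labels)) {
    cr <- crop_to_labeled_range(v, labels)
    v <- cr$volume; labels <- cr$labels
  }
  v <- normalize01(apply_window(v, w), w)
  if (!is.null(target)) {
    v <- resize_inplane(v, target, is_label = FALSE)
    if (!is.null(labels))
      labels <- resize_inplane(labels, target, is_label = TRUE)
  }
  list(volume = v, labels = labels)
}
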