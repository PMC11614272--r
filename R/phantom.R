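#' Synthetic liver-phantom configuration
#'
#' Parameters of the synthetic CT phantom used to exercise the whole
#' pipeline without external data. The phantom emulates the statistical
#' structure of contrast abdominal CT with liver annotations: an elliptical
#' soft-tissue "body" against air at -1000 HU, a liver ellipsoid of moderate
#' intensity inside it, and 0-3 hypodense spherical "tumors" fully contained
#' in the liver. Region intensities are drawn per voxel, lightly Gaussian
#' smoothed (partial-volume-like boundary blur) and additive noise is added.
#'
#' @param shape integer `(D, H, W)`, each `>= 16`.
#' @param liver_axes ellipsoid semi-axes in voxels `(d, h, w)`.
#' @param n_tumors number of tumor spheres, 0-3.
#' @param tumor_radius_range `(min, max)` sphere radius in voxels; `max`
#'   must be smaller than `min(liver_axes)`.
#' @param hu_background soft-tissue `(mean, sd)` in HU.
#' @param hu_liver liver `(mean, sd)` in HU.
#' @param hu_tumor tumor `(mean, sd)` in HU; the mean must be below the
#'   liver mean (tumors are hypodense).
#' @param noise_sd additive voxel noise sd in HU.
#' @param smooth_sd Gaussian boundary-blur sd in voxels.
#' @param seed integer seed; the phantom is a pure function of the config.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32L, 64L, 64L),
                           liver_axes = c(11, 22, 22),
                           n_tumors = 2L,
                           tumor_radius_range = c(2.5, 5),
                           hu_background = c(-80, 20),
                           hu_liver = c(60, 10),
                           hu_tumor = c(25, 10),
                           noise_sd = 5,
                           smooth_sd = 1,
                           seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    abort_cfg("shape must be 3 integers, all >= 16")
  if (any(liver_axes <= 0)) abort_cfg("liver_axes must be positive")
  if (n_tumors < 0L || n_tumors > 3L) abort_cfg("n_tumors must be in 0..3")
  if (tumor_radius_range[1] > tumor_radius_range[2] ||
      tumor_radius_range[1] <= 0)
    abort_cfg("tumor_radius_range must be increasing and positive")
  if (tumor_radius_range[2] >= min(liver_axes))
    abort_cfg("max tumor radius must be smaller than min(liver_axes)")
  if (hu_tumor[1] >= hu_liver[1])
    abort_cfg("tumors must be hypodense: hu_tumor mean < hu_liver mean")
  structure(list(shape = shape, liver_axes = as.numeric(liver_axes),
                 n_tumors = as.integer(n_tumors),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 hu_background = as.numeric(hu_background),
                 hu_liver = as.numeric(hu_liver),
                 hu_tumor = as.numeric(hu_tumor),
                 noise_sd = noise_sd, smooth_sd = smooth_sd, seed = seed),
            class = "phantom_config")
}

# Normalized squared ellipsoid coordinate for every voxel.
ellipsoid_dist2 <- function(shape, center, axes) {
  d <- (seq_len(shape[1]) - center[1]) / axes[1]
  h <- (seq_len(shape[2]) - center[2]) / axes[2]
  w <- (seq_len(shape[3]) - center[3]) / axes[3]
  outer(outer(d^2, h^2, `+`), w^2, `+`)
}

#' Generate one synthetic CT phantom
#'
#' @param config a [phantom_config].
#' @return list with `volume` (a [ct_volume], HU) and `labels` (integer
#'   array, 0 = background, 1 = liver, 2 = tumor). Every tumor voxel lies
#'   inside the liver ellipsoid; identical configs (incl. seed) give
#'   bit-identical output.
#' @export
make_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config"))
    abort_cfg("config must be a phantom_config")
  with_seed(config$seed, {
    sh <- config$shape
    center <- (sh + 1) / 2

    # body: soft-tissue ellipse filling most of the plane, all depths
    body <- ellipsoid_dist2(sh, center, c(1e6, 0.46 * sh[2], 0.44 * sh[3])) <= 1

    # liver ellipsoid, slightly off-center within the body
    liver_center <- center + c(0, -0.05 * sh[2], 0.08 * sh[3])
    liver <- ellipsoid_dist2(sh, liver_center, config$liver_axes) <= 1

    labels <- array(0L, sh)
    labels[body] <- 0L
    labels[liver] <- 1L

    # tumors: spheres rejection-sampled to lie fully inside the liver;
    # containment check uses the ellipsoid shrunk by the radius per axis
    if (config$n_tumors > 0L) {
      for (t in seq_len(config$n_tumors)) {
        r <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
        placed <- FALSE
        for (attempt in 1:100) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          rad <- runif(1)^(1 / 3)
          cen <- liver_center + u * rad * (config$liver_axes - r)
          dd <- (cen[1] - liver_center[1])^2 / (config$liver_axes[1] - r)^2 +
                (cen[2] - liver_center[2])^2 / (config$liver_axes[2] - r)^2 +
                (cen[3] - liver_center[3])^2 / (config$liver_axes[3] - r)^2
          if (dd <= 1) {
            sph <- ellipsoid_dist2(sh, cen, c(r, r, r)) <= 1
            labels[sph & liver] <- 2L
            placed <- TRUE
            break
          }
        }
        if (!placed) abort_cfg("could not place tumor ", t,
                               " inside the liver after 100 attempts")
      }
    }

    img <- array(rnorm(prod(sh), -1000, 5), sh)  # air
    nb <- sum(body); img[body] <- rnorm(nb, config$hu_background[1],
                                        config$hu_background[2])
    nl <- sum(labels == 1L)
    img[labels == 1L] <- rnorm(nl, config$hu_liver[1], config$hu_liver[2])
    nt <- sum(labels == 2L)
    if (nt > 0) img[labels == 2L] <- rnorm(nt, config$hu_tumor[1],
                                           config$hu_tumor[2])
    img <- smooth_gaussian3(img, config$smooth_sd)
    if (config$noise_sd > 0)
      img <- img + rnorm(prod(sh), 0, config$noise_sd)

    list(volume = ct_volume(img), labels = labels)
  })
}

#' Write a dataset of phantom NIfTI pairs
#'
#' Generates `n` phantoms with per-case seeds derived from `config$seed`,
#' writes `case_XXX_image.nii.gz` / `case_XXX_label.nii.gz` pairs plus a
#' JSON manifest listing paths and seeds.
#'
#' @param n number of cases (>= 1).
#' @param config a [phantom_config]; its `seed` anchors the per-case seeds.
#' @param out_dir output directory (created if missing).
#' @return the manifest as a list (invisibly also written to
#'   `manifest.json`).
#' @export
make_dataset <- function(n, config = phantom_config(), out_dir) {
  if (n < 1) abort_cfg("n must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_cfg("cannot create output directory: ", out_dir)
  base <- config$seed %||% 1L
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- (base + 977L * (i - 1L)) %% .Machine$integer.max
    ph <- make_phantom(cfg_i)
    img_path <- file.path(out_dir, sprintf("case_%03d_image.nii.gz", i))
    lab_path <- file.path(out_dir, sprintf("case_%03d_label.nii.gz", i))
    write_volume(ph$volume, img_path)
    write_volume(ct_volume(ph$labels * 1, ph$volume$spacing,
                           ph$volume$affine), lab_path)
    cases[[i]] <- list(id = sprintf("case_%03d", i), image = img_path,
                       label = lab_path, seed = cfg_i$seed)
  }
  manifest <- list(n = n, shape = config$shape, cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
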