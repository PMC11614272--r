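# End-to-end workflow: simulate -> preprocess -> train -> predict ->
# evaluate. Every step is a plain function over files so the bundled CLI
# script stays a thin wrapper; nothing mutates its inputs and every run
# directory gets a config snapshot.

#' Simulate a phantom dataset
#'
#' @param n number of cases.
#' @param out_dir output directory.
#' @param phantom a [phantom_config()]; its seed anchors per-case seeds.
#' @return the dataset manifest (invisibly).
#' @export
run_simulate <- function(n, out_dir, phantom = phantom_config(seed = 1L)) {
  make_dataset(n, phantom, out_dir)
}

read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) abort_cfg("no manifest.json in ", dir)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Preprocess a simulated dataset
#'
#' Applies labeled-slice cropping, HU windowing, `[0, 1]` scaling and
#' optional in-plane resizing to every case in `in_dir`, writing the
#' results plus a new manifest to `out_dir`.
#'
#' @param in_dir directory from [run_simulate()].
#' @param out_dir output directory.
#' @param w a [window_spec()].
#' @param target in-plane side length or `NULL` to keep the native plane.
#' @return the output manifest (invisibly).
#' @export
run_preprocess <- function(in_dir, out_dir, w = window_spec(),
                           target = NULL) {
  man <- read_manifest(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cases <- lapply(man$cases, function(cs) {
    v <- read_volume(cs$image)
    lab <- read_volume(cs$label)
    labels <- array(as.integer(round(lab$data)), dim(lab$data))
    pp <- preprocess_case(v, labels, w = w, target = target)
    img_path <- file.path(out_dir, basename(cs$image))
    lab_path <- file.path(out_dir, basename(cs$label))
    write_volume(pp$volume, img_path)
    write_volume(ct_volume(pp$labels * 1, pp$volume$spacing,
                           pp$volume$affine), lab_path)
    list(id = cs$id, image = img_path, label = lab_path, seed = cs$seed)
  })
  manifest <- list(n = length(cases), window = unclass(w),
                   target = target, cases = cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Load preprocessed cases as training samples for one target class.
load_cases <- function(dir, class = c("liver", "tumor")) {
  class <- match.arg(class)
  man <- read_manifest(dir)
  lapply(man$cases, function(cs) {
    img <- read_volume(cs$image)
    lab <- read_volume(cs$label)
    labels <- array(as.integer(round(lab$data)), dim(lab$data))
    mask <- if (class == "liver") labels >= 1L else labels == 2L
    list(id = cs$id, image = img$data, mask = mask,
         labels = labels, spacing = img$spacing, affine = img$affine)
  })
}

#' Train a model for one target class on a preprocessed dataset
#'
#' Cases are split into training and validation (the last
#' `ceiling(n * val_frac)` cases validate; with a single case it is its own
#' validation). The best checkpoint, history and config snapshot are
#' written to `run_dir`.
#'
#' @param data_dir directory from [run_preprocess()].
#' @param run_dir run output directory.
#' @param class `"liver"` (labels 1 and 2 merged) or `"tumor"` (label 2).
#' @param cfg a [train_config()].
#' @param val_frac validation fraction.
#' @return the `cgan_fit` (invisibly).
#' @export
run_train <- function(data_dir, run_dir, class = c("liver", "tumor"),
                      cfg = train_config(), val_frac = 0.2) {
  class <- match.arg(class)
  cases <- load_cases(data_dir, class)
  n <- length(cases)
  if (n == 1L) {
    train_set <- cases; val_set <- cases
  } else {
    nv <- max(1L, ceiling(n * val_frac))
    val_set <- cases[(n - nv + 1L):n]
    train_set <- cases[1:(n - nv)]
  }
  fit <- fit_cgan(train_set, val_set, cfg, run_dir = run_dir)
  invisible(fit)
}

#' Predict a 3-class label map for one CT volume
#'
#' Windows and scales the input exactly as in training, runs the liver
#' (and optionally tumor) generator on the depth-padded volume, removes the
#' padding, optionally applies connected-component post-processing, and
#' writes a NIfTI aligned with the input geometry.
#'
#' @param liver_ckpt path to the liver model checkpoint.
#' @param image_in input CT NIfTI path.
#' @param label_out output NIfTI path.
#' @param tumor_ckpt optional tumor model checkpoint.
#' @param w a [window_spec()] (must match training).
#' @param target in-plane side used at training, or `NULL`.
#' @param postprocess apply [postprocess_case()]?
#' @param spec a [component_filter_spec()].
#' @param threshold binarisation threshold.
#' @return the predicted label map (invisibly).
#' @export
run_predict <- function(liver_ckpt, image_in, label_out,
                        tumor_ckpt = NULL, w = window_spec(),
                        target = NULL, postprocess = TRUE,
                        spec = component_filter_spec(), threshold = 0.5) {
  v <- read_volume(image_in)
  orig_dim <- dim(v$data)
  pp <- preprocess_case(v, labels = NULL, w = w, target = target)
  img <- pp$volume$data

  liver_fit <- load_checkpoint(liver_ckpt)
  liver_prob <- predict_probs(liver_fit$gen, img)
  tumor_prob <- NULL
  if (!is.null(tumor_ckpt)) {
    tumor_fit <- load_checkpoint(tumor_ckpt)
    tumor_prob <- predict_probs(tumor_fit$gen, img)
  }
  if (postprocess) {
    lab <- postprocess_case(liver_prob, tumor_prob, threshold, spec)
  } else {
    lab <- array(0L, dim(liver_prob))
    lab[liver_prob >= threshold] <- 1L
    if (!is.null(tumor_prob)) lab[tumor_prob >= threshold & lab == 1L] <- 2L
  }
  if (!is.null(target) && any(dim(lab)[2:3] != orig_dim[2:3]))
    lab <- resize_inplane(lab, orig_dim[2], is_label = TRUE)
  write_volume(ct_volume(lab * 1, v$spacing, v$affine), label_out)
  invisible(lab)
}

#' Evaluate predicted label maps against references
#'
#' Pairs files by name across the two directories, computes the four
#' metrics per class and case, appends a mean row, and optionally writes a
#' CSV with one column per metric and class.
#'
#' @param pred_dir,ref_dir directories of NIfTI label maps with matching
#'   file names.
#' @param out_csv optional CSV path.
#' @return a tibble (`case` plus 8 metric columns).
#' @export
run_evaluate <- function(pred_dir, ref_dir, out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.nii(\\.gz)?$"))
  refs <- sort(list.files(ref_dir, pattern = "\\.nii(\\.gz)?$"))
  missing_ref <- setdiff(preds, refs)
  missing_pred <- setdiff(refs, preds)
  if (length(missing_ref) || length(missing_pred))
    abort_cfg("unpaired files: ",
              paste(c(missing_ref, missing_pred), collapse = ", "))
  if (length(preds) == 0L) abort_cfg("no label maps found in ", pred_dir)
  rows <- lapply(preds, function(f) {
    p <- read_volume(file.path(pred_dir, f))
    r <- read_volume(file.path(ref_dir, f))
    m <- evaluate_case(array(as.integer(round(p$data)), dim(p$data)),
                       array(as.integer(round(r$data)), dim(r$data)),
                       spacing = r$spacing)
    wide <- tibble::tibble(case = sub("\\.nii(\\.gz)?$", "", f))
    for (i in seq_len(nrow(m)))
      for (col in c("dice", "jaccard", "hd95", "asd"))
        wide[[paste(m$class[i], col, sep = "_")]] <- m[[col]][i]
    wide
  })
  out <- do.call(rbind, rows)
  mean_row <- out[1, ]
  mean_row$case <- "mean"
  for (col in names(out)[-1]) mean_row[[col]] <- mean(out[[col]], na.rm = TRUE)
  out <- rbind(out, mean_row)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
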