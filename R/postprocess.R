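#' Connected-component filter specification
#'
#' @param rate fraction of the largest component's voxel count below which
#'   a component is removed (strictly-less-than rule, default 0.3).
#' @param connectivity neighborhood defining adjacency: 6 (faces),
#'   18 (faces + edges) or 26 (full cube).
#' @export
component_filter_spec <- function(rate = 0.3, connectivity = 26L) {
  if (rate <= 0 || rate > 1) abort_cfg("rate must be in (0, 1]")
  if (!connectivity %in% c(6L, 18L, 26L))
    abort_cfg("connectivity must be 6, 18 or 26")
  structure(list(rate = rate, connectivity = as.integer(connectivity)),
            class = "component_filter_spec")
}

conn_offsets <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dh = -1:1, dw = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  deg <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[deg == 1, ], "18" = off[deg <= 2, ], off)
  # half set: each undirected neighbor pair enumerated once
  off[off$dz > 0 | (off$dz == 0 & off$dh > 0) |
        (off$dz == 0 & off$dh == 0 & off$dw > 0), ]
}

#' Label connected components of a binary mask
#'
#' Builds the voxel adjacency graph of the foreground and labels its
#' connected components (components are numbered 1..k in decreasing
#' arbitrary order; 0 is background).
#'
#' @param mask binary rank-3 array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as_mask(mask)
  id <- array(0L, dim(mask))
  fg <- which(mask)
  if (length(fg) == 0L) return(id)
  id[fg] <- seq_along(fg)
  off <- conn_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    sh <- shift3(shift3(shift3(id, 1L, off$dz[r]), 2L, off$dh[r]),
                 3L, off$dw[r])
    sel <- id > 0L & sh > 0L
    from <- c(from, id[sel]); to <- c(to, sh[sel])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  out <- array(0L, dim(mask))
  out[fg] <- as.integer(memb)
  out
}

#' Remove minor connected components
#'
#' With `x` the voxel count of the largest component, removes every
#' component whose count is strictly less than `rate * x`; ties at the
#' threshold survive, and the largest component always survives. Motivated
#' by anatomy: there is only one liver, so satellite blobs in a liver
#' prediction are false positives.
#'
#' @param mask binary rank-3 array.
#' @param spec a [component_filter_spec()].
#' @return filtered binary mask (never adds a voxel).
#' @export
keep_major_components <- function(mask, spec = component_filter_spec()) {
  m <- as_mask(mask)
  lab <- label_components(m, spec$connectivity)
  if (!any(lab > 0L)) return(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= spec$rate * max(sizes)
  out <- array(FALSE, dim(m))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Compose a 3-class label map from probability volumes
#'
#' Binarises the liver probability at `threshold`, filters it with
#' [keep_major_components()], binarises the tumor probability and keeps
#' only tumor voxels inside the surviving liver, then merges into one map
#' (0 background, 1 liver, 2 tumor). The liver channel itself is never
#' altered by the tumor constraint.
#'
#' @param liver_prob,tumor_prob probability arrays in `[0, 1]`;
#'   `tumor_prob` may be `NULL`.
#' @param threshold binarisation threshold.
#' @param spec a [component_filter_spec()].
#' @return integer label map with values in `{0, 1, 2}`.
#' @export
postprocess_case <- function(liver_prob, tumor_prob = NULL, threshold = 0.5,
                             spec = component_filter_spec()) {
  if (!is.null(tumor_prob) &&
      !identical(dim(liver_prob), dim(tumor_prob)))
    abort_cfg("liver and tumor probability maps must share a shape")
  liver <- keep_major_components(liver_prob >= threshold, spec)
  out <- array(0L, dim(liver))
  out[liver] <- 1L
  if (!is.null(tumor_prob)) {
    tumor <- (tumor_prob >= threshold) & liver
    out[tumor] <- 2L
  }
  out
}
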