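`%||%` <- function(a, b) if (is.null(a)) b else a

abort_cfg <- function(...) stop(..., call. = FALSE)

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations (phantom drawing,
#' weight initialisation) do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Shift a 3D array by `by` voxels along `axis`, filling with `fill`.
shift3 <- function(x, axis, by, fill = 0) {
  d <- dim(x)
  if (by == 0) return(x)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix_src <- list(1:d[1], 1:d[2], 1:d[3]); ix_dst <- ix_src
  ix_src[[axis]] <- src; ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    x[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

# Separable Gaussian smoothing of a 3D array (replicate-edge padding),
# used to soften phantom region boundaries the way partial-volume
# averaging blurs real CT edges.
smooth_gaussian3 <- function(x, sd) {
  if (sd <= 0) return(x)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(x))
    n <- dim(x)[axis]
    for (j in seq_along(k)) {
      by <- j - r - 1L
      sh <- shift3(x, axis, -by)
      # replicate edge: positions that sampled outside take the boundary slice
      if (by != 0) {
        d <- dim(x); ix <- list(1:d[1], 1:d[2], 1:d[3])
        gap <- if (by > 0) (n - by + 1):n else 1:(-by)
        gap_ix <- ix; gap_ix[[axis]] <- gap
        edge_ix <- ix; edge_ix[[axis]] <- rep(if (by > 0) n else 1L, length(gap))
        sh[gap_ix[[1]], gap_ix[[2]], gap_ix[[3]]] <-
          x[edge_ix[[1]], edge_ix[[2]], edge_ix[[3]]]
      }
      acc <- acc + k[j] * sh
    }
    x <- acc
  }
  x
}
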