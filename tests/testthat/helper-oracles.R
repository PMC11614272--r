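# Independent brute-force oracles used to verify the package
# implementations. These deliberately share no code with the package:
# plain loops and first-principles formulas only.

# --- surface distances: all-pairs double loop ------------------------------

oracle_surface <- function(mask) {
  d <- dim(mask)
  pts <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb_bg <- FALSE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask[ii, jj, kk]) {
        nb_bg <- TRUE
        break
      }
    }
    if (nb_bg) pts[[length(pts) + 1]] <- c(i, j, k)
  }
  do.call(rbind, pts)
}

oracle_directed <- function(A, B, spacing) {
  sapply(seq_len(nrow(A)), function(i) {
    min(sapply(seq_len(nrow(B)), function(j) {
      sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
    }))
  })
}

oracle_hd <- function(S, G, spacing = c(1, 1, 1), percentile = 95) {
  A <- oracle_surface(S); B <- oracle_surface(G)
  max(quantile(oracle_directed(A, B, spacing), percentile / 100, names = FALSE),
      quantile(oracle_directed(B, A, spacing), percentile / 100, names = FALSE))
}

oracle_asd <- function(S, G, spacing = c(1, 1, 1)) {
  A <- oracle_surface(S); B <- oracle_surface(G)
  (mean(oracle_directed(A, B, spacing)) +
     mean(oracle_directed(B, A, spacing))) / 2
}

oracle_dice <- function(S, G) {
  inter <- 0; s <- 0; g <- 0
  for (i in seq_along(S)) {
    inter <- inter + (S[i] && G[i])
    s <- s + S[i]; g <- g + G[i]
  }
  2 * inter / (s + g)
}

oracle_jaccard <- function(S, G) {
  inter <- 0; uni <- 0
  for (i in seq_along(S)) {
    inter <- inter + (S[i] && G[i])
    uni <- uni + (S[i] || G[i])
  }
  inter / uni
}

# --- Tversky: per-voxel loop -----------------------------------------------

oracle_tversky <- function(y, g, alpha, beta, smooth = 1e-6) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(y)) {
    tp <- tp + y[i] * g[i]
    fp <- fp + (1 - y[i]) * g[i]
    fn <- fn + y[i] * (1 - g[i])
  }
  (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
}

# --- connected components: BFS flood fill ----------------------------------

oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dh = -1:1, dw = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  deg <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[deg == 1, ], "18" = offs[deg <= 2, ], offs)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      j <- rem %/% d[1] + 1
      i <- rem %% d[1] + 1
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs$dz[r]; jj <- j + offs$dh[r]; kk <- k + offs$dw[r]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
          next
        w <- ii + d[1] * (jj - 1) + d[1] * d[2] * (kk - 1)
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# --- shared fixtures -------------------------------------------------------

# Small phantom-derived training case (windowed, scaled), cached per session.
tiny_case <- local({
  cache <- NULL
  function(seed = 5L, shape = c(16L, 32L, 32L)) {
    key <- paste(seed, paste(shape, collapse = "x"))
    if (!is.null(cache) && identical(cache$key, key)) return(cache$val)
    ph <- make_phantom(phantom_config(
      shape = shape, liver_axes = c(6, 11, 11),
      tumor_radius_range = c(2, 3.5), n_tumors = 1L, seed = seed))
    w <- window_spec()
    val <- list(image = normalize01(apply_window(ph$volume, w), w)$data,
                mask = ph$labels >= 1L, labels = ph$labels)
    cache <<- list(key = key, val = val)
    val
  }
})

random_mask <- function(dim3, p = 0.3) {
  array(runif(prod(dim3)) < p, dim3)
}

blob_mask <- function(dim3, center, r) {
  g <- expand.grid(i = seq_len(dim3[1]), j = seq_len(dim3[2]),
                   k = seq_len(dim3[3]))
  arr <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2 <= r^2
  array(arr, dim3)
}
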