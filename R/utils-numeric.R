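# Small numeric helpers shared by the analysis machinery.

# Trilinear interpolation. arr: 3D array; pts: m x 3 in 1-based array index
# coordinates. Points outside are clamped to the boundary.
interp3 <- function(arr, pts) {
  d <- dim(arr)
  p <- cbind(pmin(pmax(pts[, 1], 1), d[1]),
             pmin(pmax(pts[, 2], 1), d[2]),
             pmin(pmax(pts[, 3], 1), d[3]))
  i0 <- pmin(floor(p), rep(d - 1L, each = nrow(p)))
  f <- p - i0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    v <- v + w * arr[idx]
  }
  v
}

# Separable Gaussian smoothing of a 3D array, NA-aware (normalized
# convolution: missing voxels get the weighted mean of their neighborhood).
gaussian_smooth3d <- function(arr, sigma = 1) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  w <- !is.na(arr)
  a <- arr; a[!w] <- 0
  conv_axis <- function(x, d) {
    out <- array(0, dim(x))
    n <- dim(x)[d]
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate edges
      out <- out + k[j] * switch(d, x[src, , , drop = FALSE],
                                 x[, src, , drop = FALSE],
                                 x[, , src, drop = FALSE])
    }
    out
  }
  for (d in 1:3) { a <- conv_axis(a, d); w <- conv_axis(w * 1, d) }
  res <- a / pmax(w, 1e-12)
  res[w < 1e-6] <- NA_real_
  res
}

# Replace NA voxels by the smoothed neighborhood value (fallback: global mean).
impute_map <- function(map, sigma = 1.5) {
  if (!anyNA(map)) return(map)
  sm <- gaussian_smooth3d(map, sigma)
  out <- map
  out[is.na(out)] <- sm[is.na(out)]
  out[is.na(out)] <- mean(map, na.rm = TRUE)
  out
}

# Periodized difference-of-Gaussians kernel sampled on a grid with per-axis
# sizes `dims` and voxel edges `h` (both length 3). Each separable lobe is a
# product of 1D image sums, truncated after trunc_sd widths.
periodized_kernel <- function(dims, h, params, trunc_sd = 4) {
  cell <- dims * h
  lobe <- function(sigma) {
    ax <- lapply(1:3, function(d) {
      g <- (0:(dims[d] - 1)) * h[d]
      M <- ceiling(trunc_sd * sigma / cell[d]) + 1L
      rowSums(sapply((-M):M,
                     function(m) exp(-(g + m * cell[d])^2 / (2 * sigma^2))))
    })
    outer(outer(ax[[1]], ax[[2]]), ax[[3]]) / (2 * pi * sigma^2)^(3 / 2)
  }
  lobe(params$v_tau_l) - params$rho * lobe(params$v_tau_s)
}

# Local maxima of a 3D array: voxels strictly greater than their 26
# neighbors (array padded with -Inf, so boundary voxels compete only with
# interior neighbors). Returns arr.ind-style matrix.
local_maxima3d <- function(arr, threshold = -Inf) {
  d <- dim(arr)
  a <- array(-Inf, d + 2L)
  a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ifelse(is.na(arr), -Inf, arr)
  core <- a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  res <- array(TRUE, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    if (dx == 1 && dy == 1 && dz == 1) next
    nb <- a[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
    res <- res & (core > nb)
  }
  which(res & core > threshold, arr.ind = TRUE)
}
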