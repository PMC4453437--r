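#' Place-field centers on a regular lattice
#'
#' Centers are cell-centered, at `(i + 1/2)/n` per axis, so none sits on a
#' wall and the input coverage is homogeneous. For a stretched box the
#' per-axis count is scaled to keep the center density fixed.
#'
#' @param per_axis centers per axis in a unit box (`>= 2`).
#' @param box per-axis box lengths (units of L).
#' @return an `m x 3` matrix of centers.
#' @export
place_centers <- function(per_axis, box = c(1, 1, 1)) {
  stopifnot(per_axis >= 2, length(box) == 3, all(box > 0))
  counts <- pmax(2L, as.integer(round(per_axis * box)))
  ax <- lapply(1:3, function(d) (seq_len(counts[d]) - 0.5) / counts[d] * box[d])
  m <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Gaussian place-cell rates at a position
#'
#' `r_j = exp(-||x - c_j||^2 / (2 sigma_p^2))`: each input unit fires as an
#' isotropic Gaussian bump around its center, with no normalization across
#' units.
#'
#' @param x position (3-vector).
#' @param centers matrix of field centers (`m x 3`).
#' @param sigma_p field width (`> 0`), same units as positions.
#' @return rate vector in `(0, 1]`.
#' @export
place_rates <- function(x, centers, sigma_p = 0.05) {
  if (sigma_p <= 0) stop("sigma_p must be positive")
  d2 <- colSums((t(centers) - x)^2)
  exp(-d2 / (2 * sigma_p^2))
}
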