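#' Voxelized reference rate maps
#'
#' Ideal field arrangements for calibrating and testing the analysis
#' machinery: analytic FCC and HCP fields (stacking axis along z for HCP), a
#' planar hexagonal pattern extended uniformly in z, an isotropic
#' white-noise rate field, and a spatially shuffled FCC map (value
#' distribution preserved, structure destroyed). Maps are sampled on a cubic voxel grid
#' over the unit box and carry the `voxel` attribute used by the analysis
#' functions.
#'
#' @param kind one of `"fcc"`, `"hcp"`, `"planar_hex"`, `"noise"`,
#'   `"shuffled"`.
#' @param a field spacing in box units (must be smaller than the box).
#' @param resolution voxels per axis (`>= 32`).
#' @param n sharpening power of the analytic fields.
#' @param box box side (default 1).
#' @return 3D array with attribute `voxel`.
#' @export
make_fixture <- function(kind = c("fcc", "hcp", "planar_hex", "noise",
                                  "shuffled"),
                         a = 0.35, resolution = 48, n = 12, box = 1) {
  kind <- match.arg(kind)
  stopifnot(resolution >= 32)
  if (a >= box) stop("spacing must be smaller than the box")
  voxel <- box / resolution
  g <- (seq_len(resolution) - 0.5) * voxel
  x <- as.matrix(expand.grid(x = g, y = g, z = g))
  vals <- switch(kind,
    fcc = psi_lattice(x, lattice_spec("fcc", a, n)),
    hcp = psi_lattice(x, lattice_spec("hcp", a, n)),
    planar_hex = {
      Kxy <- hcp_xy_wavevectors(a)
      base <- 1 + (2 / 3) * rowSums(cos(x[, 1:2] %*% t(Kxy)))
      base^n
    },
    noise = stats::rexp(resolution^3),   # isotropic structureless rates
    shuffled = {
      v <- psi_lattice(x, lattice_spec("fcc", a, n))
      sample(v)
    })
  m <- array(vals, rep(resolution, 3))
  attr(m, "voxel") <- rep(voxel, 3)
  m
}
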