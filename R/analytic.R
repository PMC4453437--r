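#' @useDynLib gridcell3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft optimize optim rnorm runif sd median cor quantile
NULL

# package-local cache for Fourier-mode tables
.gridcell3d_cache <- new.env(parent = emptyenv())

#' Adaptation-kernel parameters
#'
#' The adaptation penalty uses a difference of two radially symmetric
#' Gaussians, a broad positive lobe of width `v_tau_l` (the distance covered
#' at typical speed during the slow adaptation time) minus a narrow lobe of
#' width `v_tau_s`, scaled by `rho`. The defaults (`v_tau_l = 1`,
#' `v_tau_s = v_tau_l / 3`, `rho = 0.03`) express lengths in units of the
#' slow adaptation length; the 1/3 ratio mirrors the ratio of the two
#' adaptation rates in the network model.
#'
#' @param v_tau_l width of the broad (long time-constant) Gaussian lobe.
#' @param v_tau_s width of the narrow (short time-constant) lobe; must be
#'   smaller than `v_tau_l`.
#' @param rho relative weight of the narrow lobe, in `[0, 1)`.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(v_tau_l = 1, v_tau_s = v_tau_l / 3, rho = 0.03) {
  stopifnot(v_tau_l > 0, v_tau_s > 0, v_tau_s < v_tau_l, rho >= 0, rho < 1)
  structure(list(v_tau_l = v_tau_l, v_tau_s = v_tau_s, rho = rho),
            class = "kernel_params")
}

#' Adaptation kernel in real space
#'
#' `K(q) = G(q; v_tau_l) - rho * G(q; v_tau_s)` where `G` is a normalized
#' isotropic 3D Gaussian of the given width.
#'
#' @param q distances (vector) at which to evaluate the kernel.
#' @param params a [kernel_params()] object.
#' @return kernel values, same length as `q`.
#' @export
adaptation_kernel <- function(q, params = kernel_params()) {
  g3 <- function(q, s) exp(-q^2 / (2 * s^2)) / (2 * pi * s^2)^(3 / 2)
  g3(q, params$v_tau_l) - params$rho * g3(q, params$v_tau_s)
}

#' Fourier transform of the adaptation kernel
#'
#' Closed form: `exp(-(k v_tau_l)^2 / 2) - rho * exp(-(k v_tau_s)^2 / 2)`.
#' At `k = 0` this equals `1 - rho`, the total kernel mass.
#'
#' @param k wave-number magnitudes (vector).
#' @param params a [kernel_params()] object.
#' @return transform values, same length as `k`.
#' @export
kernel_ft <- function(k, params = kernel_params()) {
  exp(-0.5 * (k * params$v_tau_l)^2) - params$rho * exp(-0.5 * (k * params$v_tau_s)^2)
}

# ---- plane-wave lattice constructions -------------------------------------

# FCC wave vectors (rows), in absolute units for spacing a.
# Directions are the four center-to-vertex axes of a tetrahedron; each has
# squared magnitude (3/2) (2 pi / a)^2 and pairwise dot product -(1/2)(2pi/a)^2.
fcc_wavevectors <- function(a = 1) {
  (2 * pi / a) * rbind(
    c(0, 0, sqrt(3 / 2)),
    c(sqrt(4 / 3), 0, -sqrt(1 / 6)),
    c(-sqrt(1 / 3), 1, -sqrt(1 / 6)),
    c(-sqrt(1 / 3), -1, -sqrt(1 / 6))
  )
}

# Three planar wave vectors of the triangular lattice with spacing a (rows,
# xy only); squared magnitude (4/3) (2 pi / a)^2.
hcp_xy_wavevectors <- function(a = 1) {
  (2 * pi / a) * rbind(
    c(sqrt(4 / 3), 0),
    c(-sqrt(1 / 3), 1),
    c(-sqrt(1 / 3), -1)
  )
}

# Stacking wave number giving a perfect ABA close packing: the two-layer
# period is 2*sqrt(2/3)*a, so |k_z| = sqrt(3/8) * (2 pi / a) and
# k_z / |k_xy| = 3 / sqrt(32) ~ 0.53.
hcp_kz_perfect <- function(a = 1) sqrt(3 / 8) * (2 * pi / a)

#' Analytic lattice description
#'
#' Describes a periodic plane-wave firing-field arrangement with FCC (ABC
#' layer stacking) or HCP (ABA stacking) symmetry, grid spacing `a`
#' (nearest-neighbor field distance) and sharpening power `n`. The field
#' function is a non-negative combination of cosines raised to the power `n`
#' and rescaled so its average over one periodic cell is exactly 1.
#'
#' For HCP the stacking wave number is a free parameter expressed through
#' `kz_ratio = |k_z| / |k_xy|`; the geometrically perfect close packing has
#' `kz_ratio = 3 / sqrt(32) ~ 0.5303`, which is the default.
#'
#' @param kind `"fcc"` or `"hcp"`.
#' @param a grid spacing (distance between neighboring fields).
#' @param n integer power `>= 1` sharpening the fields.
#' @param kz_ratio for HCP, the ratio of stacking to planar wave numbers.
#' @return an object of class `lattice_spec` with the normalization constant
#'   `p_n` precomputed.
#' @export
lattice_spec <- function(kind = c("fcc", "hcp"), a = 1, n = 1, kz_ratio = NULL) {
  kind <- match.arg(kind)
  if (n < 1) stop("power n must be >= 1")
  if (a <= 0) stop("spacing a must be positive")
  if (kind == "fcc" && !is.null(kz_ratio))
    stop("kz_ratio only applies to HCP")
  if (kind == "hcp" && is.null(kz_ratio)) kz_ratio <- 3 / sqrt(32)
  if (kind == "hcp") stopifnot(kz_ratio >= 0)
  spec <- structure(list(kind = kind, a = a, n = n, kz_ratio = kz_ratio,
                         p_n = NA_real_),
                    class = "lattice_spec")
  spec$p_n <- 1 / lattice_modes(kind, n)$c0_raw
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s  a = %g  n = %d  p_n = %.6g%s\n",
              toupper(x$kind), x$a, as.integer(x$n), x$p_n,
              if (x$kind == "hcp") sprintf("  kz/kxy = %.4g", x$kz_ratio) else ""))
  invisible(x)
}

# Un-normalized base field (before raising to power n and rescaling).
# x: m x 3 matrix of positions. For HCP, z enters only through the scaled
# coordinate zeta = k_z * z, so the base shape does not depend on kz_ratio.
lattice_base <- function(x, kind, a = 1, kz_ratio = 3 / sqrt(32)) {
  x <- rbind(x)
  if (kind == "fcc") {
    K <- fcc_wavevectors(a)
    ph <- x %*% t(K)
    1 + rowSums(cos(ph)) / 4
  } else {
    Kxy <- hcp_xy_wavevectors(a)
    kz <- kz_ratio * sqrt(4 / 3) * (2 * pi / a)
    delta <- c(a / sqrt(3), 0)           # in-plane shift of the B layer
    ph_a <- x[, 1:2, drop = FALSE] %*% t(Kxy)
    ph_b <- sweep(x[, 1:2, drop = FALSE], 2, delta, "-") %*% t(Kxy)
    hex_a <- 1 + (2 / 3) * rowSums(cos(ph_a))
    hex_b <- 1 + (2 / 3) * rowSums(cos(ph_b))
    zf <- kz * x[, 3]
    (0.5 + 0.5 * cos(zf)) * hex_a + (0.5 - 0.5 * cos(zf)) * hex_b
  }
}

#' Evaluate an analytic lattice field
#'
#' @param x positions, an `m x 3` matrix (or a length-3 vector).
#' @param spec a [lattice_spec()].
#' @return field values `psi_n(x) = p_n * base(x)^n`, non-negative, with
#'   unit average over a periodic cell.
#' @export
psi_lattice <- function(x, spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  base <- lattice_base(x, spec$kind, spec$a,
                       if (is.null(spec$kz_ratio)) 3 / sqrt(32) else spec$kz_ratio)
  spec$p_n * pmax(base, 0)^spec$n
}

# ---- Fourier-mode tables ---------------------------------------------------

# The base functions are finite cosine sums on a periodic cell:
#   FCC cell (sqrt(3), 1, sqrt(6)) * a; HCP cell (sqrt(3), 1, 2*pi/k_z) * a.
# All harmonics of base^n sit exactly on the FFT frequency grid, so an FFT of
# the sampled field recovers the mode amplitudes to machine precision.
# Coefficients depend only on (kind, n): spacing a and kz_ratio only rescale
# the wave vectors. Tables are cached.
#
# Returns list(idx = integer matrix (m x 3) of harmonic indices,
#              coef = real amplitudes normalized so the DC mode is 1,
#              c0_raw = DC amplitude of base^n).
lattice_modes <- function(kind, n, tol = 1e-9) {
  key <- paste(kind, n, sep = "_")
  if (!is.null(.gridcell3d_cache[[key]])) return(.gridcell3d_cache[[key]])
  n <- as.integer(n)
  # per-axis maximum harmonic index of base^n
  if (kind == "fcc") {
    mx <- c(2L, 1L, 3L) * n
    cell <- c(sqrt(3), 1, sqrt(6))
  } else {
    mx <- c(2L, 1L, 1L) * n
    cell <- c(sqrt(3), 1, 2 * pi / hcp_kz_perfect(1))
  }
  N <- pmax(2L * mx + 2L, 8L)
  N <- vapply(N, function(k) stats::nextn(k, c(2, 3, 5)), integer(1))
  grids <- lapply(1:3, function(d) (0:(N[d] - 1)) / N[d] * cell[d])
  x <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  vals <- lattice_base(x, kind, a = 1)^n
  arr <- array(vals, dim = N)
  co <- fft(arr) / prod(N)
  keep <- which(Mod(co) > tol * max(Mod(co)), arr.ind = TRUE)
  idx <- keep - 1L
  for (d in 1:3) {
    wrap <- idx[, d] >= N[d] / 2
    idx[wrap, d] <- idx[wrap, d] - N[d]
  }
  coef <- co[keep]                     # complex: HCP has no central symmetry
  c0 <- Re(coef[rowSums(abs(idx)) == 0])
  out <- list(idx = idx, coef = coef / c0, c0_raw = c0)
  .gridcell3d_cache[[key]] <- out
  out
}

# Wave vectors (m x 3) for a mode table under a given spacing / ratio.
mode_wavevectors <- function(idx, kind, a, kz_ratio) {
  qx <- idx[, 1] * 2 * pi / (sqrt(3) * a)
  qy <- idx[, 2] * 2 * pi / a
  qz <- if (kind == "fcc") {
    idx[, 3] * 2 * pi / (sqrt(6) * a)
  } else {
    idx[, 3] * kz_ratio * sqrt(4 / 3) * (2 * pi / a)
  }
  cbind(qx, qy, qz)
}

#' Cost function of an analytic lattice state
#'
#' Evaluates the two terms of the variational cost by exact Fourier-mode
#' expansion of the finite cosine sum: the kinetic term
#' `H_K = <|grad psi|^2>` and the adaptation term
#' `H_A = sum_q |c_q|^2 Ktilde(|q|)` over the non-constant modes, with the
#' kernel entering through its closed-form transform. The constant mode
#' contributes `(1 - rho)` to the adaptation term independently of spacing
#' and stacking ratio; it is reported separately as `H_A_dc` and excluded
#' from `H_A` and `H`, so that the trivial uniform state has `H = 0`.
#'
#' @param spec a [lattice_spec()].
#' @param gamma relative weight of the adaptation term (`>= 0`).
#' @param params a [kernel_params()] object.
#' @return list with `H_K`, `H_A` (kernel-weighted, without `gamma`),
#'   `H = H_K + gamma * H_A`, and `H_A_dc`.
#' @export
lattice_cost <- function(spec, gamma, params = kernel_params()) {
  stopifnot(inherits(spec, "lattice_spec"), gamma >= 0)
  m <- lattice_modes(spec$kind, spec$n)
  q <- mode_wavevectors(m$idx, spec$kind, spec$a,
                        if (is.null(spec$kz_ratio)) 0 else spec$kz_ratio)
  q2 <- rowSums(q^2)
  w <- Mod(m$coef)^2
  nz <- q2 > 1e-20
  H_K <- sum(w[nz] * q2[nz])
  H_A <- sum(w[nz] * kernel_ft(sqrt(q2[nz]), params))
  list(H_K = H_K, H_A = H_A, H = H_K + gamma * H_A,
       H_A_dc = kernel_ft(0, params))
}

#' Cost function by real-space quadrature (independent check)
#'
#' Recomputes both cost terms from a sampled field on one periodic cell:
#' the kinetic term by fourth-order central finite differences and the
#' adaptation term by circular convolution with the real-space kernel
#' (periodic images, truncated at `trunc_sd` widths of the broad lobe).
#' Serves as an oracle for [lattice_cost()]; it shares no code path with the
#' mode expansion.
#'
#' @param spec a [lattice_spec()].
#' @param gamma adaptation weight.
#' @param params a [kernel_params()].
#' @param nbase grid points along the shortest cell edge.
#' @param trunc_sd kernel truncation radius in units of `v_tau_l`.
#' @param origin translation applied to the field before sampling; the cost
#'   of a periodic state is translation invariant, so the result must not
#'   depend on it.
#' @return list with `H_K`, `H_A`, `H` as in [lattice_cost()].
#' @export
lattice_cost_quadrature <- function(spec, gamma, params = kernel_params(),
                                    nbase = 64, trunc_sd = 5,
                                    origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "lattice_spec"))
  cell <- switch(spec$kind,
    fcc = c(sqrt(3), 1, sqrt(6)) * spec$a,
    hcp = c(sqrt(3), 1, 2 * pi / (spec$kz_ratio * sqrt(4 / 3) * 2 * pi / spec$a))
  )
  if (spec$kind == "hcp" && spec$kz_ratio <= 0)
    stop("quadrature oracle requires kz_ratio > 0")
  N <- pmax(8L, as.integer(round(cell / min(cell) * nbase)))
  N <- vapply(N, function(k) stats::nextn(k, c(2, 3, 5)), integer(1))
  h <- cell / N
  grids <- lapply(1:3, function(d) (0:(N[d] - 1)) * h[d])
  x <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  psi <- array(psi_lattice(sweep(x, 2, origin, "+"), spec), dim = N)

  # kinetic term: 4th-order centered first derivative on the periodic grid
  d1 <- function(arr, d) {
    sh <- function(k) {
      i <- (seq_len(N[d]) - 1 + k) %% N[d] + 1
      switch(d, arr[i, , ], arr[, i, ], arr[, , i])
    }
    (8 * (sh(1) - sh(-1)) - (sh(2) - sh(-2))) / (12 * h[d])
  }
  H_K <- mean(d1(psi, 1)^2 + d1(psi, 2)^2 + d1(psi, 3)^2)

  # adaptation term: kernel periodized on the cell. Both lobes are separable
  # Gaussians, so each periodized lobe is an outer product of 1D sums over
  # periodic images (as many images as trunc_sd widths require).
  lobe <- function(sigma) {
    ax <- lapply(1:3, function(d) {
      g <- (0:(N[d] - 1)) * h[d]
      M <- ceiling(trunc_sd * sigma / cell[d]) + 1L
      rowSums(sapply((-M):M, function(m) exp(-(g + m * cell[d])^2 / (2 * sigma^2))))
    })
    outer(outer(ax[[1]], ax[[2]]), ax[[3]]) / (2 * pi * sigma^2)^(3 / 2)
  }
  ker <- lobe(params$v_tau_l) - params$rho * lobe(params$v_tau_s)
  conv <- Re(fft(fft(psi) * fft(ker), inverse = TRUE)) / prod(N) * prod(h)
  H_A_full <- mean(psi * conv)
  dc <- mean(psi)^2 * sum(ker) * prod(h)
  H_A <- H_A_full - dc
  list(H_K = H_K, H_A = H_A, H = H_K + gamma * H_A)
}

#' Ideal close-packed lattice points
#'
#' Generates field centers of an ideal FCC (ABC layer sequence) or HCP (ABA)
#' close packing with nearest-neighbor distance `a`, covering a cube of side
#' `extent` centered at the origin. Layers are triangular lattices stacked
#' along z at separation `a * sqrt(2/3)`.
#'
#' @param kind `"fcc"` or `"hcp"`.
#' @param a nearest-neighbor distance.
#' @param extent cube side to fill.
#' @return a matrix of points (m x 3).
#' @export
lattice_points <- function(kind = c("fcc", "hcp"), a = 1, extent = 4) {
  kind <- match.arg(kind)
  if (extent < 2 * a) stop("extent must be at least 2 * a")
  dz <- a * sqrt(2 / 3)
  a1 <- c(a, 0)
  a2 <- c(a / 2, a * sqrt(3) / 2)
  off_b <- (a1 + a2) / 3
  nl <- ceiling(extent / 2 / dz) + 2
  nij <- ceiling(extent / a) + 3
  pts <- list()
  for (l in (-nl):nl) {
    phase <- if (kind == "fcc") l %% 3 else l %% 2
    off <- switch(phase + 1, c(0, 0), off_b, 2 * off_b)
    ij <- as.matrix(expand.grid(i = (-nij):nij, j = (-nij):nij))
    xy <- cbind(ij[, 1] * a1[1] + ij[, 2] * a2[1] + off[1],
                ij[, 1] * a1[2] + ij[, 2] * a2[2] + off[2])
    pts[[length(pts) + 1]] <- cbind(xy, l * dz)
  }
  p <- do.call(rbind, pts)
  colnames(p) <- c("x", "y", "z")
  p[apply(abs(p) <= extent / 2 + 1e-9, 1, all), , drop = FALSE]
}

# ---- optimization over spacing and stacking ratio --------------------------

#' Minimize the lattice cost over grid spacing (and stacking ratio)
#'
#' For FCC the cost is minimized over the spacing `a` alone; for HCP jointly
#' over `a` and `kz_ratio = |k_z|/|k_xy|`. The search runs a deterministic
#' coarse grid scan followed by local refinement, so it is robust to the
#' multiple local minima the mode structure can create.
#'
#' If the attained minimum is positive, a uniform (zero-modulation) state is
#' cheaper and the result is flagged `trivial_favored`.
#'
#' @param kind `"fcc"` or `"hcp"`.
#' @param n field-sharpening power.
#' @param gamma adaptation weight.
#' @param params a [kernel_params()].
#' @param a_range search interval for the spacing, in kernel-length units.
#' @param ratio_range search interval for the HCP stacking ratio.
#' @return list with `a_opt`, `kz_ratio_opt` (HCP; otherwise `NA`), `H_opt`,
#'   the two cost terms at the optimum and `trivial_favored`.
#' @export
optimize_lattice <- function(kind = c("fcc", "hcp"), n = 1, gamma = 1,
                             params = kernel_params(),
                             a_range = c(0.3, 40) * params$v_tau_l,
                             ratio_range = c(0, 1.2)) {
  kind <- match.arg(kind)
  m <- lattice_modes(kind, n)
  costfun <- function(a, ratio) {
    q <- mode_wavevectors(m$idx, kind, a, ratio)
    q2 <- rowSums(q^2)
    w <- Mod(m$coef)^2
    nz <- q2 > 1e-20
    sum(w[nz] * q2[nz]) + gamma * sum(w[nz] * kernel_ft(sqrt(q2[nz]), params))
  }
  la <- seq(log(a_range[1]), log(a_range[2]), length.out = 160)
  if (kind == "fcc") {
    hs <- vapply(la, function(l) costfun(exp(l), 0), numeric(1))
    i <- which.min(hs)
    lo <- la[max(1, i - 1)]; hi <- la[min(length(la), i + 1)]
    opt <- optimize(function(l) costfun(exp(l), 0), c(lo, hi), tol = 1e-10)
    a_opt <- exp(opt$minimum); ratio_opt <- NA_real_; H_opt <- opt$objective
  } else {
    rs <- seq(ratio_range[1], ratio_range[2], length.out = 49)
    grid <- expand.grid(la = la[seq(1, length(la), by = 2)], r = rs)
    hs <- mapply(function(l, r) costfun(exp(l), r), grid$la, grid$r)
    i <- which.min(hs)
    start <- c(grid$la[i], grid$r[i])
    opt <- optim(start,
                 function(p) costfun(exp(p[1]), max(p[2], 0)),
                 method = "L-BFGS-B",
                 lower = c(log(a_range[1]), ratio_range[1]),
                 upper = c(log(a_range[2]), ratio_range[2]),
                 control = list(factr = 1e4))
    a_opt <- exp(opt$par[1]); ratio_opt <- max(opt$par[2], 0)
    H_opt <- opt$value
  }
  spec <- if (kind == "fcc") lattice_spec("fcc", a_opt, n)
          else lattice_spec("hcp", a_opt, n, kz_ratio = ratio_opt)
  terms <- lattice_cost(spec, gamma, params)
  list(kind = kind, n = n, gamma = gamma,
       a_opt = a_opt, kz_ratio_opt = ratio_opt,
       H_opt = H_opt, H_K = terms$H_K, H_A = terms$H_A,
       trivial_favored = H_opt > 0)
}

# ---- relaxation-curve fitting ---------------------------------------------

#' Fit double-exponential relaxation curves to cost timecourses
#'
#' Jointly fits the kinetic and adaptation cost series with
#' `H_K(t) = A exp(-t/tau_s) + B exp(-t/tau_l) + K` and
#' `H_A(t) = C exp(-t/tau_s) - D exp(-t/tau_m) + E`,
#' sharing the short time constant `tau_s` between the two, by
#' Levenberg-Marquardt least squares with non-negativity bounds on the
#' amplitudes. Each series is weighted by its spread so neither dominates.
#'
#' The empirical weighting factor `gamma_star` is the largest `gamma` for
#' which the fitted `H_K(t) + gamma * H_A(t)` is monotonically non-increasing
#' over the fitted range (`Inf` when the adaptation curve never rises).
#'
#' @param t time points (length `>= 20`).
#' @param h_k kinetic cost series.
#' @param h_a adaptation cost series.
#' @return an object of class `cost_fit`: named coefficients, `gamma_star`,
#'   fitted curves, residuals and convergence info.
#' @export
fit_cost_timecourse <- function(t, h_k, h_a) {
  stopifnot(length(t) >= 20, length(h_k) == length(t), length(h_a) == length(t))
  span <- diff(range(t))
  sk <- stats::sd(h_k); sa <- stats::sd(h_a)
  if (sk < 1e-14 * max(abs(h_k), 1) && sa < 1e-14 * max(abs(h_a), 1)) {
    cf <- c(A = 0, B = 0, K = mean(h_k), C = 0, D = 0, E = mean(h_a),
            tau_s = span / 10, tau_m = span / 3, tau_l = span / 2)
    return(structure(list(coefficients = cf, gamma_star = Inf,
                          t = t, fitted_k = rep(mean(h_k), length(t)),
                          fitted_a = rep(mean(h_a), length(t)),
                          converged = TRUE, message = "constant series"),
                     class = "cost_fit"))
  }
  wk <- 1 / max(sk, 1e-12); wa <- 1 / max(sa, 1e-12)
  model_k <- function(p, t) p["A"] * exp(-t / p["tau_s"]) +
    p["B"] * exp(-t / p["tau_l"]) + p["K"]
  model_a <- function(p, t) p["C"] * exp(-t / p["tau_s"]) -
    p["D"] * exp(-t / p["tau_m"]) + p["E"]
  resid_fun <- function(p) {
    names(p) <- nm
    c(wk * (model_k(p, t) - h_k), wa * (model_a(p, t) - h_a))
  }
  nm <- c("A", "B", "K", "C", "D", "E", "tau_s", "tau_m", "tau_l")
  start <- c(A = max(h_k[1] - min(h_k), sk), B = sk, K = max(min(h_k), 0),
             C = max(h_a[1] - min(h_a), sa), D = sa,
             E = max(mean(h_a[t > stats::quantile(t, 0.8)]), 0),
             tau_s = span / 20, tau_m = span / 5, tau_l = span / 2)
  lower <- c(0, 0, 0, 0, 0, 0, span * 1e-4, span * 1e-4, span * 1e-4)
  upper <- c(rep(Inf, 6), span * 100, span * 100, span * 100)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par; names(p) <- nm
  tg <- seq(min(t), max(t), length.out = 2000)
  dk <- -p["A"] / p["tau_s"] * exp(-tg / p["tau_s"]) -
    p["B"] / p["tau_l"] * exp(-tg / p["tau_l"])
  da <- -p["C"] / p["tau_s"] * exp(-tg / p["tau_s"]) +
    p["D"] / p["tau_m"] * exp(-tg / p["tau_m"])
  pos <- da > 1e-12 * max(abs(da), 1e-300)
  gamma_star <- if (!any(pos)) Inf else min(-dk[pos] / da[pos])
  structure(list(coefficients = p, gamma_star = unname(gamma_star),
                 t = t, fitted_k = model_k(p, t), fitted_a = model_a(p, t),
                 converged = fit$info %in% 1:4, message = fit$message),
            class = "cost_fit")
}

#' @export
print.cost_fit <- function(x, ...) {
  cat("<cost_fit> double-exponential relaxation fit\n")
  print(round(x$coefficients, 6))
  cat(sprintf("gamma_star = %g   converged: %s\n", x$gamma_star, x$converged))
  invisible(x)
}
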