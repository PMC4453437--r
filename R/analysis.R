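# 3D gridness analysis: masked autocorrelograms, spacing, best-plane
# hexagonality, FCC/HCP long-range order scores, spike-triplet local
# gridness, population alignment and empirical cost terms.

#' Masked 3D spatial autocorrelogram
#'
#' Pearson correlation of the map with itself at every voxel displacement up
#' to `max_lag`, computed over the voxels where both copies are observed
#' (missing voxels are excluded). Displacements whose overlap is below
#' `min_overlap` of the map volume are masked. All pairwise sums are
#' obtained by FFT cross-correlation, so the cost is a handful of FFTs
#' regardless of lag range.
#'
#' @param map 3D array, possibly with `NA` for unvisited voxels; voxel edge
#'   lengths may be attached as attribute `voxel`.
#' @param max_lag maximum displacement in voxels (default: half the grid).
#' @param min_overlap minimum valid-voxel overlap fraction.
#' @return object of class `autocorr3d`: correlation array
#'   (`(2 max_lag + 1)^3`, center = zero displacement), overlap counts `n`,
#'   and voxel sizes.
#' @export
autocorr3d <- function(map, max_lag = NULL, min_overlap = 0.05) {
  d <- dim(map)
  stopifnot(length(d) == 3)
  voxel <- attr(map, "voxel") %||% rep(1 / d[1], 3)
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  max_lag <- max_lag %||% floor(min(d) / 2)
  W <- is.finite(map)
  vals <- map[W]
  if (length(vals) < 2 || stats::sd(vals) == 0) {
    warning("constant or empty map: autocorrelogram undefined")
    side <- 2 * max_lag + 1
    return(structure(list(ac = array(NA_real_, rep(side, 3)),
                          n = array(0, rep(side, 3)),
                          voxel = voxel, max_lag = max_lag),
                     class = "autocorr3d"))
  }
  M <- map; M[!W] <- 0
  pad <- d + max_lag + 1L
  pad <- vapply(pad, function(k) stats::nextn(k, c(2, 3, 5)), integer(1))
  emb <- function(x) { a <- array(0, pad); a[1:d[1], 1:d[2], 1:d[3]] <- x; a }
  FM <- fft(emb(M)); FW <- fft(emb(W * 1)); FM2 <- fft(emb(M^2))
  # S_AB(delta) = sum_x A(x) B(x + delta)
  xc <- function(FA, FB) Re(fft(Conj(FA) * FB, inverse = TRUE)) / prod(pad)
  n_d <- xc(FW, FW)
  s1 <- xc(FM, FW)    # sum M(x) W(x+d)
  s2 <- xc(FW, FM)    # sum W(x) M(x+d)
  s11 <- xc(FM2, FW)
  s22 <- xc(FW, FM2)
  s12 <- xc(FM, FM)
  # extract the centered block of displacements
  sel <- function(arr) {
    idx <- lapply(1:3, function(dd) {
      lags <- (-max_lag):max_lag
      ifelse(lags < 0, pad[dd] + lags + 1L, lags + 1L)
    })
    arr[idx[[1]], idx[[2]], idx[[3]]]
  }
  n_d <- pmax(sel(n_d), 0)
  s1 <- sel(s1); s2 <- sel(s2); s11 <- sel(s11); s22 <- sel(s22); s12 <- sel(s12)
  va <- s11 - s1^2 / pmax(n_d, 1)
  vb <- s22 - s2^2 / pmax(n_d, 1)
  ac <- (s12 - s1 * s2 / pmax(n_d, 1)) / sqrt(pmax(va, 0) * pmax(vb, 0))
  bad <- n_d < min_overlap * prod(d) | va <= 1e-12 * max(va) | vb <= 1e-12 * max(vb)
  ac[bad] <- NA_real_
  ac[ac > 1] <- 1; ac[ac < -1] <- -1
  ctr <- max_lag + 1L
  ac[ctr, ctr, ctr] <- 1
  structure(list(ac = ac, n = round(n_d), voxel = voxel, max_lag = max_lag),
            class = "autocorr3d")
}

#' @export
print.autocorr3d <- function(x, ...) {
  cat(sprintf("<autocorr3d> max_lag = %d voxels (voxel = %s L), %.1f%% masked\n",
              x$max_lag, paste(signif(x$voxel, 3), collapse = "x"),
              100 * mean(is.na(x$ac))))
  invisible(x)
}

# displacement radii (L units) for every cell of the autocorrelogram
ac_radii <- function(ac) {
  lags <- (-ac$max_lag):ac$max_lag
  gx <- lags * ac$voxel[1]; gy <- lags * ac$voxel[2]; gz <- lags * ac$voxel[3]
  sqrt(outer(outer(gx^2, gy^2, "+"), gz^2, "+"))
}

#' Spherically averaged correlation profile
#'
#' @param ac an [autocorr3d()] object.
#' @param binwidth radial bin width in L units (default: one voxel).
#' @return data.frame with bin center `r`, mean correlation `value`, count.
#' @export
radial_profile <- function(ac, binwidth = NULL) {
  binwidth <- binwidth %||% min(ac$voxel)
  r <- ac_radii(ac)
  ok <- is.finite(ac$ac)
  bin <- floor(r[ok] / binwidth)
  val <- tapply(ac$ac[ok], bin, mean)
  cnt <- tapply(ac$ac[ok], bin, length)
  b <- as.integer(names(val))
  data.frame(r = (b + 0.5) * binwidth, value = as.vector(val),
             n = as.vector(cnt))
}

#' Grid spacing from the autocorrelogram
#'
#' The first local maximum of the (lightly smoothed) radial correlation
#' profile beyond the central peak, refined by parabolic interpolation.
#' `NA` (with a warning) when no secondary peak exists.
#'
#' @param ac an [autocorr3d()] object.
#' @return spacing in L units, or `NA`.
#' @export
grid_spacing <- function(ac) {
  rp <- radial_profile(ac)
  if (nrow(rp) < 5) {
    warning("no secondary peak in radial profile")
    return(NA_real_)
  }
  v <- as.vector(stats::filter(rp$value, rep(1, 3) / 3, sides = 2))
  v[1] <- rp$value[1]; v[length(v)] <- rp$value[length(v)]
  # end of the central decay
  i_min <- NA
  for (i in 2:(length(v) - 1)) {
    if (v[i] <= v[i - 1] && v[i] < v[i + 1]) { i_min <- i; break }
  }
  if (is.na(i_min)) { warning("no secondary peak in radial profile"); return(NA_real_) }
  i_pk <- NA
  for (i in (i_min + 1):(length(v) - 1)) {
    if (v[i] >= v[i - 1] && v[i] > v[i + 1]) { i_pk <- i; break }
  }
  if (is.na(i_pk)) { warning("no secondary peak in radial profile"); return(NA_real_) }
  # a structureless map produces an essentially flat profile whose noise
  # wiggles would otherwise be declared a peak
  if (v[i_pk] - v[i_min] < 0.002) {
    warning("no secondary peak in radial profile")
    return(NA_real_)
  }
  # parabolic refinement around the peak bin
  y <- v[(i_pk - 1):(i_pk + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  off <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
  off <- max(min(off, 1), -1)
  rp$r[i_pk] + off * (rp$r[2] - rp$r[1])
}

#' Autocorrelogram peaks
#'
#' Local maxima of the smoothed correlation array above a threshold
#' (default 0.2, the contour level used to delineate fields), excluding the
#' central peak.
#'
#' @param ac an [autocorr3d()] object.
#' @param threshold minimum correlation.
#' @param smooth_sigma Gaussian smoothing in voxels applied before detection.
#' @return data.frame with displacement components (L units), radius and
#'   correlation value of each peak.
#' @export
ac_peaks <- function(ac, threshold = 0.2, smooth_sigma = 1) {
  acs <- gaussian_smooth3d(ac$ac, smooth_sigma)
  pk <- local_maxima3d(acs, threshold)
  ctr <- ac$max_lag + 1L
  keep <- rowSums(abs(pk - ctr)) > 0
  pk <- pk[keep, , drop = FALSE]
  disp <- sweep(pk, 2, ctr) * rep(ac$voxel, each = nrow(pk))
  data.frame(dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
             radius = sqrt(rowSums(disp^2)),
             value = acs[pk])
}

# orthonormal basis perpendicular to a unit vector
plane_basis <- function(n) {
  e <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- e - sum(e * n) * n
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(n[2] * u1[3] - n[3] * u1[2],
          n[3] * u1[1] - n[1] * u1[3],
          n[1] * u1[2] - n[2] * u1[1])
  cbind(u1, u2)
}

# Hexagonality scores of central slices. acs: smoothed correlation array
# (NA replaced by 0); normals: m x 3 unit rows; d_vox: first-shell radius in
# voxels. Each slice is sampled on a polar patch spanning the peak ring and
# correlated with itself rotated by 60 degrees -- the planar hexagonal
# template with pi/3 periodicity: a hexagonal slice scores ~1, a slice with
# peaks in non-hexagonal positions scores near or below 0. The in-plane
# hexagon axis is the peak direction of the 60-degree-folded ring profile.
slice_hex_scores <- function(acs, normals, d_vox, n_theta = 72,
                             radii = c(0.7, 0.85, 1, 1.15, 1.3),
                             center = TRUE) {
  ctr <- (dim(acs)[1] + 1) / 2
  m <- nrow(normals)
  t_ang <- (0:(n_theta - 1)) * 2 * pi / n_theta
  rot <- n_theta / 6                       # 60 degrees in angle samples
  scores <- numeric(m); axes <- matrix(NA_real_, m, 3)
  for (j in seq_len(m)) {
    B <- plane_basis(normals[j, ])
    patch <- matrix(0, n_theta, length(radii))
    for (ri in seq_along(radii)) {
      rr <- radii[ri] * d_vox
      pts <- ctr + rr * (outer(cos(t_ang), B[, 1]) + outer(sin(t_ang), B[, 2]))
      v <- interp3(acs, pts)
      # centering removes the radial profile, which is rotation invariant
      # by construction and would otherwise dominate the correlation; plane
      # detection uses the centered form, the zeta slice scores keep the
      # full planar values (their ratio removes the shared baseline)
      patch[, ri] <- if (center) v - mean(v) else v
    }
    shifted <- patch[c((rot + 1):n_theta, 1:rot), , drop = FALSE]
    if (stats::sd(patch) < 1e-12) { scores[j] <- 0; next }
    scores[j] <- stats::cor(as.vector(patch), as.vector(shifted))
    # hexagon axis from the 60-degree-folded mean ring profile
    prof <- rowMeans(patch)
    fold <- rowSums(matrix(prof, nrow = rot))
    pk <- which.max(fold)
    y <- fold[c((pk - 2) %% rot + 1, pk, pk %% rot + 1)]
    den <- y[1] - 2 * y[2] + y[3]
    off <- if (abs(den) > 1e-12) max(min(0.5 * (y[1] - y[3]) / den, 1), -1) else 0
    phi <- (pk - 1 + off) * 2 * pi / n_theta
    axes[j, ] <- cos(phi) * B[, 1] + sin(phi) * B[, 2]
  }
  list(score = scores, axis = axes)
}

# hemisphere grid of unit normals at a given angular step (degrees)
hemisphere_normals <- function(step = 5) {
  az <- seq(0, 180 - step, by = step) * pi / 180
  el <- seq(-90, 90, by = step) * pi / 180
  g <- expand.grid(az = az, el = el)
  cbind(cos(g$el) * cos(g$az), cos(g$el) * sin(g$az), sin(g$el))
}

#' Best hexagonal plane of a 3D autocorrelogram
#'
#' Scans central slices over the hemisphere of normals, scoring each slice's
#' first-shell ring against a hexagonal template of equidistant peaks with
#' pi/3 periodicity ([slice_hex_scores()]), with a refinement pass around
#' the coarse optimum. The best plane's normal is the layer-stacking axis of
#' the unit's field arrangement.
#'
#' @param ac an [autocorr3d()] object.
#' @param d grid spacing (L units); measured via [grid_spacing()] if `NULL`.
#' @param step coarse angular step in degrees.
#' @param refine_step refinement step in degrees.
#' @return list with `normal`, `score`, in-plane hexagon `axis`, and `d`;
#'   score 0 and undefined normal when no spacing is measurable.
#' @export
best_plane <- function(ac, d = NULL, step = 5, refine_step = 1) {
  d <- d %||% grid_spacing(ac)
  if (is.na(d)) return(list(normal = rep(NA_real_, 3), score = 0,
                            axis = rep(NA_real_, 3), d = NA_real_))
  acs <- gaussian_smooth3d(ac$ac, 1)
  acs[is.na(acs)] <- 0
  stopifnot(abs(ac$voxel[1] - ac$voxel[2]) < 1e-9,
            abs(ac$voxel[1] - ac$voxel[3]) < 1e-9)
  d_vox <- d / ac$voxel[1]
  nrm <- hemisphere_normals(step)
  sc <- slice_hex_scores(acs, nrm, d_vox)
  best <- which.max(sc$score)
  n0 <- nrm[best, ]
  # refinement: perturb around the coarse optimum
  B <- plane_basis(n0)
  dev <- expand.grid(a = seq(-step, step, by = refine_step) * pi / 180,
                     b = seq(-step, step, by = refine_step) * pi / 180)
  nref <- t(apply(dev, 1, function(ab) {
    v <- n0 + tan(ab[1]) * B[, 1] + tan(ab[2]) * B[, 2]
    v / sqrt(sum(v^2))
  }))
  scr <- slice_hex_scores(acs, nref, d_vox)
  j <- which.max(scr$score)
  list(normal = nref[j, ], score = scr$score[j], axis = scr$axis[j, ], d = d)
}

#' Count hexagonal central planes
#'
#' Scans the hemisphere of slice normals and counts distinct local maxima of
#' the hexagonality score above a threshold, merging directions closer than
#' `merge_deg`. An ideal FCC autocorrelogram has 4 such planes, an ideal
#' HCP one 7.
#'
#' @param ac an [autocorr3d()] object.
#' @param d grid spacing; measured if `NULL`.
#' @param threshold minimum slice score.
#' @param step scan step (degrees).
#' @param merge_deg merge radius (degrees).
#' @return data.frame of plane normals and scores, one row per plane.
#' @export
hex_planes <- function(ac, d = NULL, threshold = 0.75, step = 3,
                       merge_deg = 25) {
  d <- d %||% grid_spacing(ac)
  if (is.na(d)) return(data.frame())
  acs <- gaussian_smooth3d(ac$ac, 1)
  acs[is.na(acs)] <- 0
  d_vox <- d / ac$voxel[1]
  nrm <- hemisphere_normals(step)
  sc <- slice_hex_scores(acs, nrm, d_vox)$score
  ord <- order(sc, decreasing = TRUE)
  sel <- list()
  for (j in ord) {
    if (sc[j] < threshold) break
    nj <- nrm[j, ]
    dup <- FALSE
    for (s in sel) {
      ang <- acos(pmin(abs(sum(nj * nrm[s, ])), 1)) * 180 / pi
      if (ang < merge_deg) { dup <- TRUE; break }
    }
    if (!dup) sel[[length(sel) + 1]] <- j
  }
  if (!length(sel)) return(data.frame())
  idx <- unlist(sel)
  data.frame(nx = nrm[idx, 1], ny = nrm[idx, 2], nz = nrm[idx, 3],
             score = sc[idx])
}

# angle between two lines (normals up to sign), degrees in [0, 90]
line_angle <- function(u, v) acos(pmin(abs(sum(u * v)), 1)) * 180 / pi

#' FCC/HCP long-range order scores
#'
#' Measures how the hexagonal planes beyond the best one are arranged.
#' `zeta_24` sums the hexagonality scores of the best triplet of central
#' slices tilted ~72 degrees away from the best plane with ~120-degree
#' azimuthal separations (present in both FCC and HCP); `zeta_57` does the
#' same for the interleaved triplet rotated 60 degrees in azimuth, which
#' only an HCP arrangement populates (~56 degrees from the members of the
#' first triplet). The FCC similarity score is
#' `chi_fcc = (zeta_24 - zeta_57) / zeta_24`.
#'
#' Layer periodicity is probed directly on the correlation array:
#' `lambda_z = sqrt(2/3) d` is the interlayer distance of a close packing
#' with spacing `d`, and `chi_hcp` is the autocorrelation at a two-layer
#' displacement along the stacking axis -- high when the pattern repeats
#' every two layers (ABA stacking), low for the three-layer FCC period.
#'
#' @param ac an [autocorr3d()] object.
#' @param d grid spacing; measured if `NULL`.
#' @param best output of [best_plane()]; computed if `NULL`.
#' @param cone_deg cone angles scanned around the nominal 72 degrees.
#' @param az_tol azimuthal tolerance (degrees) for triplet members.
#' @return list with `zeta_24`, `zeta_57`, `chi_fcc`, `chi_hcp`,
#'   `lambda_z`, and the `best` plane used.
#' @export
fcc_hcp_scores <- function(ac, d = NULL, best = NULL,
                           cone_deg = seq(64, 80, by = 2), az_tol = 8) {
  d <- d %||% grid_spacing(ac)
  if (is.na(d)) return(list(zeta_24 = NA_real_, zeta_57 = NA_real_,
                            chi_fcc = NA_real_, chi_hcp = NA_real_,
                            lambda_z = NA_real_, best = NULL))
  best <- best %||% best_plane(ac, d)
  acs <- gaussian_smooth3d(ac$ac, 1)
  acs[is.na(acs)] <- 0
  d_vox <- d / ac$voxel[1]
  n0 <- best$normal
  B <- plane_basis(n0)
  az_step <- 2
  az <- seq(0, 360 - az_step, by = az_step) * pi / 180
  cone <- cone_deg * pi / 180
  g <- expand.grid(az = az, cone = cone)
  tang <- outer(cos(g$az), B[, 1]) + outer(sin(g$az), B[, 2])
  nrm <- outer(cos(g$cone), n0) + sweep(tang, 1, sin(g$cone), "*")
  sc <- slice_hex_scores(acs, nrm, d_vox, center = FALSE)$score
  smax <- tapply(sc, g$az, max)                  # best score per azimuth
  az_deg <- as.numeric(names(smax)) * 180 / pi
  n_az <- length(az_deg)
  # periodic window lookup: max of smax within +- az_tol of a target azimuth
  win_max <- function(target) {
    dd <- (az_deg - target + 180) %% 360 - 180
    sel <- abs(dd) <= az_tol
    list(value = max(smax[sel]), az = az_deg[sel][which.max(smax[sel])])
  }
  # first triplet: azimuths az0 + {0, 120, 240}
  best_tot <- -Inf; best_members <- NULL
  for (az0 in seq(0, 118, by = az_step)) {
    ms <- lapply(c(0, 120, 240), function(o) win_max(az0 + o))
    tot <- sum(vapply(ms, `[[`, numeric(1), "value"))
    if (tot > best_tot) { best_tot <- tot; best_members <- ms }
  }
  zeta_24 <- best_tot
  # second triplet: 60 degrees in azimuth from the first members
  ms2 <- lapply(best_members, function(m) win_max(m$az + 60))
  zeta_57 <- sum(vapply(ms2, `[[`, numeric(1), "value"))
  # the ratio is only meaningful when the first triplet actually contains
  # hexagonal planes; near-zero denominators produce unbounded values
  chi_fcc <- if (is.finite(zeta_24) && zeta_24 >= 0.75)
    (zeta_24 - zeta_57) / zeta_24 else NA_real_
  # layer periodicity along the stacking axis: correlation at a two-layer
  # displacement (the repeat distance of ABA stacking). The probe takes the
  # strongest correlation within +-15% of 2 * lambda_z on the unsmoothed
  # array, absorbing the uncertainty of the measured spacing.
  lambda_z <- sqrt(2 / 3) * d
  ctr <- ac$max_lag + 1
  ac_raw <- ac$ac; ac_raw[is.na(ac_raw)] <- 0
  ss <- seq(1.7, 2.3, by = 0.02) * lambda_z / ac$voxel[1]
  ss <- ss[ss <= ac$max_lag - 1]
  chi_hcp <- if (!length(ss)) NA_real_ else max(vapply(ss, function(s) {
    mean(interp3(ac_raw, rbind(ctr + s * n0, ctr - s * n0)))
  }, numeric(1)))
  list(zeta_24 = zeta_24, zeta_57 = zeta_57, chi_fcc = chi_fcc,
       chi_hcp = chi_hcp, lambda_z = lambda_z, best = best)
}

#' Full grid-score panel for one rate map
#'
#' @param map 3D rate map (attribute `voxel` respected).
#' @param max_lag autocorrelogram extent in voxels.
#' @return one-row data.frame: spacing, best-plane hexagonality score and
#'   normal, in-plane axis, `zeta_24`, `zeta_57`, `chi_fcc`, `chi_hcp`,
#'   `lambda_z`.
#' @export
grid_scores <- function(map, max_lag = NULL) {
  # extend beyond the half-grid default so the two-layer displacement probe
  # (chi_hcp at 2 * lambda_z) stays inside the correlation array
  max_lag <- max_lag %||% floor(0.8 * min(dim(map)))
  ac <- autocorr3d(map, max_lag)
  d <- suppressWarnings(grid_spacing(ac))
  if (is.na(d)) {
    return(data.frame(spacing = NA_real_, hex_score = 0,
                      nx = NA_real_, ny = NA_real_, nz = NA_real_,
                      ax = NA_real_, ay = NA_real_, az = NA_real_,
                      zeta_24 = NA_real_, zeta_57 = NA_real_,
                      chi_fcc = NA_real_, chi_hcp = NA_real_,
                      lambda_z = NA_real_))
  }
  bp <- best_plane(ac, d)
  fh <- fcc_hcp_scores(ac, d, bp)
  data.frame(spacing = d, hex_score = bp$score,
             nx = bp$normal[1], ny = bp$normal[2], nz = bp$normal[3],
             ax = bp$axis[1], ay = bp$axis[2], az = bp$axis[3],
             zeta_24 = fh$zeta_24, zeta_57 = fh$zeta_57,
             chi_fcc = fh$chi_fcc, chi_hcp = fh$chi_hcp,
             lambda_z = fh$lambda_z)
}

#' Grid scores for every unit of a run checkpoint
#'
#' @param run a `grid3d_run`.
#' @param checkpoint checkpoint index (default last).
#' @param units unit indices (default all).
#' @param max_lag autocorrelogram extent.
#' @return data.frame with one row per unit (see [grid_scores()]).
#' @export
analyze_run <- function(run, checkpoint = length(run$maps), units = NULL,
                        max_lag = NULL) {
  units <- units %||% seq_len(dim(run$maps[[checkpoint]])[4])
  out <- lapply(units, function(i)
    grid_scores(rate_map(run, i, checkpoint), max_lag))
  cbind(unit = units, do.call(rbind, out))
}

#' Pairwise alignment angles across a population
#'
#' `beta`: angles between the best-plane normals of all unit pairs, folded
#' to `[0, 90]` degrees. `omega`: for pairs with `beta < beta_max`, the
#' angle between their in-plane hexagon axes (one axis projected into the
#' other's plane), folded to `[0, 30]` by hexagonal symmetry.
#'
#' @param scores data.frame from [analyze_run()] (columns nx..nz, ax..az).
#' @param beta_max co-planarity threshold in degrees for `omega` pairs.
#' @return list with numeric vectors `beta` and `omega`.
#' @export
population_alignment <- function(scores, beta_max = 15) {
  ok <- stats::complete.cases(scores[, c("nx", "ny", "nz")])
  N <- scores[ok, c("nx", "ny", "nz"), drop = FALSE]
  A <- scores[ok, c("ax", "ay", "az"), drop = FALSE]
  m <- nrow(N)
  if (m < 2) return(list(beta = numeric(0), omega = numeric(0)))
  beta <- c(); omega <- c()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    b <- line_angle(as.numeric(N[i, ]), as.numeric(N[j, ]))
    beta <- c(beta, b)
    if (b < beta_max && all(is.finite(as.numeric(A[i, ]))) &&
        all(is.finite(as.numeric(A[j, ])))) {
      ni <- as.numeric(N[i, ])
      aj <- as.numeric(A[j, ])
      proj <- aj - sum(aj * ni) * ni
      pn <- sqrt(sum(proj^2))
      if (pn > 1e-9) {
        ang <- line_angle(as.numeric(A[i, ]), proj / pn)  # [0, 90]
        w <- ang %% 60
        omega <- c(omega, min(w, 60 - w))
      }
    }
  }
  list(beta = beta, omega = omega)
}

#' Poisson spike sample from a rate map
#'
#' Spike positions drawn with probability proportional to voxel rate,
#' uniformly jittered within the voxel.
#'
#' @param map nonnegative 3D rate map (`NA` treated as zero).
#' @param n_spikes number of spikes.
#' @return `n_spikes x 3` matrix of positions in L units.
#' @export
poisson_spikes <- function(map, n_spikes) {
  d <- dim(map)
  voxel <- attr(map, "voxel") %||% rep(1 / d[1], 3)
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  p <- as.vector(map)
  p[!is.finite(p) | p < 0] <- 0
  if (sum(p) <= 0) stop("all-zero rate map: cannot sample spikes")
  idx <- sample.int(length(p), n_spikes, replace = TRUE, prob = p)
  ar <- arrayInd(idx, d)
  jit <- matrix(stats::runif(3 * n_spikes), ncol = 3)
  sweep(ar - 1 + jit, 2, voxel, "*")
}

#' Local (triplet) gridness from spike positions
#'
#' The pairwise-distance histogram of the spikes is multi-peaked: the first
#' peak collects intra-field distances, the second distances between
#' neighboring fields, which defines the grid distance `d`. Spike pairs
#' within a window around `d` (the surrounding troughs when present,
#' otherwise `[0.5 d, 1.4 d]`) are declared neighbors; all spike triplets
#' that are mutual neighbors contribute their three internal angles to an
#' angular distribution, which is compared (as a ratio) with the same
#' distribution from control spikes lacking field structure. The
#' characteristic angle is the median of the data angles in the
#' above-chance region; the significance is the maximal ratio.
#'
#' @param spikes `m x 3` spike positions.
#' @param control control spike positions (default: uniform in the spikes'
#'   bounding box, same count).
#' @param nbins distance-histogram bins.
#' @param angle_bin angular bin width in degrees.
#' @param n_triplet_max spikes subsampled for triangle enumeration.
#' @return list: grid distance `d`, neighbor `window`, `char_angle`
#'   (degrees), `significance`, the angle `ratio` table and raw `angles`.
#' @export
local_gridness <- function(spikes, control = NULL, nbins = 150,
                           angle_bin = 5, n_triplet_max = 900) {
  stopifnot(nrow(spikes) >= 100)
  if (is.null(control)) {
    lo <- apply(spikes, 2, min); hi <- apply(spikes, 2, max)
    control <- sweep(sweep(matrix(stats::runif(length(spikes)),
                                  ncol = 3), 2, hi - lo, "*"), 2, lo, "+")
  }
  dd <- as.vector(stats::dist(spikes))
  h <- hist(dd, breaks = nbins, plot = FALSE)
  cnt <- as.vector(stats::filter(h$counts, rep(1, 5) / 5, sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  mid <- h$mids
  pk <- which(diff(sign(diff(cnt))) == -2) + 1
  if (length(pk) < 2) {
    warning("unimodal distance distribution: grid distance undefined")
    return(list(d = NA_real_, window = c(NA, NA), char_angle = NA_real_,
                significance = NA_real_, ratio = NULL, angles = numeric(0)))
  }
  d <- mid[pk[2]]
  tr <- which(diff(sign(diff(cnt))) == 2) + 1
  tr_lo <- tr[tr < pk[2] & tr > pk[1]]
  tr_hi <- tr[tr > pk[2]]
  lo_w <- if (length(tr_lo)) mid[max(tr_lo)] else 0.5 * d
  hi_w <- if (length(tr_hi)) mid[min(tr_hi)] else 1.4 * d
  # Internal angles of mutual-neighbor spike triplets. Dense patterns
  # produce combinatorially many triangles, so neighbor edges are capped and
  # each edge contributes at most a few completing vertices; this samples
  # the triangle population without biasing the angle distribution.
  angles_of <- function(pts, max_edges = 4000, max_k = 8) {
    if (nrow(pts) > n_triplet_max)
      pts <- pts[sample.int(nrow(pts), n_triplet_max), , drop = FALSE]
    D <- as.matrix(stats::dist(pts))
    adj <- D >= lo_w & D <= hi_w
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(edges) == 0) return(numeric(0))
    if (nrow(edges) > max_edges)
      edges <- edges[sample.int(nrow(edges), max_edges), , drop = FALSE]
    ang <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      ks <- which(adj[i, ] & adj[j, ])
      ks <- ks[ks > j]
      if (!length(ks)) next
      if (length(ks) > max_k) ks <- sample(ks, max_k)
      a <- D[j, ks]; b <- D[i, ks]; cc <- D[i, j]
      A1 <- acos(pmin(pmax((b^2 + cc^2 - a^2) / (2 * b * cc), -1), 1))
      A2 <- acos(pmin(pmax((a^2 + cc^2 - b^2) / (2 * a * cc), -1), 1))
      ang[[e]] <- c(A1, A2, pi - A1 - A2) * 180 / pi
    }
    out <- unlist(ang)
    if (is.null(out)) numeric(0) else out
  }
  ang_d <- angles_of(spikes)
  ang_c <- angles_of(control)
  brks <- seq(0, 180, by = angle_bin)
  hd <- hist(ang_d, breaks = brks, plot = FALSE)$counts
  hc <- hist(ang_c, breaks = brks, plot = FALSE)$counts
  dens_d <- hd / max(sum(hd), 1)
  dens_c <- hc / max(sum(hc), 1)
  valid <- hc >= 25
  ratio <- rep(NA_real_, length(hd))
  ratio[valid] <- dens_d[valid] / dens_c[valid]
  mids <- brks[-1] - angle_bin / 2
  above <- which(valid & ratio > 1)
  char_angle <- if (length(above) && length(ang_d)) {
    in_above <- ang_d[findInterval(ang_d, brks, rightmost.closed = TRUE) %in% above]
    stats::median(in_above)
  } else NA_real_
  significance <- if (any(valid)) max(ratio[valid]) else NA_real_
  list(d = d, window = c(lo_w, hi_w), char_angle = char_angle,
       significance = significance,
       ratio = data.frame(angle = mids, ratio = ratio),
       angles = ang_d)
}

#' Empirical cost terms of a rate map
#'
#' The kinetic term is the volume-averaged squared discrete gradient
#' (central differences, one-sided at the box faces). The adaptation term
#' is the volume-normalized double sum `<psi (K * psi)>` with the
#' difference-of-Gaussians kernel, evaluated by circular convolution with
#' the kernel periodized on the box (truncated after `trunc_sd` widths).
#' Unvisited voxels are imputed from their smoothed neighborhood first.
#' The adaptation term here keeps the constant (mean-rate) background, so a
#' constant map `c` yields `H_A = c^2 (1 - rho)`.
#'
#' @param map 3D rate map.
#' @param params a [kernel_params()] in L units (see
#'   [kernel_from_config()] for the network equivalent).
#' @param trunc_sd kernel truncation, in widths of the broad lobe.
#' @return list with `H_K` and `H_A` (no `gamma` weighting applied).
#' @export
empirical_cost <- function(map, params, trunc_sd = 4) {
  d <- dim(map)
  voxel <- attr(map, "voxel") %||% rep(1 / d[1], 3)
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  if (any(trunc_sd * params$v_tau_l > d * voxel))
    warning("kernel wider than the box; adaptation term is strongly periodized")
  psi <- impute_map(map)
  # squared gradient: 4th-order central differences in the interior,
  # 2nd-order (one-sided at the faces) within two voxels of the boundary
  grad2 <- 0
  for (ax in 1:3) {
    n <- d[ax]
    sh <- function(k) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      switch(ax, psi[idx, , , drop = FALSE], psi[, idx, , drop = FALSE],
             psi[, , idx, drop = FALSE])
    }
    h <- voxel[ax]
    d4 <- (8 * (sh(1) - sh(-1)) - (sh(2) - sh(-2))) / (12 * h)
    ip <- pmin(seq_len(n) + 1L, n); im <- pmax(seq_len(n) - 1L, 1L)
    hh <- (ip - im) * h
    d2 <- switch(ax, (psi[ip, , ] - psi[im, , ]) / hh,
                 (psi[, ip, ] - psi[, im, ]) / rep(hh, each = d[1]),
                 (psi[, , ip] - psi[, , im]) / rep(hh, each = d[1] * d[2]))
    border <- c(1L, 2L, n - 1L, n)
    switch(ax, d4[border, , ] <- d2[border, , ],
           d4[, border, ] <- d2[, border, ],
           d4[, , border] <- d2[, , border])
    grad2 <- grad2 + d4^2
  }
  H_K <- mean(grad2)
  ker <- periodized_kernel(d, voxel, params, trunc_sd)
  conv <- Re(fft(fft(psi) * fft(ker), inverse = TRUE)) / prod(d) * prod(voxel)
  H_A <- mean(psi * conv)
  list(H_K = H_K, H_A = H_A)
}

#' Adaptation-kernel parameters implied by a network configuration
#'
#' The kernel lengths are the distances covered at the simulated speed
#' during the slow and fast adaptation times: `v_tau_l = v_step / b2`,
#' `v_tau_s = v_step / b1` (so their ratio is `b2 / b1 = 1/3` with the
#' default rates), in units of L.
#'
#' @param cfg a [sim_config()].
#' @param rho narrow-lobe weight (default 0.03).
#' @return a [kernel_params()] object.
#' @export
kernel_from_config <- function(cfg, rho = 0.03) {
  kernel_params(v_tau_l = cfg$v_step / cfg$b2,
                v_tau_s = cfg$v_step / cfg$b1, rho = rho)
}
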