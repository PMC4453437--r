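test_that("autocorrelograms are normalized, symmetric and bounded", {
  ac <- fcc_ac()
  ctr <- ac$max_lag + 1
  expect_equal(ac$ac[ctr, ctr, ctr], 1)
  expect_true(all(abs(ac$ac) <= 1 + 1e-9, na.rm = TRUE))
  flipped <- ac$ac[rev(seq_len(dim(ac$ac)[1])), rev(seq_len(dim(ac$ac)[2])),
                   rev(seq_len(dim(ac$ac)[3]))]
  expect_equal(ac$ac, flipped, tolerance = 1e-9)
  expect_warning(autocorr3d(array(1, c(8, 8, 8))), "constant")
})

test_that("fixture spacing is recovered from the radial profile", {
  expect_equal(grid_spacing(fcc_ac()), 0.35, tolerance = 0.05)
  expect_equal(grid_spacing(hcp_ac()), 0.35, tolerance = 0.05)
})

test_that("first-shell peak structure separates FCC from HCP", {
  count_pairs <- function(ac) {
    d <- grid_spacing(ac)
    pk <- ac_peaks(ac)
    shell <- pk[pk$radius > 0.7 * d & pk$radius < 1.3 * d, ]
    matched <- vapply(seq_len(nrow(shell)), function(i) {
      dd <- sqrt((shell$dx + shell$dx[i])^2 + (shell$dy + shell$dy[i])^2 +
                   (shell$dz + shell$dz[i])^2)
      any(dd < 0.15 * d)
    }, logical(1))
    c(n = nrow(shell), pairs = sum(matched) / 2)
  }
  expect_equal(unname(count_pairs(fcc_ac())), c(12, 6))
  expect_equal(unname(count_pairs(hcp_ac())), c(18, 9))
})

test_that("best plane recovery on ideal and null maps", {
  # HCP stacking axis is z by construction
  bp <- hcp_scores()$bp
  expect_gt(bp$score, 0.9)
  expect_lt(acos(min(abs(bp$normal[3]), 1)) * 180 / pi, 5)
  # planar hexagonal pattern extended in z: near-perfect score, normal z
  ph <- make_fixture("planar_hex", a = 0.35, resolution = 48)
  bph <- best_plane(autocorr3d(ph, max_lag = 30))
  expect_gt(bph$score, 0.9)
  expect_lt(acos(min(abs(bph$normal[3]), 1)) * 180 / pi, 5)
  # shuffled map: no spacing, score collapses to 0
  set.seed(20)
  sh <- make_fixture("shuffled", a = 0.35, resolution = 48)
  bsh <- suppressWarnings(best_plane(autocorr3d(sh, max_lag = 30)))
  expect_lt(bsh$score, 0.2)
})

test_that("long-range order scores identify their own arrangement", {
  fs <- fcc_scores(); hs <- hcp_scores()
  expect_gt(fs$chi_fcc, 0.8)
  expect_lt(hs$chi_fcc, 0.3)
  expect_gt(hs$chi_hcp, 0.8)
  expect_lt(fs$chi_hcp, 0.3)
  # zeta scores live in [-3, 3]; FCC populates only the first triplet
  expect_gt(fs$zeta_24, 2.5)
  expect_lt(abs(fs$zeta_57), 1)
  expect_gt(hs$zeta_57, 1.5)
  expect_true(all(abs(c(fs$zeta_24, fs$zeta_57, hs$zeta_24, hs$zeta_57)) <= 3))
})

test_that("scores are invariant to 90-degree rotations and rescaling", {
  m <- hcp_fixture()
  sc0 <- grid_scores(m, max_lag = 30)
  rot <- aperm(m, c(2, 3, 1))            # rotate lattice axes
  attr(rot, "voxel") <- attr(m, "voxel")
  sc_rot <- grid_scores(rot, max_lag = 30)
  expect_equal(sc_rot$spacing, sc0$spacing, tolerance = 1e-3)
  expect_equal(sc_rot$hex_score, sc0$hex_score, tolerance = 0.05)
  expect_equal(sc_rot$chi_hcp, sc0$chi_hcp, tolerance = 0.1)
  scaled <- m * 7.3
  attr(scaled, "voxel") <- attr(m, "voxel")
  sc_s <- grid_scores(scaled, max_lag = 30)
  expect_equal(sc_s$spacing, sc0$spacing, tolerance = 1e-9)
  expect_equal(sc_s$hex_score, sc0$hex_score, tolerance = 1e-9)
  expect_equal(sc_s$chi_fcc, sc0$chi_fcc, tolerance = 1e-9)
})

test_that("Poisson spike sampling follows the rate map", {
  m <- array(0, c(6, 6, 6))
  m[3, 4, 2] <- 1
  set.seed(21)
  sp <- poisson_spikes(m, 50)
  expect_true(all(sp[, 1] >= 2 / 6 & sp[, 1] <= 3 / 6))
  expect_true(all(sp[, 2] >= 3 / 6 & sp[, 2] <= 4 / 6))
  expect_true(all(sp[, 3] >= 1 / 6 & sp[, 3] <= 2 / 6))
  # chi-square goodness of fit against the sampling law
  set.seed(22)
  m2 <- array(runif(27, 0.2, 1), c(3, 3, 3))
  sp2 <- poisson_spikes(m2, 1e5)
  vox <- pmin(floor(sweep(sp2, 2, rep(1 / 3, 3), "/")), 2)
  counts <- tabulate(vox[, 1] + 3 * vox[, 2] + 9 * vox[, 3] + 1, nbins = 27)
  expect_gt(stats::chisq.test(counts, p = as.vector(m2) / sum(m2))$p.value,
            0.01)
  set.seed(5); a <- poisson_spikes(m2, 100)
  set.seed(5); b <- poisson_spikes(m2, 100)
  expect_identical(a, b)
  expect_error(poisson_spikes(array(0, c(4, 4, 4)), 10), "all-zero")
})

test_that("triplet gridness recovers spacing and the 60-degree angle", {
  set.seed(23)
  sp <- poisson_spikes(fcc_fixture(), 2500)
  lg <- local_gridness(sp)
  expect_equal(lg$d, 0.35, tolerance = 0.05)
  expect_equal(lg$char_angle, 60, tolerance = 0.1)   # within 6 degrees
  expect_gt(lg$significance, 1.3)
})

test_that("uniform spikes carry no angular structure", {
  set.seed(24)
  u <- matrix(runif(6000), ncol = 3)
  lg <- suppressWarnings(local_gridness(u, n_triplet_max = 1500))
  if (!is.na(lg$significance)) {
    # bounds reflect finite triangle sampling around a flat ratio of 1
    expect_lt(lg$significance, 1.5)
    expect_lt(max(abs(lg$ratio$ratio - 1), na.rm = TRUE), 0.5)
  }
})

test_that("population alignment angles behave at the two extremes", {
  fs <- fcc_scores()
  row <- data.frame(nx = fs$bp$normal[1], ny = fs$bp$normal[2],
                    nz = fs$bp$normal[3], ax = fs$bp$axis[1],
                    ay = fs$bp$axis[2], az = fs$bp$axis[3])
  same <- rbind(row, row, row)
  pa <- population_alignment(same)
  expect_true(all(pa$beta < 1e-6))
  expect_true(all(pa$omega < 1e-4))
  # random planes: mean angle matches the Monte-Carlo mean between random
  # lines in 3D
  set.seed(25)
  nr <- matrix(rnorm(120), ncol = 3); nr <- nr / sqrt(rowSums(nr^2))
  ax <- matrix(rnorm(120), ncol = 3)
  ax <- ax - rowSums(ax * nr) * nr; ax <- ax / sqrt(rowSums(ax^2))
  rand <- data.frame(nx = nr[, 1], ny = nr[, 2], nz = nr[, 3],
                     ax = ax[, 1], ay = ax[, 2], az = ax[, 3])
  pa_r <- population_alignment(rand)
  u <- matrix(rnorm(3e5 * 3), ncol = 3); u <- u / sqrt(rowSums(u^2))
  v <- matrix(rnorm(3e5 * 3), ncol = 3); v <- v / sqrt(rowSums(v^2))
  mc_mean <- mean(acos(pmin(abs(rowSums(u * v)), 1)) * 180 / pi)
  expect_equal(mean(pa_r$beta), mc_mean, tolerance = 0.05)
})

test_that("empirical cost terms match their closed forms", {
  kp <- kernel_params(v_tau_l = 0.12, v_tau_s = 0.04, rho = 0.03)
  cm <- array(0.5, c(32, 32, 32)); attr(cm, "voxel") <- rep(1 / 32, 3)
  ec <- empirical_cost(cm, kp)
  expect_equal(ec$H_K, 0)
  expect_equal(ec$H_A, 0.25 * (1 - 0.03), tolerance = 1e-4)
  # kinetic term of the analytic FCC field at 64^3 resolution
  s1 <- lattice_spec("fcc", a = 0.35, n = 1)
  g <- (seq_len(64) - 0.5) / 64
  x <- as.matrix(expand.grid(g, g, g))
  mp <- array(psi_lattice(x, s1), c(64, 64, 64))
  attr(mp, "voxel") <- rep(1 / 64, 3)
  hk <- empirical_cost(mp, kp)$H_K
  expect_equal(hk, lattice_cost(s1, 0)$H_K, tolerance = 0.02)
})
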