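test_that("wave vectors have the prescribed magnitudes and geometry", {
  K <- gridcell3d:::fcc_wavevectors(1)
  expect_equal(rowSums(K^2), rep(1.5 * (2 * pi)^2, 4), tolerance = 1e-12)
  # tetrahedral: pairwise dot products -(1/2)(2 pi)^2 and zero sum
  dots <- K %*% t(K)
  expect_equal(dots[upper.tri(dots)], rep(-0.5 * (2 * pi)^2, 6),
               tolerance = 1e-9)
  expect_equal(colSums(K), rep(0, 3), tolerance = 1e-9)
  Kxy <- gridcell3d:::hcp_xy_wavevectors(1)
  expect_equal(rowSums(Kxy^2), rep(4 / 3 * (2 * pi)^2, 3), tolerance = 1e-12)
  expect_equal(gridcell3d:::hcp_kz_perfect(1)^2, 3 / 8 * (2 * pi)^2,
               tolerance = 1e-12)
  # perfect stacking ratio 3/sqrt(32)
  expect_equal(gridcell3d:::hcp_kz_perfect(1) / sqrt(4 / 3 * (2 * pi)^2),
               3 / sqrt(32), tolerance = 1e-12)
})

test_that("lattice fields are non-negative with unit cell average", {
  expect_equal(unname(gridcell3d:::lattice_base(c(0, 0, 0), "fcc")), 2)
  set.seed(16)
  x <- matrix(runif(1500, -2, 2), ncol = 3)
  for (kind in c("fcc", "hcp")) for (n in 1:3) {
    sp <- lattice_spec(kind, a = 1, n = n)
    v <- psi_lattice(x, sp)
    expect_true(all(v >= 0))
    # cell average via the commensurate grid equals 1
    cell <- if (kind == "fcc") c(sqrt(3), 1, sqrt(6))
            else c(sqrt(3), 1, 2 * pi / gridcell3d:::hcp_kz_perfect(1))
    g <- lapply(cell, function(cl) (0:23) / 24 * cl)
    xx <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
    expect_equal(mean(psi_lattice(xx, sp)), 1, tolerance = 1e-6)
  }
  expect_error(lattice_spec("fcc", n = 0.5), "n must be")
  expect_error(lattice_spec("fcc", kz_ratio = 0.5), "only applies")
})

test_that("close-packed point sets have 12 equidistant first neighbors", {
  for (kind in c("fcc", "hcp")) {
    p <- lattice_points(kind, a = 1, extent = 6)
    interior <- p[apply(abs(p) <= 1.5, 1, all), , drop = FALSE]
    expect_gt(nrow(interior), 10)
    for (i in seq_len(min(nrow(interior), 8))) {
      dd <- sqrt(colSums((t(p) - interior[i, ])^2))
      nn <- sort(dd)[2:14]
      expect_equal(nn[1:12], rep(1, 12), tolerance = 1e-9)
      expect_gt(nn[13], 1.3)
    }
  }
  # layer separation sqrt(2/3) a
  p <- lattice_points("hcp", a = 1, extent = 4)
  zs <- sort(unique(round(p[, 3], 9)))
  expect_equal(unique(round(diff(zs), 9)), round(sqrt(2 / 3), 9))
})

test_that("FCC is centrally symmetric about a site, HCP is not", {
  for (kind in c("fcc", "hcp")) {
    p <- lattice_points(kind, a = 1, extent = 6)
    ctr <- p[which.min(rowSums(p^2)), ]
    near <- p[sqrt(colSums((t(p) - ctr)^2)) < 1.1, , drop = FALSE]
    refl <- sweep(-sweep(near, 2, ctr), 2, -ctr)   # reflect about ctr
    matched <- vapply(seq_len(nrow(refl)), function(i)
      min(sqrt(colSums((t(near) - refl[i, ])^2))) < 1e-6, logical(1))
    if (kind == "fcc") expect_true(all(matched))
    else expect_false(all(matched))
  }
})

test_that("kernel transform matches its quadrature and limits", {
  kp <- kernel_params()
  expect_equal(kernel_ft(0, kp), 1 - kp$rho)
  kp0 <- kernel_params(rho = 0)
  ks <- c(0.5, 2, 2 * pi)
  expect_equal(kernel_ft(ks, kp0), exp(-0.5 * ks^2), tolerance = 1e-12)
  # radial quadrature of the 3D transform at k = 2 pi
  k <- 2 * pi
  num <- stats::integrate(function(q)
    4 * pi * q * sin(k * q) / k * adaptation_kernel(q, kp),
    0, 8, rel.tol = 1e-10)$value
  expect_equal(num, kernel_ft(k, kp), tolerance = 1e-6)
})

test_that("mode-expansion cost agrees with real-space quadrature", {
  for (kind in c("fcc", "hcp")) for (n in 1:2) {
    sp <- lattice_spec(kind, a = 1, n = n)
    co <- lattice_cost(sp, gamma = 1)
    oq <- lattice_cost_quadrature(sp, gamma = 1, nbase = 64)
    expect_equal(co$H_K, oq$H_K, tolerance = 1e-3)
    expect_equal(co$H_A, oq$H_A, tolerance = 1e-3)
    expect_equal(co$H, oq$H, tolerance = 1e-3)
  }
  sp <- lattice_spec("fcc", a = 1, n = 1)
  expect_equal(lattice_cost(sp, gamma = 0)$H, lattice_cost(sp, 0)$H_K)
})

test_that("the n = 2 FCC kinetic coefficient is an exact rational", {
  # the four tetrahedral wave vectors sum to zero, so the six pairwise-sum
  # cosines merge coherently into three double-amplitude modes; the exact
  # coefficient of k^2 is 73/162 (not 71/162: see the methods vignette)
  sp <- lattice_spec("fcc", a = 1, n = 2)
  k2 <- 1.5 * (2 * pi)^2
  num <- lattice_cost(sp, 0)$H_K / k2 * 162
  expect_equal(num, 73, tolerance = 1e-9)
  # adaptation part: corrected coefficient pattern (256, 1, 6, 12)/648
  kp <- kernel_params()
  k <- sqrt(k2)
  ha <- (256 * kernel_ft(k, kp) + kernel_ft(2 * k, kp) +
         6 * kernel_ft(2 * sqrt(2) / sqrt(3) * k, kp) +
         12 * kernel_ft(2 / sqrt(3) * k, kp)) / 648
  expect_equal(lattice_cost(sp, 1)$H_A, ha, tolerance = 1e-9)
})

test_that("cost is invariant under translations of the field", {
  set.seed(17)
  for (kind in c("fcc", "hcp")) {
    sp <- lattice_spec(kind, a = 1, n = 2)
    base <- lattice_cost_quadrature(sp, 1, nbase = 48)
    sh <- lattice_cost_quadrature(sp, 1, nbase = 48, origin = runif(3, -1, 1))
    expect_equal(base$H, sh$H, tolerance = 1e-8)
  }
})

test_that("spacing optimization reproduces the stacking-ratio asymptotics", {
  # n = 1: columnar solution, optimal stacking ratio 0 for any gamma
  for (g in c(1e3, 1e4, 1e5)) {
    o <- optimize_lattice("hcp", n = 1, gamma = g)
    expect_lt(o$kz_ratio_opt, 0.02)
  }
  # high power: ratio approaches the perfect close-packing value 3/sqrt(32)
  o6 <- optimize_lattice("hcp", n = 6, gamma = 1e5)
  expect_equal(o6$kz_ratio_opt, 3 / sqrt(32), tolerance = 0.05)
  # small gamma: smoothness dominates and the uniform state wins
  expect_true(optimize_lattice("fcc", 2, gamma = 100)$trivial_favored)
  expect_false(optimize_lattice("fcc", 2, gamma = 1e4)$trivial_favored)
})

test_that("multi-start refinement lands on the same spacing", {
  g <- 1e4
  ref <- optimize_lattice("fcc", 2, gamma = g)
  set.seed(18)
  kp <- kernel_params()
  obj <- function(la) lattice_cost(lattice_spec("fcc", exp(la), 2), g, kp)$H
  starts <- runif(10, log(0.5), log(15))
  mins <- vapply(starts, function(s)
    exp(optim(s, obj, method = "L-BFGS-B", lower = log(0.3),
              upper = log(40))$par), numeric(1))
  # every start that escapes its local basin agrees with the grid search
  expect_lt(min(abs(mins - ref$a_opt)), 1e-3)
  expect_gt(mean(abs(mins - ref$a_opt) < 1e-3), 0.3)
})

test_that("optimal spacing shifts monotonically with gamma and power", {
  gs <- c(3e3, 1e4, 3e4, 1e5)
  a_g <- vapply(gs, function(g) optimize_lattice("fcc", 2, gamma = g)$a_opt,
                numeric(1))
  expect_true(all(diff(a_g) < 0))
  a_n <- vapply(1:4, function(n) optimize_lattice("hcp", n, gamma = 1e4)$a_opt,
                numeric(1))
  expect_true(all(diff(a_n) > -1e-6))
})

test_that("FCC and HCP cost envelopes are nearly equivalent", {
  # compared where the optimal power is interior to the modeled set
  for (g in c(3162, 6813)) {
    hf <- min(vapply(1:8, function(n)
      optimize_lattice("fcc", n, gamma = g)$H_opt, numeric(1)))
    hh <- min(vapply(1:8, function(n)
      optimize_lattice("hcp", n, gamma = g)$H_opt, numeric(1)))
    expect_lt(abs(hf - hh) / abs(hf), 0.05)
  }
})

test_that("relaxation-curve fitting recovers generating parameters", {
  tt <- seq(0, 2e7, length.out = 80)
  p0 <- c(A = 2, B = 1, K = 0.5, C = 1.5, D = 0.8, E = 1.2,
          tau_s = 8e5, tau_m = 3e6, tau_l = 8e6)
  hk <- p0["A"] * exp(-tt / p0["tau_s"]) + p0["B"] * exp(-tt / p0["tau_l"]) + p0["K"]
  ha <- p0["C"] * exp(-tt / p0["tau_s"]) - p0["D"] * exp(-tt / p0["tau_m"]) + p0["E"]
  set.seed(19)
  fit <- fit_cost_timecourse(tt, hk * (1 + rnorm(80, 0, 0.01)),
                             ha * (1 + rnorm(80, 0, 0.01)))
  expect_true(fit$converged)
  rel <- abs(fit$coefficients[names(p0)] - p0) / p0
  expect_true(all(rel < 0.1))
  # the sum H_K + gamma* H_A is non-increasing on the fitted curves
  p <- fit$coefficients
  tg <- seq(0, 2e7, length.out = 500)
  tot <- p["A"] * exp(-tg / p["tau_s"]) + p["B"] * exp(-tg / p["tau_l"]) + p["K"] +
    fit$gamma_star * (p["C"] * exp(-tg / p["tau_s"]) -
                      p["D"] * exp(-tg / p["tau_m"]) + p["E"])
  expect_true(all(diff(tot) <= 1e-8 * max(abs(tot))))
})

test_that("constant cost series yield null amplitudes and unbounded gamma", {
  tt <- seq(0, 100, length.out = 25)
  fit <- fit_cost_timecourse(tt, rep(2, 25), rep(0.5, 25))
  expect_equal(unname(fit$coefficients[c("A", "B", "C", "D")]), rep(0, 4))
  expect_identical(fit$gamma_star, Inf)
})
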