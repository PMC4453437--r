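test_that("collateral weights match the construction on a hand-built case", {
  cfg <- sim_config(n_mec = 3, per_axis_inp = 2)
  l <- cfg$v_step * cfg$tau_delay            # 0.1 L offset
  dir <- c(1, 0, 0)
  theta <- rbind(dir, dir, dir)
  # unit 2's field sits exactly l behind unit 1 along the shared preferred
  # direction: the 1 <- 2 weight attains the pre-threshold maximum 1 - kappa
  aux <- rbind(c(0.5, 0.5, 0.5),
               c(0.5 - l, 0.5, 0.5),
               c(0.5, 0.5 - 0.3, 0.5))
  W <- build_collateral(aux, theta, cfg)
  expect_equal(diag(W), rep(0, 3))
  # hand-computed unnormalized row 1
  w12 <- 1 - cfg$kappa
  f_y <- cfg$hd_c + (1 - cfg$hd_c) * exp(cfg$hd_nu * (0 - 1))  # omega _|_ theta
  w13 <- max(f_y^2 * exp(-(0.3 - l)^2 / (2 * cfg$sigma_f^2)) - cfg$kappa, 0)
  expected <- c(0, w12, w13) / sqrt(w12^2 + w13^2)
  expect_equal(W[1, ], expected, tolerance = 1e-12)
  # rows with any positive entry are unit norm
  nrm <- sqrt(rowSums(W^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-9))
})

test_that("kappa >= 1 rectifies everything away and is flagged", {
  cfg <- sim_config(n_mec = 4, per_axis_inp = 2, kappa = 1)
  set.seed(13)
  aux <- matrix(runif(12), 4)
  theta <- matrix(rnorm(12), 4); theta <- theta / sqrt(rowSums(theta^2))
  expect_warning(W <- build_collateral(aux, theta, cfg), "zero")
  expect_true(all(W == 0))
  expect_equal(attr(W, "degenerate_rows"), 4)
})

test_that("sparsity grows monotonically with kappa", {
  set.seed(14)
  n <- 30
  aux <- matrix(runif(3 * n), n)
  theta <- matrix(rnorm(3 * n), n); theta <- theta / sqrt(rowSums(theta^2))
  zero_frac <- vapply(c(0, 0.05, 0.15, 0.3), function(k) {
    cfg <- sim_config(n_mec = n, per_axis_inp = 2, kappa = k)
    mean(build_collateral(aux, theta, cfg) == 0)
  }, numeric(1))
  expect_true(all(diff(zero_frac) >= 0))
})

test_that("weights encode offset alignment with the preferred directions", {
  set.seed(15)
  n <- 25
  cfg <- sim_config(n_mec = n, per_axis_inp = 2)
  aux <- matrix(runif(3 * n, 0.2, 0.8), n)
  theta <- matrix(rnorm(3 * n), n); theta <- theta / sqrt(rowSums(theta^2))
  W <- build_collateral(aux, theta, cfg)
  Wperm <- build_collateral(aux, theta[sample(n), ], cfg)
  # predictor built from the true tuning: tuning-weighted offset Gaussian
  l <- cfg$v_step * cfg$tau_delay
  pred <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    if (i == k) next
    om <- aux[i, ] - aux[k, ]; om <- om / sqrt(sum(om^2))
    d2 <- sum((aux[i, ] - aux[k, ] - l * om)^2)
    pred[i, k] <- hd_tuning(theta[i, ], om, cfg$hd_c, cfg$hd_nu) *
      hd_tuning(theta[k, ], om, cfg$hd_c, cfg$hd_nu) *
      exp(-d2 / (2 * cfg$sigma_f^2))
  }
  off <- row(W) != col(W)
  expect_gt(cor(W[off], pred[off]), cor(Wperm[off], pred[off]) + 0.1)
})
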