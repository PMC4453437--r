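#' Run the full self-organization experiment
#'
#' Orchestrates one learning run: flight trajectory, place-cell inputs,
#' adaptation dynamics with activity/sparsity control, head-direction
#' gating, delayed collateral drive and Hebbian learning on the feed-forward
#' weights, with occupancy-normalized rate maps accumulated in the windows
#' between checkpoints. Deterministic given the seed in the run
#' configuration.
#'
#' @param rc a [run_config()].
#' @return an object of class `grid3d_run`: checkpoint rate maps (lists of
#'   4D arrays, voxels x units, `NA` in unvisited voxels), occupancy counts,
#'   per-window activity/sparsity statistics, final weights and state, plus
#'   the full configuration echo.
#' @export
run_simulation <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- rc$cfg
  set.seed(rc$seed)
  box <- cfg$box_scale
  centers <- place_centers(cfg$per_axis_inp, box)
  n_inp <- nrow(centers)
  W0 <- init_weights(cfg$n_mec, n_inp)
  theta <- random_unit_vectors(cfg$n_mec)
  aux_idx <- sample.int(n_inp, cfg$n_mec, replace = cfg$n_mec > n_inp)
  aux <- centers[aux_idx, , drop = FALSE]
  rho <- if (rc$no_collaterals) 0 else cfg$rho_coll
  Wcoll <- if (rho > 0) build_collateral(aux, theta, cfg)
           else matrix(0, cfg$n_mec, cfg$n_mec)
  b1 <- if (rc$heterogeneous_b1)
    stats::runif(cfg$n_mec, 0.85, 1.2) * cfg$b1 else rep(cfg$b1, cfg$n_mec)
  b2 <- b1 / 3
  head0 <- as.vector(random_unit_vectors(1))

  res <- cpp_run_simulation(
    centers = centers, Wt0 = t(W0), Wcoll = Wcoll, theta = theta,
    b1 = b1, b2 = b2, eps = cfg$eps, eta = cfg$eta,
    a0 = cfg$a0, s0 = cfg$s0, b3 = cfg$b3, b4 = cfg$b4,
    band_tol = cfg$band_tol, max_iter = as.integer(cfg$max_iter),
    hd_c = cfg$hd_c, hd_nu = cfg$hd_nu, rho_coll = rho,
    tau_delay = as.integer(cfg$tau_delay), sigma_p = cfg$sigma_p,
    v_step = cfg$v_step, sigma_h = cfg$sigma_h,
    n_steps = rc$n_steps, checkpoints = rc$checkpoints,
    map_res = rc$map_res, box = box, g0 = cfg$g0, mu0 = cfg$mu0,
    pos0 = box / 2, head0 = head0, learn = cfg$eps > 0)

  nck <- length(rc$checkpoints)
  resn <- rc$map_res
  occ <- array(res$occupancy, dim = c(resn, resn, resn, nck))
  maps <- vector("list", nck)
  for (k in seq_len(nck)) {
    m <- array(res$maps[[k]], dim = c(resn, resn, resn, cfg$n_mec))
    ok <- occ[, , , k] > 0
    for (i in seq_len(cfg$n_mec)) {
      mi <- m[, , , i]
      mi[ok] <- mi[ok] / occ[, , , k][ok]
      mi[!ok] <- NA_real_
      m[, , , i] <- mi
    }
    maps[[k]] <- m
  }
  stats <- data.frame(checkpoint = rc$checkpoints,
                      a = as.vector(res$a_mean), s = as.vector(res$s_mean),
                      g = as.vector(res$g_trace), mu = as.vector(res$mu_trace),
                      nonconverged = as.vector(res$nonconverged))
  structure(list(config = rc, maps = maps, occupancy = occ, stats = stats,
                 W = res$W, alpha = as.vector(res$alpha),
                 beta = as.vector(res$beta), theta = theta,
                 centers = centers, aux = aux, W_coll = Wcoll, b1 = b1,
                 g = res$g, mu = res$mu,
                 voxel = box / resn),
            class = "grid3d_run")
}

#' @export
print.grid3d_run <- function(x, ...) {
  rc <- x$config
  cat(sprintf("<grid3d_run> %d units, %d inputs, %s steps (seed %d)\n",
              rc$cfg$n_mec, nrow(x$centers),
              format(rc$n_steps, big.mark = ","), rc$seed))
  cat(sprintf("  checkpoints: %s\n", paste(rc$checkpoints, collapse = ", ")))
  cat("  window stats (a, s should sit near a0 = 0.1, s0 = 0.3):\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Extract one unit's finalized rate map
#'
#' @param run a `grid3d_run`.
#' @param unit unit index.
#' @param checkpoint checkpoint index (default: last).
#' @return 3D array with attribute `voxel` (voxel edge lengths in L units).
#' @export
rate_map <- function(run, unit, checkpoint = length(run$maps)) {
  m <- run$maps[[checkpoint]][, , , unit]
  attr(m, "voxel") <- run$voxel
  m
}
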