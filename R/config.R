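`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model parameters
#'
#' Collects every scalar parameter of the self-organizing network model.
#' Lengths are expressed in units of the box side `L`; one time step moves
#' the simulated animal by `v * dt / L` box units (0.004 with the defaults,
#' i.e. a 1 m/s flight sampled at 10 ms in a 2.5 m cube).
#'
#' @param n_mec number of output (would-be grid) units.
#' @param per_axis_inp place-cell centers per axis; the input layer has
#'   `per_axis_inp^3` units on a cubic lattice.
#' @param sigma_p place-field width (units of L).
#' @param b1,b2 fast and slow adaptation rates per time step (`b2 = b1/3`).
#' @param b3,b4 threshold and gain iteration rates.
#' @param a0,s0 target mean activity and sparsity.
#' @param band_tol relative error band for the activity/sparsity control.
#' @param max_iter cap on gain/threshold iterations within one time step.
#' @param eps Hebbian learning rate.
#' @param eta running-mean update factor.
#' @param hd_c,hd_nu baseline and concentration of the head-direction tuning.
#' @param rho_coll relative strength of the collateral input.
#' @param tau_delay collateral transmission delay, in time steps.
#' @param kappa collateral inhibition factor.
#' @param sigma_f collateral connectivity spread (units of L).
#' @param sigma_h per-step heading change standard deviation (radians).
#' @param v,dt,L physical speed (m/s), time step (s) and box side (m); only
#'   their combination `v*dt/L` enters the dynamics.
#' @param box_scale per-axis box stretch factors (>= 1) for non-cubic volumes;
#'   the place-center lattice is scaled to keep center density fixed.
#' @param g0,mu0 initial gain and threshold.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_mec = 125, per_axis_inp = 12, sigma_p = 0.05,
                       b1 = 0.1, b2 = b1 / 3, b3 = 0.01, b4 = 0.1,
                       a0 = 0.1, s0 = 0.3, band_tol = 0.1, max_iter = 100,
                       eps = 0.002, eta = 0.05,
                       hd_c = 0.2, hd_nu = 0.8, rho_coll = 0.1,
                       tau_delay = 25, kappa = 0.05, sigma_f = 0.2,
                       sigma_h = 0.15, v = 1, dt = 0.01, L = 2.5,
                       box_scale = c(1, 1, 1), g0 = 1, mu0 = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_mec >= 1, cfg$per_axis_inp >= 2, cfg$sigma_p > 0,
            cfg$b1 >= 0, cfg$b2 >= 0, cfg$a0 > 0, cfg$a0 < 1,
            cfg$s0 > 0, cfg$s0 < 1, cfg$eps >= 0, cfg$eta > 0, cfg$eta <= 1,
            cfg$rho_coll >= 0, cfg$tau_delay >= 0,
            cfg$sigma_h >= 0, cfg$v > 0, cfg$dt > 0, cfg$L > 0,
            length(cfg$box_scale) == 3, all(cfg$box_scale >= 1))
  cfg$v_step <- cfg$v * cfg$dt / cfg$L
  if (cfg$v_step >= min(cfg$box_scale))
    stop("step length v*dt/L must be smaller than the box")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  units: %d mEC, %d^3 place inputs (sigma_p = %g L)\n",
              x$n_mec, x$per_axis_inp, x$sigma_p))
  cat(sprintf("  adaptation b1 = %g, b2 = %g; targets a0 = %g, s0 = %g\n",
              x$b1, x$b2, x$a0, x$s0))
  cat(sprintf("  learning eps = %g, eta = %g; collaterals rho = %g, tau = %d\n",
              x$eps, x$eta, x$rho_coll, x$tau_delay))
  cat(sprintf("  step = %g L (v = %g m/s, dt = %g s, L = %g m), sigma_h = %g rad\n",
              x$v_step, x$v, x$dt, x$L, x$sigma_h))
  if (any(x$box_scale != 1))
    cat(sprintf("  box scale: %s\n", paste(x$box_scale, collapse = " x ")))
  invisible(x)
}

#' Full run description
#'
#' Binds a [sim_config()] to a run length, a checkpoint schedule and the
#' experiment variants: removing collateral connections, or drawing each
#' unit's fast adaptation rate from a uniform range around `b1` (0.85-1.2
#' times the common value).
#'
#' The default checkpoint schedule places checkpoints at 10%, 25%, 50% and
#' 100% of the run, the proportional equivalent of snapshots at 2, 5, 10 and
#' 20 million steps in a 20-million-step run.
#'
#' @param cfg a [sim_config()].
#' @param n_steps total number of time steps.
#' @param checkpoints strictly increasing step counts at which windowed rate
#'   maps and statistics are emitted; the last checkpoint is forced to
#'   `n_steps`.
#' @param map_res rate-map voxels per axis (per unit box side).
#' @param no_collaterals if `TRUE`, run with `rho_coll = 0`.
#' @param heterogeneous_b1 if `TRUE`, per-unit `b1 ~ U(0.85, 1.2) * b1`.
#' @param seed RNG seed for the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cfg = sim_config(), n_steps,
                       checkpoints = NULL, map_res = 25,
                       no_collaterals = FALSE, heterogeneous_b1 = FALSE,
                       seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_steps >= 1, map_res >= 4)
  if (is.null(checkpoints))
    checkpoints <- unique(pmax(1, round(n_steps * c(0.1, 0.25, 0.5, 1))))
  checkpoints <- sort(unique(c(checkpoints, n_steps)))
  if (any(diff(checkpoints) <= 0) || any(checkpoints < 1) ||
      max(checkpoints) != n_steps)
    stop("checkpoint schedule must be strictly increasing and end at n_steps")
  structure(list(cfg = cfg, n_steps = as.integer(n_steps),
                 checkpoints = as.integer(checkpoints),
                 map_res = as.integer(map_res),
                 no_collaterals = no_collaterals,
                 heterogeneous_b1 = heterogeneous_b1,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Convert between simulation steps and physical units
#'
#' Presentation helper using the physical parameter choices stored in a
#' configuration (`dt`, `v`, `L`): steps to hours of flight, and box-unit
#' lengths to meters.
#'
#' @param cfg a [sim_config()].
#' @param steps number of time steps (optional).
#' @param length_L lengths in units of the box side (optional).
#' @return a list with `hours` and/or `meters`.
#' @export
physical_units <- function(cfg, steps = NULL, length_L = NULL) {
  out <- list()
  if (!is.null(steps)) out$hours <- steps * cfg$dt / 3600
  if (!is.null(length_L)) out$meters <- length_L * cfg$L
  out
}
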