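# Reference implementations of the single-time-step unit dynamics. The full
# simulation loop runs compiled code (src/simulator.cpp); these functions
# define the semantics and are what the tests exercise.

#' Head-direction tuning factor
#'
#' `f = c + (1 - c) exp(nu (cos(gamma) - 1))` where `gamma` is the 3D angle
#' between the unit's preferred direction and the movement direction
#' (`cos(gamma)` is their dot product). Maximal (1) along the preferred
#' direction; never below `c + (1 - c) exp(-2 nu)`.
#'
#' @param theta_pref preferred direction, unit 3-vector.
#' @param omega movement direction, unit 3-vector.
#' @param c baseline (default 0.2).
#' @param nu tuning concentration (default 0.8).
#' @return scalar tuning factor in `(0, 1]`.
#' @export
hd_tuning <- function(theta_pref, omega, c = 0.2, nu = 0.8) {
  if (abs(sum(theta_pref^2) - 1) > 1e-6 || abs(sum(omega^2) - 1) > 1e-6)
    stop("theta_pref and omega must be unit vectors")
  c + (1 - c) * exp(nu * (sum(theta_pref * omega) - 1))
}

#' Total input to the output units
#'
#' `h_i = f_i (sum_j W_ij r_j + rho sum_k Wcoll_ik Psi_k(t - tau))`:
#' feed-forward drive from the place layer plus delayed collateral drive,
#' multiplicatively gated by the head-direction factor. With `rho_coll = 0`
#' this reduces to the pure feed-forward summation.
#'
#' @param W_ff feed-forward weights (`n_mec x n_inp`).
#' @param r input rates (length `n_inp`).
#' @param f head-direction factors (scalar or length `n_mec`).
#' @param W_coll collateral weights (`n_mec x n_mec`), or `NULL`.
#' @param psi_delayed population rates `tau` steps ago, or `NULL` (zeros).
#' @param rho_coll collateral strength (`>= 0`).
#' @return input vector `h` (length `n_mec`).
#' @export
total_input <- function(W_ff, r, f = 1, W_coll = NULL, psi_delayed = NULL,
                        rho_coll = 0) {
  if (rho_coll < 0) stop("rho_coll must be >= 0")
  h <- as.vector(W_ff %*% r)
  if (rho_coll > 0 && !is.null(W_coll) && !is.null(psi_delayed))
    h <- h + rho_coll * as.vector(W_coll %*% psi_delayed)
  f * h
}

#' One adaptation update
#'
#' Two coupled leaky variables driven by the previous input:
#' `alpha' = alpha + b1 (h - beta - alpha)`, `beta' = beta + b2 (h - beta)`.
#' `alpha` is the adaptation-mediated input entering the transfer function;
#' `beta` is its slower companion (`b2 = b1/3` by default), so that under
#' sustained drive `beta` absorbs `h` and `alpha` decays back to zero
#' (fatigue).
#'
#' @param alpha,beta current adaptation variables (vectors).
#' @param h previous-step input (vector).
#' @param b1 fast rate; `b2` slow rate (default `b1/3`).
#' @param b2 slow rate.
#' @return list with updated `alpha`, `beta`.
#' @export
update_adaptation <- function(alpha, beta, h, b1 = 0.1, b2 = b1 / 3) {
  list(alpha = alpha + b1 * (h - beta - alpha),
       beta = beta + b2 * (h - beta))
}

#' Threshold-nonlinear transfer function
#'
#' `Psi = (2/pi) arctan(g (alpha - mu))` for `alpha > mu`, else 0; rates are
#' normalized to a maximum of 1.
#'
#' @param alpha adaptation-mediated input (vector).
#' @param mu threshold.
#' @param g gain (`> 0`).
#' @return rate vector in `[0, 1)`.
#' @export
transfer_rate <- function(alpha, mu, g) {
  if (g <= 0) stop("gain must be positive")
  ifelse(alpha > mu, (2 / pi) * atan(g * (alpha - mu)), 0)
}

#' Population sparsity
#'
#' `s = (sum Psi)^2 / (N sum Psi^2)`, in `(0, 1]`; equals 1 iff all active
#' units fire equally.
#'
#' @param psi rate vector.
#' @return scalar sparsity (0 for an all-zero vector).
#' @export
sparsity <- function(psi) {
  s2 <- sum(psi^2)
  if (s2 == 0) return(0)
  sum(psi)^2 / (length(psi) * s2)
}

#' Iterative gain/threshold control
#'
#' Adjusts the threshold toward the target mean activity and the gain toward
#' the target sparsity, `mu' = mu + b3 (a - a0)`, `g' = g + b4 g (s - s0)`,
#' until both are within a relative band `tol` of `(a0, s0)` or `max_iter`
#' is reached. On non-convergence the iterate with the smallest maximal
#' relative violation is kept and flagged.
#'
#' @param alpha adaptation-mediated input (vector).
#' @param g,mu starting gain and threshold.
#' @param a0,s0 activity and sparsity targets.
#' @param b3,b4 iteration rates.
#' @param tol relative band (default 0.1).
#' @param max_iter iteration cap.
#' @return list with `g`, `mu`, `psi`, `a`, `s`, `converged`, `iterations`.
#' @export
adjust_gain_threshold <- function(alpha, g = 1, mu = 0, a0 = 0.1, s0 = 0.3,
                                  b3 = 0.01, b4 = 0.1, tol = 0.1,
                                  max_iter = 100) {
  stopifnot(a0 > 0, a0 < 1, s0 > 0, s0 < 1, g > 0)
  best <- list(viol = Inf)
  for (k in seq_len(max_iter)) {
    psi <- transfer_rate(alpha, mu, g)
    a <- mean(psi); s <- sparsity(psi)
    viol <- max(abs(a - a0) / a0, abs(s - s0) / s0)
    if (viol < best$viol)
      best <- list(g = g, mu = mu, psi = psi, a = a, s = s, viol = viol,
                   iterations = k)
    if (viol <= tol)
      return(list(g = g, mu = mu, psi = psi, a = a, s = s, converged = TRUE,
                  iterations = k))
    mu <- mu + b3 * (a - a0)
    g <- max(g + b4 * g * (s - s0), 1e-12)
  }
  c(best[c("g", "mu", "psi", "a", "s")],
    list(converged = FALSE, iterations = max_iter))
}
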