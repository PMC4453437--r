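#' Construct fixed collateral weights
#'
#' Each output unit is temporarily assigned an auxiliary field position
#' (chosen among the place-field centers). The collateral weight from unit
#' `k` to unit `i` is
#' `W_ik = [ f_i(omega_ik) f_k(omega_ik) exp(-d_ki^2 / (2 sigma_f^2)) - kappa ]_+`,
#' where `omega_ik` is the unit vector from field `k` to field `i`, `d_ki`
#' the distance between field `i` and field `k` displaced by `l = v_step *
#' tau_delay` along `omega_ik`, and `f` the head-direction tuning of each
#' unit evaluated at `omega_ik`. `[x]_+ = max(x, 0)` keeps the weights
#' nonnegative and, with the inhibition factor `kappa`, sparse. The diagonal
#' is forced to zero and rows are L2-normalized (rows whose entries are all
#' zero are left zero and counted as degenerate).
#'
#' The construction favors strong weights between co-tuned units whose
#' fields are shifted along the shared preferred direction, seeding a common
#' grid alignment; these weights are built once and not learned.
#'
#' @param aux auxiliary field positions (`n_mec x 3`).
#' @param theta preferred directions (`n_mec x 3`, unit rows).
#' @param cfg a [sim_config()] supplying `kappa`, `sigma_f`, `hd_c`,
#'   `hd_nu`, `v_step`, `tau_delay`.
#' @return `n_mec x n_mec` weight matrix with attributes `degenerate_rows`
#'   (count of all-zero rows) and `coincident_pairs` (aux-field pairs at
#'   identical positions, whose direction was drawn at random).
#' @export
build_collateral <- function(aux, theta, cfg = sim_config()) {
  n <- nrow(aux)
  stopifnot(nrow(theta) == n)
  l <- cfg$v_step * cfg$tau_delay
  W <- matrix(0, n, n)
  coincident <- 0L
  f_at <- function(th, om) cfg$hd_c + (1 - cfg$hd_c) * exp(cfg$hd_nu * (sum(th * om) - 1))
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      dvec <- aux[i, ] - aux[k, ]
      dn <- sqrt(sum(dvec^2))
      if (dn < 1e-12) {
        om <- as.vector(random_unit_vectors(1))
        coincident <- coincident + 1L
      } else om <- dvec / dn
      dki <- aux[i, ] - (aux[k, ] + l * om)
      d2 <- sum(dki^2)
      w <- f_at(theta[i, ], om) * f_at(theta[k, ], om) *
        exp(-d2 / (2 * cfg$sigma_f^2)) - cfg$kappa
      W[i, k] <- max(w, 0)
    }
  }
  nrm <- sqrt(rowSums(W^2))
  deg <- sum(nrm == 0)
  pos <- nrm > 0
  W[pos, ] <- W[pos, , drop = FALSE] / nrm[pos]
  if (deg == n) warning("all collateral rows are zero (kappa too large?)")
  structure(W, degenerate_rows = deg, coincident_pairs = coincident)
}
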