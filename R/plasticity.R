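#' Update the running mean rates
#'
#' Exponential moving averages of the output and input rates,
#' `xbar' = xbar + eta (x - xbar)`, used for mean subtraction in the
#' Hebbian rule.
#'
#' @param psibar,rbar current means.
#' @param psi,r current rates.
#' @param eta averaging factor in `(0, 1]` (default 0.05).
#' @return list with updated `psibar`, `rbar`.
#' @export
update_running_means <- function(psibar, rbar, psi, r, eta = 0.05) {
  stopifnot(eta > 0, eta <= 1)
  list(psibar = psibar + eta * (psi - psibar),
       rbar = rbar + eta * (r - rbar))
}

#' One Hebbian learning step on the feed-forward weights
#'
#' `W~_ij = W_ij + eps (Psi_i r_j - Psibar_i rbar_j)`, followed by rescaling
#' every row to unit L2 norm. The mean-subtracted outer product moves each
#' unit's weight vector toward the inputs that co-occur with its
#' above-average firing; the normalization enforces competition within the
#' row. When the rates equal their running means the update is exactly null.
#'
#' @param W weight matrix (`n_mec x n_inp`), rows of unit L2 norm.
#' @param psi output rates (length `n_mec`).
#' @param r input rates (length `n_inp`).
#' @param psibar,rbar running mean rates.
#' @param eps learning rate (default 0.002).
#' @return updated weight matrix with unit-norm rows.
#' @export
hebb_step <- function(W, psi, r, psibar, rbar, eps = 0.002) {
  Wt <- W + eps * (outer(psi, r) - outer(psibar, rbar))
  nrm <- sqrt(rowSums(Wt^2))
  if (any(nrm == 0)) stop("weight row collapsed to zero; cannot normalize")
  Wt / nrm
}

# random nonnegative weights with unit-norm rows
init_weights <- function(n_mec, n_inp) {
  W <- matrix(stats::runif(n_mec * n_inp), n_mec, n_inp)
  W / sqrt(rowSums(W^2))
}
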