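#' One heading update of the correlated random walk
#'
#' Rotates a unit heading vector by an angle drawn from `N(0, sigma_h)`
#' about a uniformly random axis perpendicular to it: the single-parameter
#' isotropic generalization of a planar Gaussian turn to three dimensions.
#' The angle between input and output headings is distributed as
#' `|N(0, sigma_h)|`.
#'
#' @param heading unit 3-vector.
#' @param sigma_h turn-angle standard deviation in radians (`>= 0`).
#' @return the new unit heading.
#' @export
step_heading <- function(heading, sigma_h) {
  nrm <- sqrt(sum(heading^2))
  if (nrm < 1e-12) stop("zero-norm heading")
  if (sigma_h < 0) stop("sigma_h must be >= 0")
  h <- heading / nrm
  if (sigma_h == 0) return(h)
  ang <- stats::rnorm(1, 0, sigma_h)
  repeat {
    u <- stats::rnorm(3)
    u <- u - sum(u * h) * h
    if (sqrt(sum(u^2)) > 1e-12) break
  }
  u <- u / sqrt(sum(u^2))
  axh <- c(u[2] * h[3] - u[3] * h[2],
           u[3] * h[1] - u[1] * h[3],
           u[1] * h[2] - u[2] * h[1])
  nh <- cos(ang) * h + sin(ang) * axh
  nh / sqrt(sum(nh^2))
}

# uniform random unit vector(s)
random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Simulate the exploratory flight path
#'
#' Correlated random walk at constant speed inside the box: at each step the
#' heading turns by a Gaussian angle (see [step_heading()]) and the position
#' advances by `v*dt/L` box units; a step that would exit the box is
#' specularly reflected. The walk starts at the box center with a uniformly
#' random initial heading.
#'
#' @param n_steps number of positions to generate (`>= 1`).
#' @param cfg a [sim_config()]; uses `v_step`, `sigma_h`, `box_scale`.
#' @param pos0,head0 optional initial position and heading.
#' @return an `n_steps x 3` matrix of positions in box units, with the
#'   configuration attached as attribute `cfg`.
#' @export
simulate_path <- function(n_steps, cfg = sim_config(), pos0 = NULL,
                          head0 = NULL) {
  stopifnot(n_steps >= 1)
  box <- cfg$box_scale
  if (cfg$v_step >= min(box)) stop("step length exceeds box side")
  pos0 <- pos0 %||% (box / 2)
  head0 <- head0 %||% as.vector(random_unit_vectors(1))
  stopifnot(all(pos0 >= 0), all(pos0 <= box))
  p <- cpp_simulate_path(as.integer(n_steps), cfg$v_step, cfg$sigma_h,
                         box, pos0, head0)
  colnames(p) <- c("x", "y", "z")
  attr(p, "cfg") <- cfg
  p
}
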