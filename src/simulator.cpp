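// Core simulation loop: correlated random walk, place-cell inputs,
// adaptation dynamics with gain/threshold control, Hebbian learning.
// Uses R's RNG throughout so runs are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Rotate heading by an angle drawn from N(0, sigma_h) about a uniformly
// random axis perpendicular to the current heading (isotropic 3D turn with
// a single width parameter).
static void step_heading_inplace(arma::vec3 &head, double sigma_h) {
  if (sigma_h <= 0.0) return;
  double ang = R::rnorm(0.0, sigma_h);
  arma::vec3 u;
  double nu_ = 0.0;
  do {
    u[0] = R::norm_rand(); u[1] = R::norm_rand(); u[2] = R::norm_rand();
    u -= arma::dot(u, head) * head;
    nu_ = arma::norm(u);
  } while (nu_ < 1e-12);
  u /= nu_;
  arma::vec3 axh = arma::cross(u, head);
  head = std::cos(ang) * head + std::sin(ang) * axh;
  head /= arma::norm(head);
}

// One movement step with specular reflection at the box walls.
static void move_reflect(arma::vec3 &pos, arma::vec3 &head, double v_step,
                         const arma::vec3 &box) {
  pos += v_step * head;
  for (int d = 0; d < 3; ++d) {
    while (pos[d] < 0.0 || pos[d] > box[d]) {
      if (pos[d] < 0.0) { pos[d] = -pos[d]; head[d] = -head[d]; }
      else              { pos[d] = 2.0 * box[d] - pos[d]; head[d] = -head[d]; }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_simulate_path(int n_steps, double v_step, double sigma_h,
                            arma::vec box, arma::vec pos0, arma::vec head0) {
  arma::vec3 pos = pos0, head = head0;
  head /= arma::norm(head);
  arma::mat out(n_steps, 3);
  out.row(0) = pos.t();
  for (int t = 1; t < n_steps; ++t) {
    step_heading_inplace(head, sigma_h);
    move_reflect(pos, head, v_step, box);
    out.row(t) = pos.t();
  }
  return out;
}

// Threshold-nonlinear transfer; returns mean activity and sparsity through
// the output arguments.
static void transfer_eval(const arma::vec &alpha, double g, double mu,
                          arma::vec &psi, double &a, double &s) {
  const double two_over_pi = 2.0 / M_PI;
  int n = alpha.n_elem;
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = alpha[i] - mu;
    double v = d > 0.0 ? two_over_pi * std::atan(g * d) : 0.0;
    psi[i] = v;
    sum += v; sum2 += v * v;
  }
  a = sum / n;
  s = sum2 > 0.0 ? (sum * sum) / (n * sum2) : 0.0;
}

// Iterative gain/threshold adjustment driving mean activity and sparsity
// into a relative band around (a0, s0). Warm-started from the caller's
// (g, mu). If the band is not reached within max_iter iterations the
// iterate with the smallest maximal relative violation is kept.
static bool adjust_gain_threshold_inplace(const arma::vec &alpha, double &g,
                                          double &mu, double a0, double s0,
                                          double b3, double b4, double tol,
                                          int max_iter, arma::vec &psi) {
  double a, s;
  double best_g = g, best_mu = mu, best_viol = arma::datum::inf;
  for (int k = 0; k < max_iter; ++k) {
    transfer_eval(alpha, g, mu, psi, a, s);
    double viol = std::max(std::fabs(a - a0) / a0, std::fabs(s - s0) / s0);
    if (viol < best_viol) { best_viol = viol; best_g = g; best_mu = mu; }
    if (viol <= tol) return true;
    mu += b3 * (a - a0);
    g += b4 * g * (s - s0);
    if (g < 1e-12) g = 1e-12;
  }
  g = best_g; mu = best_mu;
  transfer_eval(alpha, g, mu, psi, a, s);
  return false;
}

// [[Rcpp::export]]
List cpp_run_simulation(const arma::mat &centers,     // Ninp x 3
                        const arma::mat &Wt0,         // Ninp x Nmec (columns = units)
                        const arma::mat &Wcoll,       // Nmec x Nmec
                        const arma::mat &theta,       // Nmec x 3 unit rows
                        const arma::vec &b1, const arma::vec &b2,
                        double eps, double eta,
                        double a0, double s0, double b3, double b4,
                        double band_tol, int max_iter,
                        double hd_c, double hd_nu, double rho_coll,
                        int tau_delay, double sigma_p, double v_step,
                        double sigma_h, int n_steps,
                        const arma::ivec &checkpoints,
                        int map_res, const arma::vec &box,
                        double g0, double mu0,
                        const arma::vec &pos0, const arma::vec &head0,
                        bool learn = true) {
  const int n_inp = centers.n_rows, n_mec = Wt0.n_cols;
  const int n_ck = checkpoints.n_elem;
  const int n_vox = map_res * map_res * map_res;
  const double inv2sp2 = 1.0 / (2.0 * sigma_p * sigma_p);
  const double cut2 = 36.0 * sigma_p * sigma_p;   // r < 1.6e-8 beyond 6 sigma

  arma::mat Wt = Wt0;                      // learned feed-forward weights
  arma::vec alpha(n_mec, arma::fill::zeros), beta(n_mec, arma::fill::zeros);
  arma::vec h(n_mec, arma::fill::zeros), h_prev(n_mec, arma::fill::zeros);
  arma::vec psi(n_mec, arma::fill::zeros);
  arma::vec psibar(n_mec, arma::fill::zeros), rbar(n_inp, arma::fill::zeros);
  arma::vec r(n_inp);
  arma::mat delay(n_mec, std::max(tau_delay, 1), arma::fill::zeros);
  arma::vec3 pos = pos0, head = head0;
  head /= arma::norm(head);
  double g = g0, mu = mu0;

  // per-window accumulators
  arma::mat map_acc(n_vox, n_mec, arma::fill::zeros);
  arma::vec occ_acc(n_vox, arma::fill::zeros);
  double a_acc = 0.0, s_acc = 0.0;
  long nonconv_win = 0;
  long win_len = 0;

  List maps(n_ck);
  arma::mat occ_out(n_vox, n_ck, arma::fill::zeros);
  arma::vec a_mean(n_ck), s_mean(n_ck), g_trace(n_ck), mu_trace(n_ck);
  arma::ivec nonconv(n_ck);
  int ck = 0;

  const bool use_coll = rho_coll > 0.0 && tau_delay > 0;

  for (int t = 0; t < n_steps; ++t) {
    // adaptation driven by the previous step's input
    for (int i = 0; i < n_mec; ++i) {
      alpha[i] += b1[i] * (h_prev[i] - beta[i] - alpha[i]);
      beta[i]  += b2[i] * (h_prev[i] - beta[i]);
    }

    // movement
    step_heading_inplace(head, sigma_h);
    move_reflect(pos, head, v_step, box);

    // place-cell input rates
    for (int j = 0; j < n_inp; ++j) {
      double dx = pos[0] - centers(j, 0);
      double dy = pos[1] - centers(j, 1);
      double dz = pos[2] - centers(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      r[j] = d2 > cut2 ? 0.0 : std::exp(-d2 * inv2sp2);
    }

    // total input with head-direction gating and delayed collateral drive
    h = Wt.t() * r;
    if (use_coll) {
      int slot = t % tau_delay;
      h += rho_coll * (Wcoll * delay.col(slot));  // activity at t - tau
    }
    for (int i = 0; i < n_mec; ++i) {
      double cg = theta(i, 0) * head[0] + theta(i, 1) * head[1] +
                  theta(i, 2) * head[2];
      h[i] *= hd_c + (1.0 - hd_c) * std::exp(hd_nu * (cg - 1.0));
    }

    // rates via gain/threshold control
    bool ok = adjust_gain_threshold_inplace(alpha, g, mu, a0, s0, b3, b4,
                                            band_tol, max_iter, psi);
    if (!ok) ++nonconv_win;

    // Hebbian step with running-mean subtraction, then L2 row norm
    if (learn) {
      for (int i = 0; i < n_mec; ++i) {
        double *w = Wt.colptr(i);
        const double *rp = r.memptr(), *rb = rbar.memptr();
        const double pi_ = psi[i], pb = psibar[i];
        double nrm2 = 0.0;
        for (int j = 0; j < n_inp; ++j) {
          double v = w[j] + eps * (pi_ * rp[j] - pb * rb[j]);
          w[j] = v;
          nrm2 += v * v;
        }
        if (nrm2 <= 0.0)
          stop("weight row of unit %d collapsed to zero at step %d", i + 1, t + 1);
        double inv = 1.0 / std::sqrt(nrm2);
        for (int j = 0; j < n_inp; ++j) w[j] *= inv;
      }
      psibar += eta * (psi - psibar);
      rbar += eta * (r - rbar);
    }

    if (use_coll) delay.col(t % tau_delay) = psi;
    h_prev = h;

    // rate-map accumulation on the voxel grid
    int ix = std::min((int)(pos[0] / box[0] * map_res), map_res - 1);
    int iy = std::min((int)(pos[1] / box[1] * map_res), map_res - 1);
    int iz = std::min((int)(pos[2] / box[2] * map_res), map_res - 1);
    int vox = ix + map_res * (iy + map_res * iz);
    map_acc.row(vox) += psi.t();
    occ_acc[vox] += 1.0;
    a_acc += arma::mean(psi);
    {
      double ssum = arma::accu(psi), ssum2 = arma::dot(psi, psi);
      s_acc += ssum2 > 0 ? ssum * ssum / (n_mec * ssum2) : 0.0;
    }
    ++win_len;

    if ((t & 2047) == 0 && (!alpha.is_finite() || !h.is_finite()))
      stop("non-finite network state at step %d", t + 1);

    if (ck < n_ck && t + 1 == checkpoints[ck]) {
      maps[ck] = map_acc;
      occ_out.col(ck) = occ_acc;
      a_mean[ck] = a_acc / win_len;
      s_mean[ck] = s_acc / win_len;
      g_trace[ck] = g; mu_trace[ck] = mu;
      nonconv[ck] = (int)nonconv_win;
      map_acc.zeros(); occ_acc.zeros();
      a_acc = s_acc = 0.0; nonconv_win = 0; win_len = 0;
      ++ck;
    }

    if ((t & 16383) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["maps"] = maps, _["occupancy"] = occ_out,
    _["a_mean"] = a_mean, _["s_mean"] = s_mean,
    _["g_trace"] = g_trace, _["mu_trace"] = mu_trace,
    _["nonconverged"] = nonconv,
    _["W"] = Wt.t(), _["alpha"] = alpha, _["beta"] = beta,
    _["psibar"] = psibar, _["rbar"] = rbar,
    _["g"] = g, _["mu"] = mu,
    _["pos"] = pos, _["head"] = head);
}
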