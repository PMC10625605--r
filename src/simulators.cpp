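// Simulation cores for the stochastic spiking samplers.
// All randomness goes through R's RNG so set.seed() in R controls every run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double kDeg2Rad = M_PI / 180.0;

// Wrap-safe population-vector mean of a (possibly signed) mass vector
// over preferred stimuli theta (degrees): the circular resultant locates
// the activity bump, then the linear mean of minimal-arc deviations
// around it gives the exact activity-weighted mean. Returns the angle in
// (-180, 180] and the total mass; NaN when the decode is undefined.
static inline void popvec(const arma::vec &m, const arma::vec &theta,
                          const arma::vec &ct, const arma::vec &st,
                          double &ang, double &tot) {
  double c = arma::dot(m, ct);
  double s = arma::dot(m, st);
  tot = arma::accu(m);
  if ((c == 0.0 && s == 0.0) || tot == 0.0) {
    ang = NA_REAL;
    return;
  }
  double ref = std::atan2(s, c) / kDeg2Rad;
  double dev = 0.0;
  const int n = theta.n_elem;
  for (int j = 0; j < n; ++j) {
    double d = theta[j] - ref;
    d -= 360.0 * std::floor(d / 360.0 + 0.5);  // minimal arc, [-180, 180)
    if (d <= -180.0) d += 360.0;
    dev += m[j] * d;
  }
  ang = ref + dev / tot;
  ang -= 360.0 * std::floor(ang / 360.0 + 0.5);
  if (ang <= -180.0) ang += 360.0;
}

// Excitatory-only linear sampling network: fixed feedforward count vector
// u_f presented every step, self-connected recurrence w_e * r_{t-1}, and
// Poisson-mimicking multiplicative noise on the recurrent input
// (or optional additive noise of SD sigma_r).
// [[Rcpp::export]]
List sim_eonly_cpp(const arma::vec &u_f, double w_e, int n_steps,
                   const arma::vec &theta_deg, bool noise_mult,
                   double sigma_r, double rate_ceiling, bool keep_arrays) {
  const int n = u_f.n_elem;
  arma::vec ct = arma::cos(theta_deg * kDeg2Rad);
  arma::vec st = arma::sin(theta_deg * kDeg2Rad);

  arma::vec r_prev(n, arma::fill::zeros);
  arma::vec u_r(n), lambda(n);
  arma::mat summary(n_steps, 6);
  arma::mat R_keep, UR_keep, LAM_keep;
  if (keep_arrays) {
    R_keep.set_size(n, n_steps);
    UR_keep.set_size(n, n_steps);
    LAM_keep.set_size(n, n_steps);
  }
  int status = 0, bad_step = -1;

  for (int t = 0; t < n_steps; ++t) {
    // mean recurrent input from previous spikes, then noise corruption
    for (int j = 0; j < n; ++j) {
      double ubar = w_e * r_prev[j];
      double u = ubar;
      if (noise_mult) {
        double v = ubar > 0.0 ? ubar : 0.0;
        if (v > 0.0) u += std::sqrt(v) * R::norm_rand();
      }
      if (sigma_r > 0.0) u += sigma_r * R::norm_rand();
      u_r[j] = u;
      lambda[j] = u_f[j] + u;
    }
    double n_lambda = arma::accu(lambda);
    if (n_lambda > rate_ceiling) { status = 1; bad_step = t; break; }

    arma::vec r(n);
    for (int j = 0; j < n; ++j) {
      double lam = lambda[j];
      r[j] = lam > 0.0 ? R::rpois(lam) : 0.0;
    }

    double s_hat, n_r, z_hat, n_ur, s_bar, tot_l;
    popvec(r, theta_deg, ct, st, s_hat, n_r);
    popvec(u_r, theta_deg, ct, st, z_hat, n_ur);
    if (n_ur <= 0.0) z_hat = NA_REAL;
    popvec(lambda, theta_deg, ct, st, s_bar, tot_l);
    summary(t, 0) = s_hat;
    summary(t, 1) = n_r;
    summary(t, 2) = z_hat;
    summary(t, 3) = n_ur;
    summary(t, 4) = s_bar;
    summary(t, 5) = n_lambda;

    if (keep_arrays) {
      R_keep.col(t) = r;
      UR_keep.col(t) = u_r;
      LAM_keep.col(t) = lambda;
    }
    r_prev = r;
  }

  List out = List::create(_["summary"] = summary, _["status"] = status,
                          _["bad_step"] = bad_step + 1);
  if (keep_arrays) {
    out["r"] = R_keep;
    out["u_r"] = UR_keep;
    out["lambda"] = LAM_keep;
  }
  return out;
}

struct EIState {
  arma::vec ye, yi, xfe, xfi; // synaptically filtered spike trains (1/ms)
  arma::ivec ref_e, ref_i;    // refractory countdowns (steps)
  EIState(int ne, int ni)
      : ye(ne, arma::fill::zeros), yi(ni, arma::fill::zeros),
        xfe(ne, arma::fill::zeros), xfi(ni, arma::fill::zeros),
        ref_e(ne, arma::fill::zeros), ref_i(ni, arma::fill::zeros) {}
};

static inline void draw_spikes(const arma::vec &lam, double dt, int ref_steps,
                               arma::ivec &refr, arma::vec &spk) {
  const int n = lam.n_elem;
  for (int j = 0; j < n; ++j) {
    if (refr[j] > 0) {
      refr[j]--;
      spk[j] = 0.0;
    } else {
      double l = lam[j];
      spk[j] = l > 0.0 ? R::rpois(l * dt) : 0.0;
      if (spk[j] > 0.0 && ref_steps > 0) refr[j] = ref_steps;
    }
  }
}

// One E-I ring network (Hawkes process with synaptic filtering,
// refractoriness and multiplicative recurrent noise). Feedforward drive is a
// stream of independent Poisson spikes with rates rate_e (per E neuron) and
// rate_i (every I neuron), in spikes/ms. Weight matrices arrive pre-scaled
// by 1/sqrt(N) and signed (inhibitory entries negative). Spikes of E
// neurons are decoded with a population vector in non-overlapping windows;
// the feedforward stream is decoded in the same windows for the likelihood.
// [[Rcpp::export]]
List sim_ei_cpp(const arma::vec &rate_e, double rate_i, const arma::mat &Jee,
                const arma::mat &Jei, const arma::mat &Jie,
                const arma::mat &Jii, int n_steps, double dt, double tau_d,
                int ref_steps, int window_steps, const arma::vec &theta_deg,
                bool rec_noise, double rate_ceiling, bool keep_arrays) {
  const int ne = rate_e.n_elem, ni = Jii.n_rows;
  arma::vec ct = arma::cos(theta_deg * kDeg2Rad);
  arma::vec st = arma::sin(theta_deg * kDeg2Rad);
  const double decay = std::exp(-dt / tau_d);

  EIState S(ne, ni);
  arma::vec se_f(ne), si_f(ni), re(ne), ri(ni);
  arma::vec win_r(ne, arma::fill::zeros), win_ff(ne, arma::fill::zeros);
  arma::vec win_ur(ne, arma::fill::zeros);
  const int n_win = n_steps / window_steps;
  arma::mat wins(n_win, 7);
  int iw = 0, status = 0, bad_step = -1;
  double rate_sum_e = 0.0, rate_sum_i = 0.0;
  arma::mat RE_keep;
  if (keep_arrays) RE_keep.set_size(ne, n_steps);

  for (int t = 0; t < n_steps; ++t) {
    // feedforward Poisson streams, synaptically filtered
    for (int j = 0; j < ne; ++j) se_f[j] = R::rpois(rate_e[j] * dt);
    for (int j = 0; j < ni; ++j) si_f[j] = R::rpois(rate_i * dt);
    S.xfe = S.xfe * decay + se_f / tau_d;
    S.xfi = S.xfi * decay + si_f / tau_d;

    arma::vec ur_e = Jee * S.ye + Jei * S.yi;
    arma::vec ur_i = Jie * S.ye + Jii * S.yi;
    if (rec_noise) {
      for (int j = 0; j < ne; ++j) {
        double v = ur_e[j] > 0.0 ? ur_e[j] : 0.0;
        if (v > 0.0) ur_e[j] += std::sqrt(v) * R::norm_rand();
      }
      for (int j = 0; j < ni; ++j) {
        double v = ur_i[j] > 0.0 ? ur_i[j] : 0.0;
        if (v > 0.0) ur_i[j] += std::sqrt(v) * R::norm_rand();
      }
    }
    arma::vec lam_e = S.xfe + ur_e;
    arma::vec lam_i = S.xfi + ur_i;
    double mean_rate = arma::accu(lam_e);
    if (mean_rate > rate_ceiling) { status = 1; bad_step = t; break; }

    draw_spikes(lam_e, dt, ref_steps, S.ref_e, re);
    draw_spikes(lam_i, dt, ref_steps, S.ref_i, ri);
    S.ye = S.ye * decay + re / tau_d;
    S.yi = S.yi * decay + ri / tau_d;

    rate_sum_e += arma::accu(re);
    rate_sum_i += arma::accu(ri);
    win_r += re;
    win_ff += se_f;
    win_ur += ur_e;
    if (keep_arrays) RE_keep.col(t) = re;

    if ((t + 1) % window_steps == 0 && iw < n_win) {
      double s_hat, n_r, mu_ff, n_ff, z_hat, n_ur;
      popvec(win_r, theta_deg, ct, st, s_hat, n_r);
      popvec(win_ff, theta_deg, ct, st, mu_ff, n_ff);
      popvec(win_ur, theta_deg, ct, st, z_hat, n_ur);
      wins(iw, 0) = iw + 1;
      wins(iw, 1) = s_hat;
      wins(iw, 2) = n_r;
      wins(iw, 3) = mu_ff;
      wins(iw, 4) = n_ff;
      wins(iw, 5) = n_ur <= 0.0 ? NA_REAL : z_hat;
      wins(iw, 6) = n_ur;
      iw++;
      win_r.zeros();
      win_ff.zeros();
      win_ur.zeros();
    }
  }

  List out = List::create(
      _["windows"] = wins.rows(0, std::max(iw - 1, 0)), _["status"] = status,
      _["bad_step"] = bad_step + 1,
      _["mean_rate_e"] = rate_sum_e / (ne * n_steps * dt) * 1000.0,
      _["mean_rate_i"] = rate_sum_i / (ni * n_steps * dt) * 1000.0);
  if (keep_arrays) out["r_e"] = RE_keep;
  return out;
}

// Two coupled E-I ring circuits. Within a network there are no E-to-E
// connections (uniform marginal prior); across networks E neurons project
// with a ring-Gaussian profile onto E cells (Jx) and uniformly onto I cells
// (Jxi). Recurrent interactions carry no noise in the coupled model.
// [[Rcpp::export]]
List sim_coupled_cpp(const arma::mat &rate_e2, double rate_i,
                     const arma::mat &Jei, const arma::mat &Jie,
                     const arma::mat &Jii, const arma::mat &Jx,
                     const arma::mat &Jxi, int n_steps, double dt,
                     double tau_d, int ref_steps, int window_steps,
                     const arma::vec &theta_deg, double rate_ceiling) {
  const int ne = rate_e2.n_rows, ni = Jii.n_rows;
  arma::vec ct = arma::cos(theta_deg * kDeg2Rad);
  arma::vec st = arma::sin(theta_deg * kDeg2Rad);
  const double decay = std::exp(-dt / tau_d);

  EIState S1(ne, ni), S2(ne, ni);
  arma::vec sf(ne), sfi(ni), re(ne), ri(ni);
  arma::mat win_r(ne, 2, arma::fill::zeros), win_ff(ne, 2, arma::fill::zeros);
  const int n_win = n_steps / window_steps;
  arma::mat wins(n_win, 9);
  int iw = 0, status = 0, bad_step = -1;

  for (int t = 0; t < n_steps; ++t) {
    EIState *nets[2] = {&S1, &S2};
    arma::vec lam_e[2], lam_i[2];
    for (int m = 0; m < 2; ++m) {
      EIState &Sm = *nets[m];
      EIState &So = *nets[1 - m];
      for (int j = 0; j < ne; ++j) sf[j] = R::rpois(rate_e2(j, m) * dt);
      for (int j = 0; j < ni; ++j) sfi[j] = R::rpois(rate_i * dt);
      Sm.xfe = Sm.xfe * decay + sf / tau_d;
      Sm.xfi = Sm.xfi * decay + sfi / tau_d;
      win_ff.col(m) += sf;
      lam_e[m] = Sm.xfe + Jei * Sm.yi + Jx * So.ye;
      lam_i[m] = Sm.xfi + Jie * Sm.ye + Jii * Sm.yi + Jxi * So.ye;
    }
    double tot = arma::accu(lam_e[0]) + arma::accu(lam_e[1]);
    if (tot > rate_ceiling) { status = 1; bad_step = t; break; }
    for (int m = 0; m < 2; ++m) {
      EIState &Sm = *nets[m];
      draw_spikes(lam_e[m], dt, ref_steps, Sm.ref_e, re);
      draw_spikes(lam_i[m], dt, ref_steps, Sm.ref_i, ri);
      Sm.ye = Sm.ye * decay + re / tau_d;
      Sm.yi = Sm.yi * decay + ri / tau_d;
      win_r.col(m) += re;
    }

    if ((t + 1) % window_steps == 0 && iw < n_win) {
      wins(iw, 0) = iw + 1;
      for (int m = 0; m < 2; ++m) {
        double s_hat, n_r, mu_ff, n_ff;
        popvec(win_r.col(m), theta_deg, ct, st, s_hat, n_r);
        popvec(win_ff.col(m), theta_deg, ct, st, mu_ff, n_ff);
        wins(iw, 1 + 4 * m) = s_hat;
        wins(iw, 2 + 4 * m) = n_r;
        wins(iw, 3 + 4 * m) = mu_ff;
        wins(iw, 4 + 4 * m) = n_ff;
      }
      iw++;
      win_r.zeros();
      win_ff.zeros();
    }
  }

  return List::create(_["windows"] = wins.rows(0, std::max(iw - 1, 0)),
                      _["status"] = status, _["bad_step"] = bad_step + 1);
}
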