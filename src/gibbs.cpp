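#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the whole-genome regression
//   y = mu * 1 + Z v + e,  e ~ N(0, sigma2_e I)
// BayesA: v_j ~ N(0, sigma2_vj), sigma2_vj ~ S0 / chisq(df_m) with S0 the
// total prior scale (prior mode S0 / (df_m + 2))
// BayesB: v_j = 0 with prob (1 - prob_in), else as BayesA; the inclusion
// indicator is sampled from its marginal odds with v_j integrated out.
//
// Z must arrive column-centred; zero-variance columns carry zsq == 0 and are
// held at effect 0. Variance updates draw (scale + SS) / rchisq(df + k),
// the scaled-inverse-chi-squared conditional in total-scale form.
//
// Uses R's RNG, so the chain is reproducible under set.seed() in R.
// [[Rcpp::export]]
List gibbs_wgr(const NumericMatrix& Z, const NumericVector& y,
               const int n_iter, const int burn_in,
               const bool bayesb, const double prob_in,
               const double df_marker, const double df_resid,
               const double S0, const double Se0,
               const double var_marker_fixed,  // <= 0: sample per-marker
               const double var_e_fixed) {    // <= 0: sample
  const int n = Z.nrow(), m = Z.ncol();
  RNGScope scope;

  std::vector<double> zsq(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }

  double ybar = 0.0, yvar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
  yvar /= (n - 1);

  double mu = ybar;
  std::vector<double> v(m, 0.0), s2v(m);
  const bool fix_v = var_marker_fixed > 0.0;
  const bool fix_e = var_e_fixed > 0.0;
  double s2e = fix_e ? var_e_fixed : 0.5 * yvar;
  if (s2e <= 0.0) s2e = 1e-8;
  for (int j = 0; j < m; ++j) s2v[j] = fix_v ? var_marker_fixed : S0;

  std::vector<double> r(n);  // residual y - mu - Z v
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> delta(m, 1.0);  // inclusion state (BayesB)
  std::vector<double> mu_sum(1, 0.0), v_sum(m, 0.0), v2_sum(m, 0.0),
      incl_sum(m, 0.0);
  double s2e_sum = 0.0, varg_sum = 0.0;
  int kept = 0;
  const double log_prior_odds =
      (prob_in >= 1.0) ? R_PosInf
                       : (prob_in <= 0.0 ? R_NegInf
                                         : std::log(prob_in / (1.0 - prob_in)));

  NumericMatrix trace(n_iter, 3);  // mu, sigma2_e, var(Zv) per iteration

  for (int it = 0; it < n_iter; ++it) {
    // mu | rest
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    double mu_new = mu + rbar + norm_rand() * std::sqrt(s2e / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= shift;
    mu = mu_new;

    // markers
    for (int j = 0; j < m; ++j) {
      if (zsq[j] <= 0.0) continue;  // monomorphic: effect held at 0
      const double* zj = &Z(0, j);
      double rhs = zsq[j] * v[j];
      for (int i = 0; i < n; ++i) rhs += zj[i] * r[i];

      bool include = true;
      if (bayesb) {
        if (prob_in >= 1.0) {
          include = true;
        } else if (prob_in <= 0.0) {
          include = false;
        } else {
          // marginal log Bayes factor for delta_j = 1 (v_j integrated out)
          double denom = s2e + zsq[j] * s2v[j];
          double log_bf = 0.5 * (std::log(s2e) - std::log(denom)) +
                          0.5 * rhs * rhs * s2v[j] / (s2e * denom);
          double logit = log_prior_odds + log_bf;
          double p1 = 1.0 / (1.0 + std::exp(-logit));
          include = unif_rand() < p1;
        }
      }

      double v_new = 0.0;
      if (include) {
        double C = zsq[j] + s2e / s2v[j];
        v_new = rhs / C + norm_rand() * std::sqrt(s2e / C);
      }
      if (v_new != v[j]) {
        double d = v[j] - v_new;
        for (int i = 0; i < n; ++i) r[i] += zj[i] * d;
        v[j] = v_new;
      }
      delta[j] = include ? 1.0 : 0.0;

      if (!fix_v) {
        if (include) {
          s2v[j] = (S0 + v[j] * v[j]) / ::Rf_rchisq(df_marker + 1.0);
        } else {
          s2v[j] = S0 / ::Rf_rchisq(df_marker);
        }
        if (s2v[j] < 1e-12) s2v[j] = 1e-12;
      }
    }

    // sigma2_e | rest
    if (!fix_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      s2e = (Se0 + sse) / ::Rf_rchisq(df_resid + n);
      if (s2e < 1e-12) s2e = 1e-12;
    }

    // realised genetic variance var(Zv) this iteration
    double gbar = 0.0, gvar = 0.0;
    for (int i = 0; i < n; ++i) gbar += (y[i] - mu - r[i]);
    gbar /= n;
    for (int i = 0; i < n; ++i) {
      double g = y[i] - mu - r[i] - gbar;
      gvar += g * g;
    }
    gvar /= (n - 1);

    trace(it, 0) = mu;
    trace(it, 1) = s2e;
    trace(it, 2) = gvar;

    if (it >= burn_in) {
      ++kept;
      mu_sum[0] += mu;
      s2e_sum += s2e;
      varg_sum += gvar;
      for (int j = 0; j < m; ++j) {
        v_sum[j] += v[j];
        v2_sum[j] += v[j] * v[j];
        incl_sum[j] += delta[j];
      }
    }
  }

  NumericVector eff(m), eff_sd(m), incl(m);
  for (int j = 0; j < m; ++j) {
    double mean = v_sum[j] / kept;
    double msq = v2_sum[j] / kept;
    eff[j] = mean;
    double var = msq - mean * mean;
    eff_sd[j] = var > 0 ? std::sqrt(var) : 0.0;
    incl[j] = incl_sum[j] / kept;
  }

  return List::create(
      _["mu"] = mu_sum[0] / kept, _["effects"] = eff,
      _["effects_sd"] = eff_sd, _["inclusion_prob"] = incl,
      _["var_e"] = s2e_sum / kept, _["var_g"] = varg_sum / kept,
      _["n_kept"] = kept, _["trace"] = trace);
}
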