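// Adaptive Metropolis-within-Gibbs sampler for the shared-component
// spatial model: two Bernoulli/logit outcomes, one shared ICAR field with
// reciprocal (or free) loadings, two outcome-specific ICAR fields, PC
// priors on the spatial precisions. The (intercept, coefficients) pair of
// each outcome moves as one block with Haario-style adaptive proposal
// covariance; fields, loading and precisions move by scalar random walks
// with Robbins-Monro scale adaptation. All adaptation happens during
// burn-in only; the linear predictors are cached and updated
// incrementally. Uses R's RNG stream so set.seed() on the R side gives
// bitwise reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log-likelihood change when eta -> eta + deta for a fixed set of rows
static inline double dll_const(const std::vector<int>& rows,
                               const int* y, const double* eta,
                               double deta) {
  double s = 0.0;
  for (size_t k = 0; k < rows.size(); ++k) {
    const int i = rows[k];
    const double e = eta[i];
    s += y[i] * deta - (softplus(e + deta) - softplus(e));
  }
  return s;
}

// log-likelihood change for row-specific predictor shifts
static inline double dll_vec(int n, const int* y, const double* eta,
                             const double* deta) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double e = eta[i];
    s += y[i] * deta[i] - (softplus(e + deta[i]) - softplus(e));
  }
  return s;
}

static inline double pc_logpdf(double tau, double lambda) {
  return std::log(lambda / 2.0) - 1.5 * std::log(tau) -
         lambda / std::sqrt(tau);
}

// in-place lower Cholesky of a small dense SPD matrix (row-major q x q)
static bool chol_small(std::vector<double>& A, int q) {
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * q + j];
      for (int k = 0; k < j; ++k) s -= A[i * q + k] * A[j * q + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * q + i] = std::sqrt(s);
      } else {
        A[i * q + j] = s / A[j * q + j];
      }
    }
    for (int j = i + 1; j < q; ++j) A[i * q + j] = 0.0;
  }
  return true;
}

// Haario-style adaptive proposal covariance for one coefficient block:
// running mean/covariance of the visited states, refreshed Cholesky,
// global scale tuned by Robbins-Monro toward the multivariate target.
struct BlockAdapt {
  int q = 0;
  long n_seen = 0;
  std::vector<double> mean, cov, chol;  // cov/chol row-major q x q
  double ls = 0.0;                       // log global scale
  void init(int q_) {
    q = q_;
    mean.assign(q, 0.0);
    cov.assign((size_t)q * q, 0.0);
    for (int i = 0; i < q; ++i) cov[i * q + i] = 0.01;
    chol.assign((size_t)q * q, 0.0);
    refresh();
  }
  void update(const std::vector<double>& x) {
    ++n_seen;
    const double w = 1.0 / (double)n_seen;
    for (int i = 0; i < q; ++i) {
      const double di = x[i] - mean[i];
      mean[i] += w * di;
      for (int j = 0; j <= i; ++j) {
        const double dj = x[j] - mean[j];
        // rank-1 covariance update (Welford)
        const double c = di * dj * (1.0 - w);
        cov[i * q + j] += w * (c - cov[i * q + j]);
        cov[j * q + i] = cov[i * q + j];
      }
    }
  }
  void refresh() {
    std::vector<double> A = cov;
    const double jitter = 1e-8;
    for (int i = 0; i < q; ++i) A[i * q + i] += jitter + 1e-12;
    if (n_seen < 10 * q) {                 // too few samples: identity
      A.assign((size_t)q * q, 0.0);
      for (int i = 0; i < q; ++i) A[i * q + i] = 0.01;
    }
    if (!chol_small(A, q)) {
      A.assign((size_t)q * q, 0.0);
      for (int i = 0; i < q; ++i) A[i * q + i] = 0.1;
    }
    chol = A;
  }
  // proposal step: 2.38/sqrt(q) * exp(ls) * L z
  void propose(std::vector<double>& step) {
    std::vector<double> z(q);
    for (int i = 0; i < q; ++i) z[i] = norm_rand();
    const double s = 2.38 / std::sqrt((double)q) * std::exp(ls);
    for (int i = 0; i < q; ++i) {
      double v = 0.0;
      for (int j = 0; j <= i; ++j) v += chol[i * q + j] * z[j];
      step[i] = s * v;
    }
  }
};

struct Adapt {
  std::vector<double> ls;   // log proposal scales
  double target, rate;
  bool on;
  void tune(int k, double acc_prob, int t) {
    if (on) ls[k] += rate / std::sqrt((double)t + 1.0) * (acc_prob - target);
  }
};

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix y, NumericMatrix X, IntegerVector district,
                   int n_nodes, IntegerMatrix edges, IntegerVector comp,
                   double scale_c,
                   double tau_beta, double load_mean, double load_prec,
                   double lambda_pc,
                   bool include_shared, bool include_specific,
                   bool reciprocal,
                   LogicalVector upd_alpha, LogicalVector upd_beta,
                   bool upd_V, LogicalVector upd_S,
                   bool upd_delta, bool upd_tauV, LogicalVector upd_tauS,
                   NumericVector alpha0, NumericMatrix beta0,
                   NumericVector V0, NumericMatrix S0,
                   NumericVector delta0, NumericVector tau0,
                   int n_iter, int burn_in, int thin,
                   double target_accept, double target_block,
                   double adapt_rate, double init_scale) {
  const int n = y.nrow(), p = X.ncol();
  const int n_delta = reciprocal ? 1 : 2;

  // --- state ---
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  NumericMatrix beta = clone(beta0);          // p x 2
  std::vector<double> V(V0.begin(), V0.end());
  NumericMatrix S = clone(S0);                // n_nodes x 2
  std::vector<double> ldelta(n_delta);        // log loading(s)
  for (int k = 0; k < n_delta; ++k) ldelta[k] = std::log(delta0[k]);
  double tau_V = tau0[0];
  double tau_S[2] = { tau0[1], tau0[2] };
  double sigma[2];
  auto set_sigma = [&]() {
    if (reciprocal) {
      sigma[0] = std::exp(ldelta[0]);
      sigma[1] = std::exp(-ldelta[0]);
    } else {
      sigma[0] = std::exp(ldelta[0]);
      sigma[1] = std::exp(ldelta[1]);
    }
    if (!include_shared) { sigma[0] = sigma[1] = 0.0; }
  };
  set_sigma();

  // --- bookkeeping ---
  std::vector<std::vector<int> > by_district(n_nodes);
  for (int i = 0; i < n; ++i) by_district[district[i]].push_back(i);
  std::vector<std::vector<int> > nb(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    nb[edges(e, 0)].push_back(edges(e, 1));
    nb[edges(e, 1)].push_back(edges(e, 0));
  }
  std::vector<std::vector<int> > xnz(p);      // rows with X != 0 per column
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) xnz[k].push_back(i);
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  int n_comp = 0;
  for (int j = 0; j < n_nodes; ++j) n_comp = std::max(n_comp, comp[j] + 1);
  std::vector<int> comp_size(n_comp, 0);
  for (int j = 0; j < n_nodes; ++j) comp_size[comp[j]]++;
  const double rank = (double)(n_nodes - n_comp);

  // cached linear predictors
  NumericMatrix eta(n, 2);
  for (int d = 0; d < 2; ++d)
    for (int i = 0; i < n; ++i) {
      double e = alpha[d];
      for (int k = 0; k < p; ++k) e += X(i, k) * beta(k, d);
      const int j = district[i];
      e += sigma[d] * V[j] + (include_specific ? S(j, d) : 0.0);
      eta(i, d) = e;
    }

  // quadratic form of a field over the edge set
  auto qform_vec = [&](const std::vector<double>& s) {
    double q = 0.0;
    for (int e = 0; e < edges.nrow(); ++e) {
      const double dd = s[edges(e, 0)] - s[edges(e, 1)];
      q += dd * dd;
    }
    return q;
  };
  auto qform_Scol = [&](int d) {
    double q = 0.0;
    for (int e = 0; e < edges.nrow(); ++e) {
      const double dd = S(edges(e, 0), d) - S(edges(e, 1), d);
      q += dd * dd;
    }
    return q;
  };

  // --- proposal scales ---
  // scalar-update layout: [0, n_nodes) V, then 2*n_nodes S, n_delta
  // loadings, 3 log-taus; the per-outcome (alpha, beta) blocks use
  // adaptive-covariance proposals instead
  const int oV = 0, oS = oV + n_nodes, oD = oS + 2 * n_nodes,
            oT = oD + n_delta;
  Adapt ad;
  ad.ls.assign(oT + 3, std::log(init_scale));
  ad.target = target_accept;
  ad.rate = adapt_rate;

  // joint (alpha_d, beta_d) blocks: coord 0 = intercept (if free),
  // then the free coefficient vector
  BlockAdapt blk[2];
  int blk_has_alpha[2];
  for (int d = 0; d < 2; ++d) {
    blk_has_alpha[d] = upd_alpha[d] ? 1 : 0;
    const int q = blk_has_alpha[d] + (upd_beta[d] ? p : 0);
    if (q > 0) blk[d].init(q);
  }
  std::vector<double> bstep, deta(n);

  // acceptance counters (post burn-in), per block
  double acc[5] = {0, 0, 0, 0, 0};   // coef V S delta tau
  double try_[5] = {0, 0, 0, 0, 0};

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int n_par = 2 + 2 * p + 3 * n_nodes + n_delta + 3;
  NumericMatrix draws(n_keep, n_par);
  int row = 0;

  RNGScope scope;
  const int* yc[2] = { &y(0, 0), &y(0, 1) };
  double* etac[2] = { &eta(0, 0), &eta(0, 1) };

  for (int it = 0; it < n_iter; ++it) {
    ad.on = (it < burn_in);
    const bool rec = (it >= burn_in);

    // ---- joint (alpha_d, beta_d) block, adaptive-covariance RW ----
    for (int d = 0; d < 2; ++d) {
      const int q = blk[d].q;
      if (q == 0) continue;
      bstep.assign(q, 0.0);
      blk[d].propose(bstep);
      const double da = blk_has_alpha[d] ? bstep[0] : 0.0;
      const double* db = bstep.data() + blk_has_alpha[d];
      const int nb_coef = q - blk_has_alpha[d];
      std::fill(deta.begin(), deta.end(), da);
      for (int kk = 0; kk < nb_coef; ++kk) {
        if (db[kk] == 0.0) continue;
        for (size_t m = 0; m < xnz[kk].size(); ++m)
          deta[xnz[kk][m]] += db[kk];     // dummy design: X is 0/1
      }
      double dlp = dll_vec(n, yc[d], etac[d], deta.data());
      if (blk_has_alpha[d]) {
        const double a1 = alpha[d] + da;
        dlp += -0.5 * tau_beta * (a1 * a1 - alpha[d] * alpha[d]);
      }
      for (int kk = 0; kk < nb_coef; ++kk) {
        const double b1 = beta(kk, d) + db[kk];
        dlp += -0.5 * tau_beta * (b1 * b1 - beta(kk, d) * beta(kk, d));
      }
      const double ap = std::min(1.0, std::exp(dlp));
      if (rec) try_[0] += 1;
      if (unif_rand() < ap) {
        if (blk_has_alpha[d]) alpha[d] += da;
        for (int kk = 0; kk < nb_coef; ++kk) beta(kk, d) += db[kk];
        for (int i = 0; i < n; ++i) etac[d][i] += deta[i];
        if (rec) acc[0] += 1;
      }
      if (ad.on) {
        blk[d].ls += adapt_rate / std::sqrt((double)it + 1.0) *
                     (ap - target_block);
        std::vector<double> x(q);
        int c = 0;
        if (blk_has_alpha[d]) x[c++] = alpha[d];
        for (int kk = 0; kk < nb_coef; ++kk) x[c++] = beta(kk, d);
        blk[d].update(x);
        if (it % 50 == 49 || it == burn_in - 1) blk[d].refresh();
      }
    }

    // ---- shared field V (single-site, then per-component recenter) ----
    if (include_shared && upd_V) {
      for (int j = 0; j < n_nodes; ++j) {
        if (nb[j].empty()) continue;            // isolated: fixed at 0
        const int k = oV + j;
        const double dv = std::exp(ad.ls[k]) * norm_rand();
        const double v1 = V[j] + dv;
        double dq = 0.0;
        for (size_t m = 0; m < nb[j].size(); ++m) {
          const double vk = V[nb[j][m]];
          dq += (v1 - vk) * (v1 - vk) - (V[j] - vk) * (V[j] - vk);
        }
        double dlp = -0.5 * tau_V * scale_c * dq;
        dlp += dll_const(by_district[j], yc[0], etac[0], sigma[0] * dv);
        dlp += dll_const(by_district[j], yc[1], etac[1], sigma[1] * dv);
        const double ap = std::min(1.0, std::exp(dlp));
        if (rec) try_[1] += 1;
        if (unif_rand() < ap) {
          V[j] = v1;
          for (size_t m = 0; m < by_district[j].size(); ++m) {
            const int i = by_district[j][m];
            etac[0][i] += sigma[0] * dv;
            etac[1][i] += sigma[1] * dv;
          }
          if (rec) acc[1] += 1;
        }
        ad.tune(k, ap, it);
      }
      // recenter per component (identifiability projection)
      std::vector<double> cm(n_comp, 0.0);
      for (int j = 0; j < n_nodes; ++j) cm[comp[j]] += V[j];
      for (int c = 0; c < n_comp; ++c) cm[c] /= comp_size[c];
      for (int j = 0; j < n_nodes; ++j) V[j] -= cm[comp[j]];
      for (int i = 0; i < n; ++i) {
        const double m = cm[comp[district[i]]];
        etac[0][i] -= sigma[0] * m;
        etac[1][i] -= sigma[1] * m;
      }
    }

    // ---- specific fields S_d ----
    if (include_specific) {
      for (int d = 0; d < 2; ++d) {
        if (!upd_S[d]) continue;
        for (int j = 0; j < n_nodes; ++j) {
          if (nb[j].empty()) continue;
          const int k = oS + d * n_nodes + j;
          const double ds = std::exp(ad.ls[k]) * norm_rand();
          const double s1 = S(j, d) + ds;
          double dq = 0.0;
          for (size_t m = 0; m < nb[j].size(); ++m) {
            const double sk = S(nb[j][m], d);
            dq += (s1 - sk) * (s1 - sk) - (S(j, d) - sk) * (S(j, d) - sk);
          }
          double dlp = -0.5 * tau_S[d] * scale_c * dq;
          dlp += dll_const(by_district[j], yc[d], etac[d], ds);
          const double ap = std::min(1.0, std::exp(dlp));
          if (rec) try_[2] += 1;
          if (unif_rand() < ap) {
            S(j, d) = s1;
            for (size_t m = 0; m < by_district[j].size(); ++m)
              etac[d][by_district[j][m]] += ds;
            if (rec) acc[2] += 1;
          }
          ad.tune(k, ap, it);
        }
        std::vector<double> cm(n_comp, 0.0);
        for (int j = 0; j < n_nodes; ++j) cm[comp[j]] += S(j, d);
        for (int c = 0; c < n_comp; ++c) cm[c] /= comp_size[c];
        for (int j = 0; j < n_nodes; ++j) S(j, d) -= cm[comp[j]];
        for (int i = 0; i < n; ++i)
          etac[d][i] -= cm[comp[district[i]]];
      }
    }

    // ---- loading(s), random walk on the log scale ----
    if (include_shared && upd_delta) {
      if (reciprocal) {
        const int k = oD;
        const double step = std::exp(ad.ls[k]) * norm_rand();
        const double ld1 = ldelta[0] + step;
        const double s0n = std::exp(ld1), s1n = std::exp(-ld1);
        double dlp = -0.5 * load_prec *
          ((ld1 - load_mean) * (ld1 - load_mean) -
           (ldelta[0] - load_mean) * (ldelta[0] - load_mean));
        for (int i = 0; i < n; ++i) {
          const double vj = V[district[i]];
          const double e0 = etac[0][i], e1 = etac[1][i];
          const double de0 = (s0n - sigma[0]) * vj;
          const double de1 = (s1n - sigma[1]) * vj;
          dlp += yc[0][i] * de0 - (softplus(e0 + de0) - softplus(e0));
          dlp += yc[1][i] * de1 - (softplus(e1 + de1) - softplus(e1));
        }
        const double ap = std::min(1.0, std::exp(dlp));
        if (rec) try_[3] += 1;
        if (unif_rand() < ap) {
          for (int i = 0; i < n; ++i) {
            const double vj = V[district[i]];
            etac[0][i] += (s0n - sigma[0]) * vj;
            etac[1][i] += (s1n - sigma[1]) * vj;
          }
          ldelta[0] = ld1;
          set_sigma();
          if (rec) acc[3] += 1;
        }
        ad.tune(k, ap, it);
      } else {
        for (int d = 0; d < 2; ++d) {
          const int k = oD + d;
          const double step = std::exp(ad.ls[k]) * norm_rand();
          const double ld1 = ldelta[d] + step;
          const double sn = std::exp(ld1);
          double dlp = -0.5 * load_prec *
            ((ld1 - load_mean) * (ld1 - load_mean) -
             (ldelta[d] - load_mean) * (ldelta[d] - load_mean));
          for (int i = 0; i < n; ++i) {
            const double de = (sn - sigma[d]) * V[district[i]];
            const double e = etac[d][i];
            dlp += yc[d][i] * de - (softplus(e + de) - softplus(e));
          }
          const double ap = std::min(1.0, std::exp(dlp));
          if (rec) try_[3] += 1;
          if (unif_rand() < ap) {
            for (int i = 0; i < n; ++i)
              etac[d][i] += (sn - sigma[d]) * V[district[i]];
            ldelta[d] = ld1;
            set_sigma();
            if (rec) acc[3] += 1;
          }
          ad.tune(k, ap, it);
        }
      }
    }

    // ---- spatial precisions, random walk on log tau ----
    // target in log-tau coordinates: (rank/2) log tau - (tau c /2) Q
    //   + PC log-density + log tau (Jacobian)
    auto tau_update = [&](double& tau, double Q, int k) {
      const double step = std::exp(ad.ls[k]) * norm_rand();
      const double lt0 = std::log(tau), lt1 = lt0 + step;
      const double t1 = std::exp(lt1);
      double dlp = 0.5 * rank * (lt1 - lt0) -
        0.5 * scale_c * Q * (t1 - tau) +
        pc_logpdf(t1, lambda_pc) - pc_logpdf(tau, lambda_pc) +
        (lt1 - lt0);
      const double ap = std::min(1.0, std::exp(dlp));
      if (rec) try_[4] += 1;
      if (unif_rand() < ap) { tau = t1; if (rec) acc[4] += 1; }
      ad.tune(k, ap, it);
      return;
    };
    if (include_shared && upd_tauV) tau_update(tau_V, qform_vec(V), oT);
    if (include_specific) {
      for (int d = 0; d < 2; ++d)
        if (upd_tauS[d]) tau_update(tau_S[d], qform_Scol(d), oT + 1 + d);
    }

    // ---- record ----
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      int c = 0;
      draws(row, c++) = alpha[0];
      draws(row, c++) = alpha[1];
      for (int d = 0; d < 2; ++d)
        for (int k = 0; k < p; ++k) draws(row, c++) = beta(k, d);
      for (int j = 0; j < n_nodes; ++j) draws(row, c++) = V[j];
      for (int d = 0; d < 2; ++d)
        for (int j = 0; j < n_nodes; ++j) draws(row, c++) = S(j, d);
      for (int k = 0; k < n_delta; ++k) draws(row, c++) = std::exp(ldelta[k]);
      draws(row, c++) = tau_V;
      draws(row, c++) = tau_S[0];
      draws(row, c++) = tau_S[1];
      ++row;
    }
  }

  NumericVector acc_rates(5);
  const char* blk_names[5] = {"coef", "V", "S", "delta", "tau"};
  CharacterVector blknm(5);
  for (int b = 0; b < 5; ++b) {
    acc_rates[b] = try_[b] > 0 ? acc[b] / try_[b] : NA_REAL;
    blknm[b] = blk_names[b];
  }
  acc_rates.attr("names") = blknm;
  return List::create(_["draws"] = draws, _["accept"] = acc_rates);
}
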