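// Metropolis-within-Gibbs sampler for hierarchical Poisson disease-mapping
// models with BYM convolution spatial effects, iid + RW1 temporal effects,
// and an optional Kronecker-structured space-time interaction field.
//
// Model (most general form):
//   Y_it ~ Poisson(lambda_it),
//   log lambda_it = log E_it + beta0 + X_i beta + v_i + u_i + g_t + ph_t + d_it
// with v iid Normal(0, s2v); u intrinsic CAR over the adjacency graph;
// g iid Normal(0, s2g); ph RW1; d Gaussian with precision
// tau_d * (K_space (x) K_time). Latent sites are updated one at a time by
// adaptive random-walk Metropolis (exact Gibbs where no likelihood term
// applies); variances by conjugate Gamma draws or truncated-Gamma inverse-CDF
// draws under a uniform-on-sd prior. Intrinsic fields are recentred every
// iteration with compensating shifts so the linear predictor is unchanged.
//
// Uses R's RNG throughout: results are reproducible from set.seed() in R.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Adj {
  std::vector<std::vector<int>> nb;
  std::vector<double> n_nb;
};

// rate-parameterised gamma draw
inline double rgamma_rate(double shape, double rate) {
  return R::rgamma(shape, 1.0 / rate);
}

// draw sigma2 given quadratic form q and rank r
inline double draw_sigma2(double q, double r, int prior_type,
                          double shape, double rate, double upper) {
  if (prior_type == 0) {                       // Gamma(shape, rate) on precision
    double tau = rgamma_rate(shape + 0.5 * r, rate + 0.5 * q);
    return 1.0 / tau;
  }
  // Uniform(0, upper) on sd: psi = 1/sigma2 ~ Gamma((r-1)/2, q/2) truncated
  // to psi > upper^-2, sampled by inverse CDF
  double a = 0.5 * (r - 1.0);
  if (a <= 0.0) a = 0.5;                       // degenerate rank guard
  double lo = R::pgamma(1.0 / (upper * upper), a, 2.0 / q, 1, 0);
  double uu = R::runif(lo, 1.0);
  if (uu >= 1.0) uu = 1.0 - 1e-12;
  double psi = R::qgamma(uu, a, 2.0 / q, 1, 0);
  if (psi <= 0.0) psi = 1e-12;
  return 1.0 / psi;
}

struct StepSize {
  double s = 0.1;
  int acc = 0, tot = 0;
  void tune() {
    if (tot == 0) return;
    double rate = (double)acc / tot;
    if (rate > 0.5) s *= 1.2; else if (rate < 0.3) s /= 1.2;
    if (s < 1e-6) s = 1e-6;
    if (s > 10.0) s = 10.0;
    acc = 0; tot = 0;
  }
};

}  // namespace

// [[Rcpp::export(name = ".bym_mcmc")]]
List bym_mcmc(NumericMatrix Y, NumericMatrix logE, IntegerMatrix mask,
              NumericMatrix X, List neighbors, double icar_rank,
              bool has_temporal, bool has_interaction, int int_type,
              int n_iter, int n_burnin, int thin,
              int prior_type, double prior_shape, double prior_rate,
              double prior_upper,
              NumericVector fixed_sigma2,   // v,u,g,ph,d; NA = sample
              bool prior_only, bool sum_to_zero,
              double beta_prior_var, double init_beta0) {
  const int n = Y.nrow(), T = Y.ncol(), p = X.ncol();
  Adj adj;
  adj.nb.resize(n);
  adj.n_nb.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = neighbors[i];
    adj.nb[i] = std::vector<int>(v.begin(), v.end());
    adj.n_nb[i] = (double)v.size();
  }
  const bool space_struct = (int_type == 3 || int_type == 4);  // ICAR factor
  const bool time_struct  = (int_type == 2 || int_type == 4);  // RW1 factor

  // state
  double beta0 = init_beta0;
  std::vector<double> beta(p, 0.0), v(n, 0.0), u(n, 0.0);
  std::vector<double> g(T, 0.0), ph(T, 0.0);
  NumericMatrix del(n, T);               // zero-initialised
  double s2v = 0.1, s2u = 0.1, s2g = 0.1, s2ph = 0.1, s2d = 0.1;
  if (R_finite(fixed_sigma2[0])) s2v  = fixed_sigma2[0];
  if (R_finite(fixed_sigma2[1])) s2u  = fixed_sigma2[1];
  if (R_finite(fixed_sigma2[2])) s2g  = fixed_sigma2[2];
  if (R_finite(fixed_sigma2[3])) s2ph = fixed_sigma2[3];
  if (R_finite(fixed_sigma2[4])) s2d  = fixed_sigma2[4];

  NumericMatrix lambda(n, T);
  std::vector<double> ysum_r(n, 0.0), ysum_c(T, 0.0);
  double ysum = 0.0;
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      if (mask(i, t)) {
        ysum_r[i] += Y(i, t); ysum_c[t] += Y(i, t); ysum += Y(i, t);
      }

  std::vector<double> lsum_r(n, 0.0), lsum_c(T, 0.0);
  double lsum = 0.0;

  auto refresh_lambda = [&]() {
    std::fill(lsum_r.begin(), lsum_r.end(), 0.0);
    std::fill(lsum_c.begin(), lsum_c.end(), 0.0);
    lsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double xb = 0.0;
      for (int k = 0; k < p; ++k) xb += X(i, k) * beta[k];
      for (int t = 0; t < T; ++t) {
        if (!mask(i, t)) { lambda(i, t) = 0.0; continue; }
        double eta = logE(i, t) + beta0 + xb + v[i] + u[i];
        if (has_temporal) eta += g[t] + ph[t];
        if (has_interaction) eta += del(i, t);
        double lam = std::exp(eta);
        lambda(i, t) = lam;
        lsum_r[i] += lam; lsum_c[t] += lam; lsum += lam;
      }
    }
  };

  // K_time entries (RW1 or identity): diagonal and neighbour list over t
  auto kt_diag = [&](int t) -> double {
    if (!time_struct) return 1.0;
    return (t == 0 || t == T - 1) ? 1.0 : 2.0;
  };
  auto ks_diag = [&](int i) -> double {
    return space_struct ? adj.n_nb[i] : 1.0;
  };

  // (K_space Del K_time)_{it} via sparse neighbour sums
  auto KdK = [&](int i, int t) -> double {
    auto dkt = [&](int j) -> double {   // (Del K_time)_{j,t}
      double val = kt_diag(t) * del(j, t);
      if (time_struct) {
        if (t > 0)     val -= del(j, t - 1);
        if (t < T - 1) val -= del(j, t + 1);
      }
      return val;
    };
    double out = ks_diag(i) * dkt(i);
    if (space_struct)
      for (int j : adj.nb[i]) out -= dkt(j);
    return out;
  };

  StepSize st_b0, st_b, st_v, st_u, st_g, st_ph, st_d, st_bu;
  st_b0.s = 0.05; st_b.s = 0.05; st_bu.s = 0.1;

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericVector out_b0(n_keep);
  NumericMatrix out_beta(n_keep, p), out_v(n_keep, n), out_u(n_keep, n);
  NumericMatrix out_g(n_keep, has_temporal ? T : 0);
  NumericMatrix out_ph(n_keep, has_temporal ? T : 0);
  NumericMatrix out_d(n_keep, has_interaction ? n * T : 0);
  NumericMatrix out_s2(n_keep, 5);

  RNGScope scope;
  refresh_lambda();
  int keep = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    refresh_lambda();

    if (!prior_only) {
      // ---- intercept ----
      {
        double d0 = R::norm_rand() * st_b0.s;
        double dll = d0 * ysum - lsum * (std::exp(d0) - 1.0);
        dll += (beta0 * beta0 - (beta0 + d0) * (beta0 + d0)) / (2.0 * beta_prior_var);
        ++st_b0.tot;
        if (std::log(R::unif_rand()) < dll) {
          beta0 += d0; ++st_b0.acc;
          double f = std::exp(d0);
          lsum *= f;
          for (int i = 0; i < n; ++i) lsum_r[i] *= f;
          for (int t = 0; t < T; ++t) lsum_c[t] *= f;
          for (int i = 0; i < n; ++i)
            for (int t = 0; t < T; ++t) lambda(i, t) *= f;
        }
      }
      // ---- regression coefficients ----
      for (int k = 0; k < p; ++k) {
        double d0 = R::norm_rand() * st_b.s;
        double dll = 0.0;
        for (int i = 0; i < n; ++i) {
          double s = d0 * X(i, k);
          dll += s * ysum_r[i] - lsum_r[i] * (std::exp(s) - 1.0);
        }
        dll += (beta[k] * beta[k] - (beta[k] + d0) * (beta[k] + d0)) /
               (2.0 * beta_prior_var);
        ++st_b.tot;
        if (std::log(R::unif_rand()) < dll) {
          beta[k] += d0; ++st_b.acc;
          for (int i = 0; i < n; ++i) {
            double f = std::exp(d0 * X(i, k));
            lsum -= lsum_r[i] * (1.0 - f);
            for (int t = 0; t < T; ++t) {
              lsum_c[t] -= lambda(i, t) * (1.0 - f);
              lambda(i, t) *= f;
            }
            lsum_r[i] *= f;
          }
        }
      }
    }

    if (!prior_only) {
      // ---- deconfounding move: shift beta_k along the u null direction ----
      // proposal beta_k += d, u_i -= d (x_ik - xbar_k), beta0 -= d xbar_k
      // leaves the linear predictor (hence likelihood) unchanged; accepted
      // on the ICAR / Normal prior ratio. Breaks the slow random walk along
      // the spatially-confounded direction.
      for (int k = 0; k < p; ++k) {
        double xbar = 0.0;
        for (int i = 0; i < n; ++i) xbar += X(i, k);
        xbar /= n;
        double d0 = R::norm_rand() * st_bu.s;
        double dq = 0.0;     // change in sum over edges of (u_i - u_j)^2
        for (int i = 0; i < n; ++i) {
          for (int j : adj.nb[i]) {
            if (j <= i) continue;
            double e_old = u[i] - u[j];
            double e_new = e_old - d0 * (X(i, k) - X(j, k));
            dq += e_new * e_new - e_old * e_old;
          }
        }
        double lacc = -dq / (2.0 * s2u);
        double bn = beta[k] + d0, b0n = beta0 - d0 * xbar;
        lacc += (beta[k] * beta[k] - bn * bn) / (2.0 * beta_prior_var);
        lacc += (beta0 * beta0 - b0n * b0n) / (2.0 * beta_prior_var);
        ++st_bu.tot;
        if (std::log(R::unif_rand()) < lacc) {
          ++st_bu.acc;
          beta[k] = bn; beta0 = b0n;
          for (int i = 0; i < n; ++i) u[i] -= d0 * (X(i, k) - xbar);
        }
      }
    }

    // ---- unstructured spatial v ----
    for (int i = 0; i < n; ++i) {
      if (prior_only) { v[i] = R::norm_rand() * std::sqrt(s2v); continue; }
      double d0 = R::norm_rand() * st_v.s;
      double vn = v[i] + d0;
      double dll = d0 * ysum_r[i] - lsum_r[i] * (std::exp(d0) - 1.0);
      dll += (v[i] * v[i] - vn * vn) / (2.0 * s2v);
      ++st_v.tot;
      if (std::log(R::unif_rand()) < dll) {
        v[i] = vn; ++st_v.acc;
        double f = std::exp(d0);
        lsum -= lsum_r[i] * (1.0 - f);
        for (int t = 0; t < T; ++t) {
          lsum_c[t] -= lambda(i, t) * (1.0 - f);
          lambda(i, t) *= f;
        }
        lsum_r[i] *= f;
      }
    }

    // ---- structured spatial u (ICAR conditionals) ----
    for (int i = 0; i < n; ++i) {
      double m = 0.0;
      for (int j : adj.nb[i]) m += u[j];
      m /= adj.n_nb[i];
      double cvar = s2u / adj.n_nb[i];
      if (prior_only) {            // exact Gibbs from the prior conditional
        u[i] = m + R::norm_rand() * std::sqrt(cvar);
        continue;
      }
      double d0 = R::norm_rand() * st_u.s;
      double un = u[i] + d0;
      double dll = d0 * ysum_r[i] - lsum_r[i] * (std::exp(d0) - 1.0);
      dll += ((u[i] - m) * (u[i] - m) - (un - m) * (un - m)) / (2.0 * cvar);
      ++st_u.tot;
      if (std::log(R::unif_rand()) < dll) {
        u[i] = un; ++st_u.acc;
        double f = std::exp(d0);
        lsum -= lsum_r[i] * (1.0 - f);
        for (int t = 0; t < T; ++t) {
          lsum_c[t] -= lambda(i, t) * (1.0 - f);
          lambda(i, t) *= f;
        }
        lsum_r[i] *= f;
      }
    }

    if (has_temporal) {
      // ---- unstructured temporal g ----
      for (int t = 0; t < T; ++t) {
        if (prior_only) { g[t] = R::norm_rand() * std::sqrt(s2g); continue; }
        double d0 = R::norm_rand() * st_g.s;
        double gn = g[t] + d0;
        double dll = d0 * ysum_c[t] - lsum_c[t] * (std::exp(d0) - 1.0);
        dll += (g[t] * g[t] - gn * gn) / (2.0 * s2g);
        ++st_g.tot;
        if (std::log(R::unif_rand()) < dll) {
          g[t] = gn; ++st_g.acc;
          double f = std::exp(d0);
          lsum -= lsum_c[t] * (1.0 - f);
          for (int i = 0; i < n; ++i) {
            lsum_r[i] -= lambda(i, t) * (1.0 - f);
            lambda(i, t) *= f;
          }
          lsum_c[t] *= f;
        }
      }
      // ---- structured temporal ph (RW1 conditionals) ----
      for (int t = 0; t < T; ++t) {
        double dt = (t == 0 || t == T - 1) ? 1.0 : 2.0;
        double m = 0.0;
        if (t > 0) m += ph[t - 1];
        if (t < T - 1) m += ph[t + 1];
        m /= dt;
        double cvar = s2ph / dt;
        if (prior_only) { ph[t] = m + R::norm_rand() * std::sqrt(cvar); continue; }
        double d0 = R::norm_rand() * st_ph.s;
        double pn = ph[t] + d0;
        double dll = d0 * ysum_c[t] - lsum_c[t] * (std::exp(d0) - 1.0);
        dll += ((ph[t] - m) * (ph[t] - m) - (pn - m) * (pn - m)) / (2.0 * cvar);
        ++st_ph.tot;
        if (std::log(R::unif_rand()) < dll) {
          ph[t] = pn; ++st_ph.acc;
          double f = std::exp(d0);
          lsum -= lsum_c[t] * (1.0 - f);
          for (int i = 0; i < n; ++i) {
            lsum_r[i] -= lambda(i, t) * (1.0 - f);
            lambda(i, t) *= f;
          }
          lsum_c[t] *= f;
        }
      }
    }

    if (has_interaction) {
      for (int i = 0; i < n; ++i) {
        for (int t = 0; t < T; ++t) {
          double kd = ks_diag(i) * kt_diag(t);
          double cm = del(i, t) - KdK(i, t) / kd;   // conditional mean
          double cvar = s2d / kd;
          if (prior_only || !mask(i, t)) {
            del(i, t) = cm + R::norm_rand() * std::sqrt(cvar);
            continue;
          }
          double d0 = R::norm_rand() * st_d.s;
          double dn = del(i, t) + d0;
          double dll = d0 * Y(i, t) - lambda(i, t) * (std::exp(d0) - 1.0);
          dll += ((del(i, t) - cm) * (del(i, t) - cm) -
                  (dn - cm) * (dn - cm)) / (2.0 * cvar);
          ++st_d.tot;
          if (std::log(R::unif_rand()) < dll) {
            double f = std::exp(d0);
            del(i, t) = dn; ++st_d.acc;
            lsum -= lambda(i, t) * (1.0 - f);
            lsum_r[i] -= lambda(i, t) * (1.0 - f);
            lsum_c[t] -= lambda(i, t) * (1.0 - f);
            lambda(i, t) *= f;
          }
        }
      }
    }

    // ---- sum-to-zero recentring with compensating shifts ----
    if (sum_to_zero) {
      if (has_interaction) {
        std::vector<double> rm(n, 0.0), cm(T, 0.0);
        double gm = 0.0;
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t) {
            rm[i] += del(i, t); cm[t] += del(i, t); gm += del(i, t);
          }
        for (int i = 0; i < n; ++i) rm[i] /= T;
        for (int t = 0; t < T; ++t) cm[t] /= n;
        gm /= (double)n * T;
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t) del(i, t) -= rm[i] + cm[t] - gm;
        for (int i = 0; i < n; ++i) u[i] += rm[i] - gm;
        for (int t = 0; t < T; ++t) ph[t] += cm[t] - gm;
        beta0 += gm;
      }
      double um = 0.0;
      for (int i = 0; i < n; ++i) um += u[i];
      um /= n;
      for (int i = 0; i < n; ++i) u[i] -= um;
      beta0 += um;
      if (has_temporal) {
        double pm = 0.0;
        for (int t = 0; t < T; ++t) pm += ph[t];
        pm /= T;
        for (int t = 0; t < T; ++t) ph[t] -= pm;
        beta0 += pm;
      }
    }

    // ---- variance parameters ----
    if (!R_finite(fixed_sigma2[0])) {
      double q = 0.0;
      for (int i = 0; i < n; ++i) q += v[i] * v[i];
      s2v = draw_sigma2(q, n, prior_type, prior_shape, prior_rate, prior_upper);
    }
    if (!R_finite(fixed_sigma2[1])) {
      double q = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j : adj.nb[i])
          if (j > i) q += (u[i] - u[j]) * (u[i] - u[j]);
      s2u = draw_sigma2(q, icar_rank, prior_type, prior_shape, prior_rate,
                        prior_upper);
    }
    if (has_temporal) {
      if (!R_finite(fixed_sigma2[2])) {
        double q = 0.0;
        for (int t = 0; t < T; ++t) q += g[t] * g[t];
        s2g = draw_sigma2(q, T, prior_type, prior_shape, prior_rate, prior_upper);
      }
      if (!R_finite(fixed_sigma2[3])) {
        double q = 0.0;
        for (int t = 0; t + 1 < T; ++t)
          q += (ph[t + 1] - ph[t]) * (ph[t + 1] - ph[t]);
        s2ph = draw_sigma2(q, T - 1.0, prior_type, prior_shape, prior_rate,
                           prior_upper);
      }
    }
    if (has_interaction && !R_finite(fixed_sigma2[4])) {
      double q = 0.0;
      for (int i = 0; i < n; ++i)
        for (int t = 0; t < T; ++t) q += del(i, t) * KdK(i, t);
      double rs = space_struct ? icar_rank : (double)n;
      double rt = time_struct ? (T - 1.0) : (double)T;
      if (q < 1e-300) q = 1e-300;
      s2d = draw_sigma2(q, rs * rt, prior_type, prior_shape, prior_rate,
                        prior_upper);
    }

    // ---- adaptation (burn-in only) ----
    if (iter < n_burnin && (iter + 1) % 100 == 0) {
      st_b0.tune(); st_b.tune(); st_v.tune(); st_u.tune();
      st_g.tune(); st_ph.tune(); st_d.tune(); st_bu.tune();
    }

    // ---- storage ----
    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && keep < n_keep) {
      out_b0[keep] = beta0;
      for (int k = 0; k < p; ++k) out_beta(keep, k) = beta[k];
      for (int i = 0; i < n; ++i) { out_v(keep, i) = v[i]; out_u(keep, i) = u[i]; }
      if (has_temporal)
        for (int t = 0; t < T; ++t) { out_g(keep, t) = g[t]; out_ph(keep, t) = ph[t]; }
      if (has_interaction)
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t) out_d(keep, i * T + t) = del(i, t);
      out_s2(keep, 0) = s2v; out_s2(keep, 1) = s2u; out_s2(keep, 2) = s2g;
      out_s2(keep, 3) = s2ph; out_s2(keep, 4) = s2d;
      ++keep;
    }
    if ((iter + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta0"] = out_b0, _["beta"] = out_beta, _["v"] = out_v, _["u"] = out_u,
    _["gamma"] = out_g, _["phi"] = out_ph, _["delta"] = out_d,
    _["sigma2"] = out_s2);
}

// Moran's I permutation reference draws: returns the permuted statistics.
// [[Rcpp::export(name = ".moran_perm")]]
NumericVector moran_perm(NumericVector values, IntegerVector ei,
                         IntegerVector ej, int n_perm) {
  const int n = values.size(), E = ei.size();
  NumericVector out(n_perm);
  RNGScope scope;
  std::vector<double> z(n);
  std::vector<int> idx(n);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    double mu = 0.0;
    for (int i = 0; i < n; ++i) { z[i] = values[idx[i]]; mu += z[i]; }
    mu /= n;
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) { z[i] -= mu; den += z[i] * z[i]; }
    for (int e = 0; e < E; ++e) num += z[ei[e]] * z[ej[e]];
    out[b] = ((double)n / (2.0 * E)) * (2.0 * num) / den;
  }
  return out;
}
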