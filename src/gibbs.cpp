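#include <Rcpp.h>
using namespace Rcpp;

// Standard normal draw conditioned on being > a: naive rejection where the
// acceptance region holds enough mass, Robert's exponential rejection
// otherwise.
static double rtnorm_left(double a) {
  if (a < 0.4) {
    for (;;) {
      double z = norm_rand();
      if (z > a) return z;
    }
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double d = z - alpha;
    if (unif_rand() < std::exp(-0.5 * d * d)) return z;
  }
}

// Inverse-gamma draw for a variance with flat prior on (0, inf):
// posterior IG(shape = n/2 - 1, scale = S/2).
static double rinvgamma_flat(int n, double S) {
  double shape = 0.5 * n - 1.0;
  double g = R::rgamma(shape, 1.0);
  if (g < 1e-300) g = 1e-300;
  return (0.5 * S) / g;
}

// One-cycle Gibbs sampler for the two-level probit SEM.
// Constructs are indexed 0..C-1; with C == 2, construct 1 is regressed on
// construct 0 at both levels (within path beta_w, between path beta_b).
// Within-level item residual variances are fixed at 1 (probit); the
// dichotomization threshold is fixed at 0 with free item intercepts mu
// (between-level thresholds tau = -mu).
// [[Rcpp::export(name = ".gibbs_msem_cpp")]]
List gibbs_msem_cpp(IntegerMatrix y, IntegerVector cluster, int J,
                    IntegerVector item_construct, int n_constructs,
                    bool between, int n_iter,
                    List par, List fixed, LogicalVector constrained,
                    List prior, Nullable<List> state_in) {
  const int N = y.nrow(), I = y.ncol(), C = n_constructs;
  const bool structural = (C == 2);

  NumericVector lam_w = clone(as<NumericVector>(par["lambda_w"]));
  NumericVector lam_b = clone(as<NumericVector>(par["lambda_b"]));
  NumericVector mu    = clone(as<NumericVector>(par["mu"]));
  NumericVector theta = clone(as<NumericVector>(par["theta_b"]));
  NumericVector phi_w = clone(as<NumericVector>(par["phi_w"]));
  NumericVector phi_b = clone(as<NumericVector>(par["phi_b"]));
  double beta_w = as<double>(par["beta_w"]);
  double beta_b = as<double>(par["beta_b"]);

  LogicalVector f_lam_w = fixed["lambda_w"], f_lam_b = fixed["lambda_b"],
                f_mu = fixed["mu"], f_theta = fixed["theta_b"],
                f_phi_w = fixed["phi_w"], f_phi_b = fixed["phi_b"];
  bool f_beta_w = as<bool>(fixed["beta_w"]), f_beta_b = as<bool>(fixed["beta_b"]);

  const double lam_m = as<double>(prior["loading_mean"]);
  const double lam_v = as<double>(prior["loading_var"]);
  const double bw_m  = as<double>(prior["beta_w_mean"]);
  const double bb_m  = as<double>(prior["beta_b_mean"]);
  const double b_v   = as<double>(prior["beta_var"]);

  NumericMatrix ystar(N, I), eta_w(N, C), eta_b(J, C), nu(J, I);
  if (state_in.isNotNull()) {
    List st(state_in);
    ystar = clone(as<NumericMatrix>(st["ystar"]));
    eta_w = clone(as<NumericMatrix>(st["eta_w"]));
    eta_b = clone(as<NumericMatrix>(st["eta_b"]));
    nu    = clone(as<NumericMatrix>(st["nu"]));
  } else {
    for (int i = 0; i < I; ++i)
      for (int c = 0; c < J; ++c) nu(c, i) = mu[i];
    for (int p = 0; p < N; ++p)
      for (int i = 0; i < I; ++i)
        ystar(p, i) = (y(p, i) == 1) ? 0.5 : -0.5;
  }

  std::vector<int> nc(J, 0);
  for (int p = 0; p < N; ++p) nc[cluster[p]]++;

  const int P = 4 * I + 2 * C + 2;
  NumericMatrix draws(n_iter, P);

  for (int it = 0; it < n_iter; ++it) {
    // (a) latent responses
    for (int i = 0; i < I; ++i) {
      const int g = item_construct[i];
      const double lw = lam_w[i];
      for (int p = 0; p < N; ++p) {
        const double m = nu(cluster[p], i) + lw * eta_w(p, g);
        ystar(p, i) = (y(p, i) == 1) ? m + rtnorm_left(-m)
                                     : m - rtnorm_left(m);
      }
    }

    // (b) within factor scores, jointly over constructs
    {
      // prior covariance of (eta0, eta1); for C == 1, scalar phi_w[0]
      double d0 = 0.0, d1 = 0.0; // Lambda'Lambda by construct
      for (int i = 0; i < I; ++i) {
        if (item_construct[i] == 0) d0 += lam_w[i] * lam_w[i];
        else d1 += lam_w[i] * lam_w[i];
      }
      if (!structural) {
        const double prec = 1.0 / phi_w[0] + d0;
        const double pv = 1.0 / prec, ps = std::sqrt(pv);
        for (int p = 0; p < N; ++p) {
          double s = 0.0;
          for (int i = 0; i < I; ++i)
            s += lam_w[i] * (ystar(p, i) - nu(cluster[p], i));
          eta_w(p, 0) = pv * s + ps * norm_rand();
        }
      } else {
        const double p0 = phi_w[0], p1 = phi_w[1], b = beta_w;
        // prior precision of (eta0, eta1)
        const double q00 = 1.0 / p0 + b * b / p1, q01 = -b / p1, q11 = 1.0 / p1;
        const double Q00 = q00 + d0, Q01 = q01, Q11 = q11 + d1;
        const double det = Q00 * Q11 - Q01 * Q01;
        const double a00 = Q11 / det, a01 = -Q01 / det, a11 = Q00 / det;
        const double l00 = std::sqrt(a00), l10 = a01 / l00,
                     l11 = std::sqrt(a11 - l10 * l10);
        for (int p = 0; p < N; ++p) {
          double s0 = 0.0, s1 = 0.0;
          const int cp = cluster[p];
          for (int i = 0; i < I; ++i) {
            const double r = lam_w[i] * (ystar(p, i) - nu(cp, i));
            if (item_construct[i] == 0) s0 += r; else s1 += r;
          }
          const double m0 = a00 * s0 + a01 * s1, m1 = a01 * s0 + a11 * s1;
          const double z0 = norm_rand(), z1 = norm_rand();
          eta_w(p, 0) = m0 + l00 * z0;
          eta_w(p, 1) = m1 + l10 * z0 + l11 * z1;
        }
      }
    }

    if (between) {
      // (c) cluster-item random intercepts
      for (int i = 0; i < I; ++i) {
        const int g = item_construct[i];
        const double lw = lam_w[i], lb = lam_b[i], th = theta[i];
        std::vector<double> sum(J, 0.0);
        for (int p = 0; p < N; ++p)
          sum[cluster[p]] += ystar(p, i) - lw * eta_w(p, g);
        for (int c = 0; c < J; ++c) {
          const double prec = nc[c] + 1.0 / th;
          const double pm = (sum[c] + (mu[i] + lb * eta_b(c, g)) / th) / prec;
          nu(c, i) = pm + norm_rand() / std::sqrt(prec);
        }
      }

      // (d) between factor scores
      {
        double d0 = 0.0, d1 = 0.0;
        for (int i = 0; i < I; ++i) {
          const double w = lam_b[i] * lam_b[i] / theta[i];
          if (item_construct[i] == 0) d0 += w; else d1 += w;
        }
        if (!structural) {
          const double prec = 1.0 / phi_b[0] + d0;
          const double pv = 1.0 / prec, ps = std::sqrt(pv);
          for (int c = 0; c < J; ++c) {
            double s = 0.0;
            for (int i = 0; i < I; ++i)
              s += lam_b[i] * (nu(c, i) - mu[i]) / theta[i];
            eta_b(c, 0) = pv * s + ps * norm_rand();
          }
        } else {
          const double p0 = phi_b[0], p1 = phi_b[1], b = beta_b;
          const double q00 = 1.0 / p0 + b * b / p1, q01 = -b / p1,
                       q11 = 1.0 / p1;
          const double Q00 = q00 + d0, Q01 = q01, Q11 = q11 + d1;
          const double det = Q00 * Q11 - Q01 * Q01;
          const double a00 = Q11 / det, a01 = -Q01 / det, a11 = Q00 / det;
          const double l00 = std::sqrt(a00), l10 = a01 / l00,
                       l11 = std::sqrt(a11 - l10 * l10);
          for (int c = 0; c < J; ++c) {
            double s0 = 0.0, s1 = 0.0;
            for (int i = 0; i < I; ++i) {
              const double r = lam_b[i] * (nu(c, i) - mu[i]) / theta[i];
              if (item_construct[i] == 0) s0 += r; else s1 += r;
            }
            const double m0 = a00 * s0 + a01 * s1, m1 = a01 * s0 + a11 * s1;
            const double z0 = norm_rand(), z1 = norm_rand();
            eta_b(c, 0) = m0 + l00 * z0;
            eta_b(c, 1) = m1 + l10 * z0 + l11 * z1;
          }
        }
      }

      // (e) item intercepts (between thresholds tau = -mu), flat prior
      for (int i = 0; i < I; ++i) {
        if (f_mu[i]) continue;
        const int g = item_construct[i];
        double s = 0.0;
        for (int c = 0; c < J; ++c) s += nu(c, i) - lam_b[i] * eta_b(c, g);
        mu[i] = s / J + norm_rand() * std::sqrt(theta[i] / J);
      }
    } else {
      // no between component: nu is the intercept row, updated from all N obs
      for (int i = 0; i < I; ++i) {
        if (!f_mu[i]) {
          const int g = item_construct[i];
          double s = 0.0;
          for (int p = 0; p < N; ++p) s += ystar(p, i) - lam_w[i] * eta_w(p, g);
          mu[i] = s / N + norm_rand() / std::sqrt((double) N);
        }
        for (int c = 0; c < J; ++c) nu(c, i) = mu[i];
      }
    }

    // (f) loadings
    for (int i = 0; i < I; ++i) {
      const int g = item_construct[i];
      const bool con = constrained[i] && between;
      double sxx_w = 0.0, sxy_w = 0.0;
      if (!f_lam_w[i] || con) {
        for (int p = 0; p < N; ++p) {
          const double x = eta_w(p, g);
          sxx_w += x * x;
          sxy_w += x * (ystar(p, i) - nu(cluster[p], i));
        }
      }
      double sxx_b = 0.0, sxy_b = 0.0;
      if (between && (!f_lam_b[i] || con)) {
        for (int c = 0; c < J; ++c) {
          const double x = eta_b(c, g);
          sxx_b += x * x;
          sxy_b += x * (nu(c, i) - mu[i]);
        }
        sxx_b /= theta[i];
        sxy_b /= theta[i];
      }
      if (con) {
        const double prec = 1.0 / lam_v + sxx_w + sxx_b;
        const double pm = (lam_m / lam_v + sxy_w + sxy_b) / prec;
        const double d = pm + norm_rand() / std::sqrt(prec);
        lam_w[i] = d;
        lam_b[i] = d;
      } else {
        if (!f_lam_w[i]) {
          const double prec = 1.0 / lam_v + sxx_w;
          lam_w[i] = (lam_m / lam_v + sxy_w) / prec +
                     norm_rand() / std::sqrt(prec);
        }
        if (between && !f_lam_b[i]) {
          const double prec = 1.0 / lam_v + sxx_b;
          lam_b[i] = (lam_m / lam_v + sxy_b) / prec +
                     norm_rand() / std::sqrt(prec);
        }
      }
    }

    // (g) between indicator residual variances
    if (between) {
      for (int i = 0; i < I; ++i) {
        if (f_theta[i]) continue;
        const int g = item_construct[i];
        double S = 0.0;
        for (int c = 0; c < J; ++c) {
          const double r = nu(c, i) - mu[i] - lam_b[i] * eta_b(c, g);
          S += r * r;
        }
        theta[i] = rinvgamma_flat(J, S);
      }
    }

    // (h) factor / residual variances
    if (!f_phi_w[0]) {
      double S = 0.0;
      for (int p = 0; p < N; ++p) S += eta_w(p, 0) * eta_w(p, 0);
      phi_w[0] = rinvgamma_flat(N, S);
    }
    if (structural && !f_phi_w[1]) {
      double S = 0.0;
      for (int p = 0; p < N; ++p) {
        const double r = eta_w(p, 1) - beta_w * eta_w(p, 0);
        S += r * r;
      }
      phi_w[1] = rinvgamma_flat(N, S);
    }
    if (between) {
      if (!f_phi_b[0]) {
        double S = 0.0;
        for (int c = 0; c < J; ++c) S += eta_b(c, 0) * eta_b(c, 0);
        phi_b[0] = rinvgamma_flat(J, S);
      }
      if (structural && !f_phi_b[1]) {
        double S = 0.0;
        for (int c = 0; c < J; ++c) {
          const double r = eta_b(c, 1) - beta_b * eta_b(c, 0);
          S += r * r;
        }
        phi_b[1] = rinvgamma_flat(J, S);
      }
    }

    // (i) structural paths
    if (structural) {
      if (!f_beta_w) {
        double sxx = 0.0, sxy = 0.0;
        for (int p = 0; p < N; ++p) {
          sxx += eta_w(p, 0) * eta_w(p, 0);
          sxy += eta_w(p, 0) * eta_w(p, 1);
        }
        const double prec = 1.0 / b_v + sxx / phi_w[1];
        beta_w = (bw_m / b_v + sxy / phi_w[1]) / prec +
                 norm_rand() / std::sqrt(prec);
      }
      if (between && !f_beta_b) {
        double sxx = 0.0, sxy = 0.0;
        for (int c = 0; c < J; ++c) {
          sxx += eta_b(c, 0) * eta_b(c, 0);
          sxy += eta_b(c, 0) * eta_b(c, 1);
        }
        const double prec = 1.0 / b_v + sxx / phi_b[1];
        beta_b = (bb_m / b_v + sxy / phi_b[1]) / prec +
                 norm_rand() / std::sqrt(prec);
      }
    }

    // store
    int k = 0;
    for (int i = 0; i < I; ++i) draws(it, k++) = lam_w[i];
    for (int i = 0; i < I; ++i) draws(it, k++) = lam_b[i];
    for (int i = 0; i < I; ++i) draws(it, k++) = -mu[i]; // tau
    for (int i = 0; i < I; ++i) draws(it, k++) = theta[i];
    for (int c = 0; c < C; ++c) draws(it, k++) = phi_w[c];
    for (int c = 0; c < C; ++c) draws(it, k++) = phi_b[c];
    draws(it, k++) = beta_w;
    draws(it, k++) = beta_b;
  }

  List par_out = List::create(
    _["lambda_w"] = lam_w, _["lambda_b"] = lam_b, _["mu"] = mu,
    _["theta_b"] = theta, _["phi_w"] = phi_w, _["phi_b"] = phi_b,
    _["beta_w"] = beta_w, _["beta_b"] = beta_b);
  List state_out = List::create(
    _["ystar"] = ystar, _["eta_w"] = eta_w, _["eta_b"] = eta_b,
    _["nu"] = nu);
  return List::create(_["draws"] = draws, _["par"] = par_out,
                      _["state"] = state_out);
}
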