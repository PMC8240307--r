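// Spike-and-slab variable selection across many parallel regressions with a
// multiplicative gene-by-locus inclusion prior, pi_kj = min(pi_k * rho_j, 1).
// Per gene: a g-prior linear model over SDP genotypes with effects and error
// variance marginalized, so indicator updates only need the model R^2.
// The sampler alternates (i) Gibbs toggles of the indicators by conditional
// Bayes factors, (ii) conjugate-style Beta updates of pi_k from indicator
// counts, (iii) random-walk Metropolis updates of log rho_j.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quadratic form Q = b_S' (A_S)^{-1} b_S for a small index set S, via
// Cholesky on a copy with a tiny ridge; returns -1 on numerical failure.
static double quad_form(const std::vector<int>& S,
                        const NumericMatrix& XtX,
                        const double* bty) {
  const int m = S.size();
  if (m == 0) return 0.0;
  if (m == 1) {
    double a = XtX(S[0], S[0]);
    if (a <= 0) return -1.0;
    double b = bty[S[0]];
    return b * b / a;
  }
  std::vector<double> A(m * m), b(m);
  for (int i = 0; i < m; ++i) {
    b[i] = bty[S[i]];
    for (int j = 0; j <= i; ++j) {
      A[i * m + j] = XtX(S[i], S[j]);
    }
    A[i * m + i] += 1e-9 * (XtX(S[i], S[i]) + 1.0);
  }
  // Cholesky A = L L'
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * m + j];
      for (int t = 0; t < j; ++t) s -= A[i * m + t] * A[j * m + t];
      if (i == j) {
        if (s <= 0) return -1.0;
        A[i * m + i] = std::sqrt(s);
      } else {
        A[i * m + j] = s / A[j * m + j];
      }
    }
  }
  // forward solve L z = b
  double q = 0.0;
  std::vector<double> z(m);
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int t = 0; t < i; ++t) s -= A[i * m + t] * z[t];
    z[i] = s / A[i * m + i];
    q += z[i] * z[i];
  }
  return q;
}

// log marginal likelihood (up to a constant shared across models) of a
// g-prior model with R^2 = Q / yty on n samples:
//   -(|S|/2) log(1+g) - ((n-1)/2) log(1 - c R^2),  c = g/(1+g)
static inline double log_ml(int msize, double R2, double log1pg, double c,
                            double nm1_half) {
  double u = 1.0 - c * R2;
  if (u < 1e-12) u = 1e-12;
  return -0.5 * msize * log1pg - nm1_half * std::log(u);
}

static inline double log1m_q(double q) {
  // log(1 - q) with a cheap series for tiny q (dominant case)
  if (q < 1e-3) return -q - 0.5 * q * q - q * q * q / 3.0;
  return std::log1p(-q);
}

// [[Rcpp::export]]
List multiplicative_ss_sampler(NumericMatrix Y,      // n x G, columns centered/scaled
                  NumericMatrix X,      // n x S, columns centered
                  double a, double b,   // Beta hyperparameters of pi_k
                  double rho_shape, double rho_rate,
                  double g,             // g-prior constant
                  int iters, int burnin,
                  double rw_sd) {
  const int n = Y.nrow(), G = Y.ncol(), S = X.ncol();
  const double log1pg = std::log1p(g);
  const double c = g / (1.0 + g);
  const double nm1_half = 0.5 * (n - 1);
  const double QMAX = 1.0 - 1e-9;

  // Gram matrices
  NumericMatrix XtX(S, S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0;
      for (int t = 0; t < n; ++t) s += X(t, i) * X(t, j);
      XtX(i, j) = s; XtX(j, i) = s;
    }
  std::vector<double> XtY(static_cast<size_t>(S) * G);
  std::vector<double> yty(G);
  std::vector<double> lml1(static_cast<size_t>(S) * G);  // single-predictor
  for (int k = 0; k < G; ++k) {
    double s2 = 0;
    for (int t = 0; t < n; ++t) s2 += Y(t, k) * Y(t, k);
    yty[k] = (s2 > 0) ? s2 : 1.0;
    for (int j = 0; j < S; ++j) {
      double s = 0;
      for (int t = 0; t < n; ++t) s += X(t, j) * Y(t, k);
      size_t idx = static_cast<size_t>(k) * S + j;
      XtY[idx] = s;
      double ajj = XtX(j, j);
      double r2 = (ajj > 0) ? s * s / (ajj * yty[k]) : 0.0;
      lml1[idx] = log_ml(1, r2, log1pg, c, nm1_half);
    }
  }

  // state (log priors cached so the hot toggle path avoids log calls)
  std::vector<std::vector<int> > model(G);
  std::vector<double> curQ(G, 0.0);
  std::vector<double> pi_k(G, a / (a + b));
  std::vector<double> lpi_k(G, std::log(a / (a + b)));
  std::vector<double> rho(S, 1.0);
  std::vector<double> lrho(S, 0.0);
  std::vector<double> ppi(static_cast<size_t>(G) * S, 0.0);
  std::vector<double> ppi_h1(static_cast<size_t>(G) * S, 0.0);
  std::vector<int> order(S);
  for (int j = 0; j < S; ++j) order[j] = j;
  int kept = 0, kept_h1 = 0;
  long mh_acc = 0, mh_try = 0;
  const int half_point = burnin + (iters - burnin) / 2;

  for (int it = 0; it < iters; ++it) {
    // shuffle predictor order (shared across genes this iteration)
    for (int j = S - 1; j > 0; --j) {
      int u = static_cast<int>(R::unif_rand() * (j + 1));
      if (u > j) u = j;
      std::swap(order[j], order[u]);
    }

    for (int k = 0; k < G; ++k) {
      std::vector<int>& mk = model[k];
      const double* bty = &XtY[static_cast<size_t>(k) * S];
      const double* lml1_k = &lml1[static_cast<size_t>(k) * S];
      for (int oi = 0; oi < S; ++oi) {
        const int j = order[oi];
        bool inc = false;
        int pos = -1;
        for (size_t t = 0; t < mk.size(); ++t)
          if (mk[t] == j) { inc = true; pos = t; break; }

        double d;  // log posterior odds of inclusion
        double q_with = 0.0, q_without = 0.0;
        double prior_q = pi_k[k] * rho[j];
        double lq;
        if (prior_q > QMAX) { prior_q = QMAX; lq = std::log(prior_q); }
        else if (prior_q < 1e-12) { prior_q = 1e-12; lq = std::log(prior_q); }
        else lq = lpi_k[k] + lrho[j];
        const double l1mq = log1m_q(prior_q);

        if (mk.empty() || (inc && mk.size() == 1)) {
          // empty <-> single-predictor toggle: precomputed marginal
          double ajj = XtX(j, j);
          q_with = (ajj > 0) ? bty[j] * bty[j] / ajj : 0.0;
          q_without = 0.0;
          d = lml1_k[j] + lq - l1mq;
        } else {
          int m_without;
          if (inc) {
            q_with = curQ[k];
            std::vector<int> Sm(mk);
            Sm.erase(Sm.begin() + pos);
            q_without = quad_form(Sm, XtX, bty);
            m_without = Sm.size();
            if (q_without < 0) continue;  // keep state on numerical failure
          } else {
            q_without = curQ[k];
            m_without = mk.size();
            std::vector<int> Sp(mk);
            Sp.push_back(j);
            q_with = quad_form(Sp, XtX, bty);
            if (q_with < 0) continue;  // collinear addition: skip
          }
          d = log_ml(m_without + 1, q_with / yty[k], log1pg, c, nm1_half) -
              log_ml(m_without, q_without / yty[k], log1pg, c, nm1_half) +
              lq - l1mq;
        }
        bool new_inc;
        if (d > 35.0) new_inc = true;
        else if (d < -35.0) new_inc = false;
        else new_inc = (R::unif_rand() * (1.0 + std::exp(-d)) < 1.0);
        if (new_inc != inc) {
          if (new_inc) {
            mk.push_back(j);
            curQ[k] = q_with;
          } else {
            mk.erase(mk.begin() + pos);
            curQ[k] = q_without;
          }
        }
      }
      // (ii) pi_k | gamma  ~ Beta(a + m, b + S - m)  (indicator-count update)
      pi_k[k] = R::rbeta(a + mk.size(), b + S - mk.size());
      if (pi_k[k] < 1e-8) pi_k[k] = 1e-8;
      lpi_k[k] = std::log(pi_k[k]);
    }

    // (iii) rho_j by random-walk Metropolis on log rho
    for (int j = 0; j < S; ++j) {
      double lr = std::log(rho[j]);
      double lr_new = lr + R::norm_rand() * rw_sd;
      double r_new = std::exp(lr_new);
      // log posterior (Gamma prior with log-scale Jacobian) difference
      double d = rho_shape * (lr_new - lr) - rho_rate * (r_new - rho[j]);
      for (int k = 0; k < G; ++k) {
        double q_old = pi_k[k] * rho[j];
        double q_new = pi_k[k] * r_new;
        if (q_old > QMAX) q_old = QMAX;
        if (q_new > QMAX) q_new = QMAX;
        bool inc = false;
        const std::vector<int>& mk = model[k];
        for (size_t t = 0; t < mk.size(); ++t)
          if (mk[t] == j) { inc = true; break; }
        if (inc) d += std::log(q_new) - std::log(q_old);
        else d += log1m_q(q_new) - log1m_q(q_old);
      }
      ++mh_try;
      if (std::log(R::unif_rand()) < d) {
        rho[j] = r_new;
        lrho[j] = lr_new;
        ++mh_acc;
      }
    }

    if (it >= burnin) {
      ++kept;
      bool first_half = it < half_point;
      if (first_half) ++kept_h1;
      for (int k = 0; k < G; ++k) {
        for (size_t t = 0; t < model[k].size(); ++t) {
          size_t idx = static_cast<size_t>(k) * S + model[k][t];
          ppi[idx] += 1.0;
          if (first_half) ppi_h1[idx] += 1.0;
        }
      }
    }
  }

  NumericMatrix gamma_hat(G, S), gamma_h1(G, S), gamma_h2(G, S);
  const int kept_h2 = kept - kept_h1;
  for (int k = 0; k < G; ++k)
    for (int j = 0; j < S; ++j) {
      size_t idx = static_cast<size_t>(k) * S + j;
      gamma_hat(k, j) = ppi[idx] / std::max(kept, 1);
      gamma_h1(k, j) = ppi_h1[idx] / std::max(kept_h1, 1);
      gamma_h2(k, j) = (ppi[idx] - ppi_h1[idx]) / std::max(kept_h2, 1);
    }

  return List::create(
    _["gamma_hat"] = gamma_hat,
    _["gamma_half1"] = gamma_h1,
    _["gamma_half2"] = gamma_h2,
    _["pi_k"] = NumericVector(pi_k.begin(), pi_k.end()),
    _["rho_j"] = NumericVector(rho.begin(), rho.end()),
    _["mh_accept"] = mh_try ? static_cast<double>(mh_acc) / mh_try : NA_REAL);
}
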