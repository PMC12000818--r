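// MCMC engine for the dimension-grouped mixed membership model.
//
// All randomness goes through R's RNG (R::rgamma, unif_rand, ...) so that a
// single set.seed() in R makes every routine here bit-reproducible.
//
// Index conventions: categories, profiles and groups are 0-based throughout
// this file; the R wrappers translate to the 1-based user-facing coding.
// lambda is stored as a (dmax x K x p) cube; for item j only the first d[j]
// rows of slice j are meaningful, the rest stay 0.
//
// Numerical care: membership rows are drawn in log space (log-gamma draws
// via the Gamma(a + 1) * U^(1/a) boost), so sum_i log pi_{i,k} stays finite
// even when alpha_k is far below the probability-scale underflow threshold.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double ALPHA_MIN = 1e-290;  // keep alpha away from exact zero

// log of a Gamma(a, 1) draw, stable for small shapes.
static double rloggamma(double a) {
  if (a < 1.0) {
    double g;
    do { g = R::rgamma(a + 1.0, 1.0); } while (g <= 0.0);
    double u;
    do { u = unif_rand(); } while (u <= 0.0);
    return std::log(g) + std::log(u) / a;
  }
  double g;
  do { g = R::rgamma(a, 1.0); } while (g <= 0.0);
  return std::log(g);
}

// Dirichlet draw via normalized gammas (shapes >= 1 in all call sites).
static void rdirich(const arma::vec& a, double* out) {
  const int K = a.n_elem;
  double s = 0.0;
  for (int k = 0; k < K; ++k) { out[k] = R::rgamma(a[k], 1.0); s += out[k]; }
  if (!(s > 0.0) || !std::isfinite(s)) {
    for (int k = 0; k < K; ++k) out[k] = 0.0;
    out[a.index_max()] = 1.0;
    return;
  }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

static arma::vec rdirich_vec(const arma::vec& a) {
  arma::vec out(a.n_elem);
  rdirich(a, out.memptr());
  return out;
}

// log-space Dirichlet draw: fills logp with log of a Dirichlet(a) draw.
static void rdirich_log(const double* a, int K, double* logp) {
  double m = NEG_INF;
  for (int k = 0; k < K; ++k) {
    logp[k] = rloggamma(a[k]);
    if (logp[k] > m) m = logp[k];
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(logp[k] - m);
  const double lse = m + std::log(s);
  for (int k = 0; k < K; ++k) logp[k] -= lse;
}

// Sample a 0-based index from unnormalized log-weights.
static int rcat_log(const double* lw, int K) {
  double m = NEG_INF;
  for (int k = 0; k < K; ++k) if (lw[k] > m) m = lw[k];
  if (m == NEG_INF)
    stop("all categorical log-weights are -Inf (zero-probability state)");
  double tot = 0.0;
  double w[64];
  std::vector<double> wbig;
  double* wp = w;
  if (K > 64) { wbig.resize(K); wp = wbig.data(); }
  for (int k = 0; k < K; ++k) { wp[k] = std::exp(lw[k] - m); tot += wp[k]; }
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) { c += wp[k]; if (u <= c) return k; }
  return K - 1;
}

static int rcat_prob(const double* p, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += p[k];
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) { c += p[k]; if (u <= c) return k; }
  return K - 1;
}

// ---------------------------------------------------------------- updates --

// Step 1: conditional probability table columns, Dirichlet(1 + counts).
// Fills both lambda and its elementwise log.
static void upd_lambda(const arma::imat& y, const arma::ivec& d,
                       const arma::ivec& s, const arma::imat& Z, int K,
                       arma::cube& lam, arma::cube& llam) {
  const int n = y.n_rows, p = y.n_cols;
  for (int j = 0; j < p; ++j) {
    const int dj = (int)d[j], g = (int)s[j];
    arma::mat cnt(dj, K, arma::fill::ones);  // prior Dirichlet(1,...,1)
    const arma::sword* yj = y.colptr(j);
    const arma::sword* zg = Z.colptr(g);
    for (int i = 0; i < n; ++i) cnt((int)yj[i], (int)zg[i]) += 1.0;
    for (int k = 0; k < K; ++k) {
      arma::vec col(dj);
      rdirich(cnt.col(k), col.memptr());
      for (int c = 0; c < dj; ++c) {
        lam(c, k, j) = col[c];
        llam(c, k, j) = col[c] > 0.0 ? std::log(col[c]) : NEG_INF;
      }
    }
  }
}

// Step 2: membership rows, Dirichlet(alpha + assignment counts), drawn in
// log space.  Fills Pi, logPi and the column sums Slog[k] = sum_i log pi_ik.
static void upd_pi(const arma::imat& Z, const arma::vec& alpha,
                   arma::mat& Pi, arma::mat& logPi, arma::vec& Slog) {
  const int n = Z.n_rows, G = Z.n_cols, K = alpha.n_elem;
  Slog.zeros();
  std::vector<double> shape(K), lp(K);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) shape[k] = alpha[k];
    for (int g = 0; g < G; ++g) shape[(int)Z(i, g)] += 1.0;
    rdirich_log(shape.data(), K, lp.data());
    for (int k = 0; k < K; ++k) {
      logPi(i, k) = lp[k];
      Pi(i, k) = std::exp(lp[k]);
      Slog[k] += lp[k];
    }
  }
}

// Per-group log-likelihood accumulator A(i,k,g) = sum_{j: s_j=g} log
// lambda_j(y_ij, k).  Depends on (y, s, lambda) only.
static void group_loglik(const arma::imat& y, const arma::ivec& s,
                         const arma::cube& llam, arma::cube& A) {
  const int n = y.n_rows, p = y.n_cols, K = A.n_cols;
  A.zeros();
  for (int j = 0; j < p; ++j) {
    const int g = (int)s[j];
    const arma::sword* yj = y.colptr(j);
    const arma::mat& lj = llam.slice(j);
    arma::mat& Ag = A.slice(g);
    for (int k = 0; k < K; ++k) {
      const double* lcol = lj.colptr(k);
      double* acol = Ag.colptr(k);
      for (int i = 0; i < n; ++i) acol[i] += lcol[(int)yj[i]];
    }
  }
}

// Step 3: latent assignments, categorical in log space.
static void upd_z(arma::imat& Z, const arma::cube& A,
                  const arma::mat& logPi) {
  const int n = Z.n_rows, G = Z.n_cols, K = logPi.n_cols;
  std::vector<double> lw(K);
  for (int g = 0; g < G; ++g) {
    const arma::mat& Ag = A.slice(g);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) lw[k] = logPi(i, k) + Ag(i, k);
      Z(i, g) = rcat_log(lw.data(), K);
    }
  }
}

// Step 4: item grouping s, then group weights xi.
static void upd_s(arma::ivec& s, arma::vec& xi, const arma::imat& y,
                  const arma::cube& llam, const arma::imat& Z, int G) {
  const int n = y.n_rows, p = y.n_cols;
  const int dmax = llam.n_rows;
  std::vector<double> lw(G), logxi(G);
  for (int g = 0; g < G; ++g)
    logxi[g] = xi[g] > 0.0 ? std::log(xi[g]) : NEG_INF;
  for (int j = 0; j < p; ++j) {
    const double* lj = llam.slice(j).memptr();  // (c, k) at c + k * dmax
    const arma::sword* yj = y.colptr(j);
    for (int g = 0; g < G; ++g) {
      const arma::sword* zg = Z.colptr(g);
      double acc = 0.0;
      for (int i = 0; i < n; ++i)
        acc += lj[(int)yj[i] + (int)zg[i] * dmax];
      lw[g] = logxi[g] + acc;
    }
    s[j] = rcat_log(lw.data(), G);
  }
  arma::vec cnt(G, arma::fill::ones);  // uniform Dirichlet prior
  for (int j = 0; j < p; ++j) cnt[(int)s[j]] += 1.0;
  rdirich(cnt, xi.memptr());
}

// Step 4, partially collapsed variant: sample each s_j from its full
// conditional with the latent assignments z integrated out,
//   P(s_j = g | s_-j, Lambda, Pi, xi, y)
//     \propto xi_g * prod_i m_i(B_g + {j}) / m_i(B_g),
// where B_g is group g's item set without j and
// m_i(S) = sum_k pi_ik prod_{j' in S} lambda_{j'}(y_ij', k) is the per-
// subject group-block mixture likelihood.  The caller must redraw z from
// its conditional before anything else conditions on z (partially
// collapsed Gibbs); the sweep does exactly that.
//
// Implementation: cache, per group, the stabilized unnormalized posterior
// weights U(i,k,g) = exp(logPi + A_g - m_ig) and their sums base(i,g); the
// "add item j" mixture is then a K-term dot product with lambda_j, and the
// "remove item j" one divides the weights by lambda_j.  Products over
// subjects are accumulated in chunks to avoid underflow.
// `temper` scales the data term of the grouping weights (1 = exact full
// conditional); values below 1 are used only during an annealed burn-in
// ramp to let the grouping explore before the likelihood barriers lock in.
static void upd_s_collapsed(arma::ivec& s, arma::vec& xi, const arma::imat& y,
                            const arma::cube& lambda, const arma::cube& llam,
                            const arma::mat& logPi, int G,
                            double temper = 1.0) {
  const int n = y.n_rows, p = y.n_cols, K = logPi.n_cols;
  arma::cube A(n, K, G);
  group_loglik(y, s, llam, A);
  // caches in K-major layout so the per-subject inner products are
  // contiguous: U(k, i, g) = exp(logPi + A_g - m_ig), base(i, g) = sum_k U
  arma::cube U(K, n, G);
  arma::mat base(n, G);
  arma::mat tlogPi(K, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) tlogPi(k, i) = logPi(i, k);

  auto refresh = [&](int g) {
    const arma::mat& Ag = A.slice(g);
    arma::mat& Ug = U.slice(g);
    for (int i = 0; i < n; ++i) {
      double m = NEG_INF;
      for (int k = 0; k < K; ++k) {
        const double v = tlogPi(k, i) + Ag(i, k);
        if (v > m) m = v;
      }
      double b = 0.0;
      double* ucol = Ug.colptr(i);
      for (int k = 0; k < K; ++k) {
        ucol[k] = std::exp(tlogPi(k, i) + Ag(i, k) - m);
        b += ucol[k];
      }
      base(i, g) = b;
    }
  };
  for (int g = 0; g < G; ++g) refresh(g);

  std::vector<double> lw(G), logxi(G), lamrow(K);
  for (int g = 0; g < G; ++g)
    logxi[g] = xi[g] > 0.0 ? std::log(xi[g]) : NEG_INF;

  for (int j = 0; j < p; ++j) {
    const int g0 = (int)s[j];
    const arma::sword* yj = y.colptr(j);
    const arma::mat& lamj = lambda.slice(j);
    const int dj = lamj.n_rows;
    for (int g = 0; g < G; ++g) {
      const double* Ug = U.slice(g).memptr();
      const double* bg = base.colptr(g);
      double t = 0.0, num = 1.0, den = 1.0;
      if (g == g0) {
        // ratio m_i(A_g0) / m_i(A_g0 - item j)
        for (int i = 0; i < n; ++i) {
          const double* u = Ug + (size_t)i * K;
          const double* lr = lamj.memptr() + (int)yj[i];  // stride dj over k
          double denom = 0.0;
          for (int k = 0; k < K; ++k) denom += u[k] / lr[k * dj];
          num *= bg[i];
          den *= denom;
          if (num < 1e-280 || num > 1e280 || den < 1e-280 || den > 1e280) {
            t += std::log(num) - std::log(den);
            num = den = 1.0;
          }
        }
      } else {
        // ratio m_i(A_g + item j) / m_i(A_g)
        for (int i = 0; i < n; ++i) {
          const double* u = Ug + (size_t)i * K;
          const double* lr = lamj.memptr() + (int)yj[i];
          double plus = 0.0;
          for (int k = 0; k < K; ++k) plus += u[k] * lr[k * dj];
          num *= plus;
          den *= bg[i];
          if (num < 1e-280 || num > 1e280 || den < 1e-280 || den > 1e280) {
            t += std::log(num) - std::log(den);
            num = den = 1.0;
          }
        }
      }
      t += std::log(num) - std::log(den);
      lw[g] = logxi[g] + temper * t;
    }
    const int g2 = rcat_log(lw.data(), G);
    if (g2 != g0) {
      s[j] = g2;
      arma::mat& A0 = A.slice(g0);
      arma::mat& A2 = A.slice(g2);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) {
          const double b = llam((int)yj[i], k, j);
          A0(i, k) -= b;
          A2(i, k) += b;
        }
      refresh(g0);
      refresh(g2);
    }
  }
  arma::vec cnt(G, arma::fill::ones);  // uniform Dirichlet prior
  for (int j = 0; j < p; ++j) cnt[(int)s[j]] += 1.0;
  rdirich(cnt, xi.memptr());
}

// Step 5: Metropolis-Hastings update of alpha with lognormal proposals.
// Slog[k] = sum_i log pi_{i,k}.  Returns acceptance; logr_out gets log r*.
static bool upd_alpha_mh(arma::vec& alpha, const arma::vec& Slog, int n,
                         double sigma, double aA, double bA,
                         double* logr_out) {
  const int K = alpha.n_elem;
  arma::vec prop(K);
  for (int k = 0; k < K; ++k) {
    prop[k] = std::exp(R::rnorm(std::log(alpha[k]), sigma));
    if (prop[k] < ALPHA_MIN) prop[k] = ALPHA_MIN;
  }
  const double a0 = arma::accu(alpha), a0s = arma::accu(prop);
  // Prior on alpha: alpha_0 ~ Gamma(aA, bA), eta = alpha/alpha_0 uniform on
  // the simplex.  As a density in alpha this carries the change-of-variables
  // Jacobian alpha_0^-(K-1), hence the (aA - K) exponent below.
  double logr = (aA - (double)K) * (std::log(a0s) - std::log(a0)) -
                bA * (a0s - a0);
  double lg = R::lgammafn(a0s) - R::lgammafn(a0);
  for (int k = 0; k < K; ++k)
    lg += R::lgammafn(alpha[k]) - R::lgammafn(prop[k]);
  logr += (double)n * lg;
  for (int k = 0; k < K; ++k)
    logr += (prop[k] - alpha[k]) * Slog[k] +
            std::log(prop[k]) - std::log(alpha[k]);
  if (logr_out) *logr_out = logr;
  if (std::isnan(logr)) return false;  // degenerate state: reject
  const bool acc = std::log(unif_rand()) < logr;  // r = min(1, r*)
  if (acc) alpha = prop;
  return acc;
}

// Chinese Restaurant Table draw: number of tables after m customers at
// concentration r, as a sum of independent Bernoulli(r/(r+l-1)).
static int rcrt(int m, double r) {
  int t = 0;
  for (int l = 1; l <= m; ++l)
    if (unif_rand() < r / (r + (double)(l - 1))) ++t;
  return t;
}

// Step 5*: fully Gibbs alpha update via Beta/CRT augmentation.
static void upd_alpha_gibbs(arma::vec& alpha, const arma::imat& Z,
                            double a0p, double b0p) {
  const int n = Z.n_rows, G = Z.n_cols, K = alpha.n_elem;
  arma::imat Zm(n, K, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < G; ++g) Zm(i, Z(i, g)) += 1;
  const double al0 = arma::accu(alpha);
  double sumlog = 0.0;  // sum_i log(1 - q_i) < 0
  for (int i = 0; i < n; ++i) {
    double q = R::rbeta((double)G, al0);
    if (q > 1.0 - 1e-12) q = 1.0 - 1e-12;
    sumlog += std::log1p(-q);
  }
  const double rate = b0p - sumlog;
  for (int k = 0; k < K; ++k) {
    int tk = 0;
    for (int i = 0; i < n; ++i) tk += rcrt(Zm(i, k), alpha[k]);
    double a = R::rgamma(a0p + (double)tk, 1.0 / rate);
    alpha[k] = (a > ALPHA_MIN) ? a : ALPHA_MIN;
  }
}

// log p(y_i | theta) = sum_g log sum_k pi_{i,k} exp(A(i,k,g)), stabilized.
static void pointwise_loglik(const arma::cube& A, const arma::mat& logPi,
                             double* out) {
  const int n = logPi.n_rows, K = logPi.n_cols, G = A.n_slices;
  for (int i = 0; i < n; ++i) out[i] = 0.0;
  for (int g = 0; g < G; ++g) {
    const arma::mat& Ag = A.slice(g);
    for (int i = 0; i < n; ++i) {
      double m = NEG_INF;
      for (int k = 0; k < K; ++k) {
        const double v = logPi(i, k) + Ag(i, k);
        if (v > m) m = v;
      }
      if (m == NEG_INF) { out[i] = NEG_INF; continue; }
      double sum = 0.0;
      for (int k = 0; k < K; ++k)
        sum += std::exp(logPi(i, k) + Ag(i, k) - m);
      out[i] += m + std::log(sum);
    }
  }
}

static arma::cube log_cube(const arma::cube& x) {
  arma::cube out = x;
  out.transform([](double v) { return v > 0.0 ? std::log(v) : NEG_INF; });
  return out;
}

static arma::mat log_mat(const arma::mat& x) {
  arma::mat out = x;
  out.transform([](double v) { return v > 0.0 ? std::log(v) : NEG_INF; });
  return out;
}

// --------------------------------------------------------- exported steps --

// [[Rcpp::export]]
arma::cube cpp_update_lambda(const arma::imat& y, const arma::ivec& d,
                             const arma::ivec& s, const arma::imat& Z,
                             int K, int dmax) {
  arma::cube lam(dmax, K, y.n_cols, arma::fill::zeros);
  arma::cube llam(dmax, K, y.n_cols, arma::fill::zeros);
  upd_lambda(y, d, s, Z, K, lam, llam);
  return lam;
}

// Returns the membership matrix together with its exact log values and the
// per-profile log sums (the sufficient statistic of the alpha updates).
// [[Rcpp::export]]
List cpp_update_pi(const arma::imat& Z, const arma::vec& alpha) {
  const int n = Z.n_rows, K = alpha.n_elem;
  arma::mat Pi(n, K), logPi(n, K);
  arma::vec Slog(K);
  upd_pi(Z, alpha, Pi, logPi, Slog);
  return List::create(_["Pi"] = Pi, _["logPi"] = logPi, _["Slog"] = Slog);
}

// [[Rcpp::export]]
arma::imat cpp_update_z(const arma::imat& y, const arma::ivec& s,
                        const arma::cube& lambda, const arma::mat& Pi,
                        int G) {
  const int K = Pi.n_cols;
  arma::cube llam = log_cube(lambda);
  arma::cube A(y.n_rows, K, G);
  group_loglik(y, s, llam, A);
  arma::mat logPi = log_mat(Pi);
  arma::imat Z(y.n_rows, G);
  upd_z(Z, A, logPi);
  return Z;
}

// [[Rcpp::export]]
List cpp_update_s(const arma::imat& y, const arma::cube& lambda,
                  const arma::imat& Z, const arma::vec& xi, int G) {
  arma::cube llam = log_cube(lambda);
  arma::ivec s(y.n_cols);
  arma::vec xi2 = xi;
  upd_s(s, xi2, y, llam, Z, G);
  return List::create(_["s"] = s, _["xi"] = xi2);
}

// [[Rcpp::export]]
List cpp_update_s_collapsed(const arma::imat& y, const arma::cube& lambda,
                            const arma::mat& Pi, const arma::ivec& s,
                            const arma::vec& xi, int G) {
  arma::cube llam = log_cube(lambda);
  arma::mat logPi = log_mat(Pi);
  arma::ivec s2 = s;
  arma::vec xi2 = xi;
  upd_s_collapsed(s2, xi2, y, lambda, llam, logPi, G);
  return List::create(_["s"] = s2, _["xi"] = xi2);
}

// [[Rcpp::export]]
List cpp_update_alpha_mh(const arma::vec& alpha, const arma::vec& Slog,
                         int n, double sigma, double a_alpha,
                         double b_alpha) {
  arma::vec a = alpha;
  double logr = 0.0;
  bool acc = upd_alpha_mh(a, Slog, n, sigma, a_alpha, b_alpha, &logr);
  return List::create(_["alpha"] = a, _["accepted"] = acc,
                      _["logRatio"] = logr);
}

// [[Rcpp::export]]
int cpp_rcrt(int m, double r) { return rcrt(m, r); }

// [[Rcpp::export]]
arma::vec cpp_update_alpha_gibbs(const arma::vec& alpha, const arma::imat& Z,
                                 double a0, double b0) {
  arma::vec a = alpha;
  upd_alpha_gibbs(a, Z, a0, b0);
  return a;
}

// [[Rcpp::export]]
arma::vec cpp_pointwise_loglik(const arma::imat& y, const arma::ivec& s,
                               const arma::cube& lambda, const arma::mat& Pi,
                               int G) {
  const int K = Pi.n_cols;
  arma::cube llam = log_cube(lambda);
  arma::cube A(y.n_rows, K, G);
  group_loglik(y, s, llam, A);
  arma::mat logPi = log_mat(Pi);
  arma::vec out(y.n_rows);
  pointwise_loglik(A, logPi, out.memptr());
  return out;
}

// Redraw y | (lambda, s, Z); used by the joint-distribution (Geweke) tests.
// [[Rcpp::export]]
arma::imat cpp_draw_y(const arma::ivec& d, const arma::ivec& s,
                      const arma::cube& lambda, const arma::imat& Z) {
  const int n = Z.n_rows, p = s.n_elem;
  arma::imat y(n, p);
  std::vector<double> col;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      const int k = (int)Z(i, (int)s[j]);
      col.resize(d[j]);
      for (int c = 0; c < (int)d[j]; ++c) col[c] = lambda(c, k, j);
      y(i, j) = rcat_prob(col.data(), d[j]);
    }
  return y;
}

// Forward simulation from the generative process.  Subjects are generated
// strictly one at a time (pi_i, then z_i, then y_i) so that enlarging n
// extends an existing dataset under the same seed instead of reshuffling it.
// [[Rcpp::export]]
List cpp_simulate(const arma::ivec& d, const arma::ivec& s,
                  const arma::cube& lambda, const arma::vec& alpha,
                  int n, int G) {
  const int p = s.n_elem, K = alpha.n_elem;
  arma::imat y(n, p), Z(n, G);
  arma::mat Pi(n, K);
  std::vector<double> col;
  for (int i = 0; i < n; ++i) {
    arma::vec pi = rdirich_vec(alpha);
    Pi.row(i) = pi.t();
    for (int g = 0; g < G; ++g) Z(i, g) = rcat_prob(pi.memptr(), K);
    for (int j = 0; j < p; ++j) {
      const int k = (int)Z(i, (int)s[j]);
      col.resize(d[j]);
      for (int c = 0; c < (int)d[j]; ++c) col[c] = lambda(c, k, j);
      y(i, j) = rcat_prob(col.data(), d[j]);
    }
  }
  return List::create(_["y"] = y, _["Pi"] = Pi, _["Z"] = Z);
}

// ----------------------------------------------------------- full sampler --

// One full sweep order: lambda, pi, z, (s, xi), alpha (MH or Gibbs).
// [[Rcpp::export]]
List cpp_run_chain(const arma::imat& y, const arma::ivec& d, int G, int K,
                   int iterations, int burnin, int thin, bool gibbs_alpha,
                   double sigma_alpha, double a_alpha, double b_alpha,
                   double a0, double b0, int collapse_every, int anneal,
                   arma::ivec s, arma::cube lambda, arma::mat Pi,
                   arma::imat Z, arma::vec xi, arma::vec alpha) {
  const int n = y.n_rows, p = y.n_cols;
  const int dmax = (int)d.max();
  const int T = (iterations - burnin) / thin;
  const int sumd = (int)arma::accu(d);

  arma::imat s_dr(T, p);
  arma::mat alpha_dr(T, K), xi_dr(T, G), ll_dr(T, n);
  arma::cube lam_dr(sumd, K, T);
  NumericVector accept(iterations, NA_REAL);

  arma::ivec off(p);
  { int o = 0; for (int j = 0; j < p; ++j) { off[j] = o; o += (int)d[j]; } }

  arma::cube llam = log_cube(lambda);
  arma::mat logPi = log_mat(Pi);
  arma::vec Slog(K);
  arma::cube A(n, K, G);
  arma::vec ll(n);

  // Annealing runs in cycles; each cycle ramps the grouping temperature
  // from 0 to 1, the end-of-cycle state is scored by its total data
  // log-likelihood (z marginalized), and the best-scoring state is
  // restored when the ramp ends.  Multiple restarts make the mode search
  // robust to a single ramp freezing a wrong merge.
  const int cycles = (anneal >= 1500) ? 3 : (anneal > 0 ? 1 : 0);
  const int clen = cycles > 0 ? anneal / cycles : 0;
  double bestScore = -std::numeric_limits<double>::infinity();
  arma::ivec best_s;
  arma::imat best_Z;
  arma::cube best_lambda;
  arma::mat best_Pi;
  arma::vec best_xi, best_alpha;

  int t = 0;
  for (int it = 1; it <= iterations; ++it) {
    upd_lambda(y, d, s, Z, K, lambda, llam);
    upd_pi(Z, alpha, Pi, logPi, Slog);
    const bool annealing = anneal > 0 && it <= anneal;
    if (annealing || (collapse_every > 0 && it % collapse_every == 0)) {
      // partially collapsed grouping move: s with z marginalized, then z
      double temper = 1.0;
      if (annealing && clen > 0) {
        const int pos = (it - 1) % clen + 1;
        // quadratic ramp: grouping merges lock in at temperatures of order
        // 1/n, so the schedule spends most of its iterations there
        const double frac = std::min(1.0, (double)pos / (double)clen);
        temper = frac * frac;
      }
      upd_s_collapsed(s, xi, y, lambda, llam, logPi, G, temper);
      group_loglik(y, s, llam, A);
      upd_z(Z, A, logPi);
    } else {
      group_loglik(y, s, llam, A);
      upd_z(Z, A, logPi);
      upd_s(s, xi, y, llam, Z, G);
    }
    if (annealing && clen > 0 &&
        ((it % clen == 0 && it > clen / 2) || it == anneal)) {
      pointwise_loglik(A, logPi, ll.memptr());
      const double score = arma::accu(ll);
      if (score > bestScore) {
        bestScore = score;
        best_s = s; best_Z = Z; best_lambda = lambda;
        best_Pi = Pi; best_xi = xi; best_alpha = alpha;
      }
      if (it == anneal) {  // hand the best state to the exact phase
        s = best_s; Z = best_Z; lambda = best_lambda;
        llam = log_cube(lambda);
        Pi = best_Pi; logPi = log_mat(Pi);
        for (int k = 0; k < K; ++k) {
          Slog[k] = 0.0;
          for (int i = 0; i < n; ++i) Slog[k] += logPi(i, k);
        }
        xi = best_xi; alpha = best_alpha;
      }
    }
    if (gibbs_alpha) {
      upd_alpha_gibbs(alpha, Z, a0, b0);
    } else {
      double lr;
      accept[it - 1] =
          upd_alpha_mh(alpha, Slog, n, sigma_alpha, a_alpha, b_alpha, &lr)
              ? 1.0 : 0.0;
    }
    // While the grouping is still sorting itself during the annealed ramp,
    // keep every profile alive: a concentration component that collapses
    // toward zero at this stage is absorbing (its profile is never used
    // again), so alpha is floored during burn-in annealing only.
    if (annealing)
      for (int k = 0; k < K; ++k)
        if (alpha[k] < 0.05) alpha[k] = 0.05;

    if (it > burnin && (it - burnin) % thin == 0 && t < T) {
      for (int j = 0; j < p; ++j) s_dr(t, j) = (int)s[j];
      alpha_dr.row(t) = alpha.t();
      xi_dr.row(t) = xi.t();
      for (int j = 0; j < p; ++j)
        for (int c = 0; c < (int)d[j]; ++c)
          for (int k = 0; k < K; ++k)
            lam_dr(off[j] + c, k, t) = lambda(c, k, j);
      group_loglik(y, s, llam, A);  // grouping changed after the z step
      pointwise_loglik(A, logPi, ll.memptr());
      ll_dr.row(t) = ll.t();
      ++t;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["s"] = s_dr, _["alpha"] = alpha_dr, _["xi"] = xi_dr,
      _["lambda"] = lam_dr, _["logLik"] = ll_dr, _["accept"] = accept,
      _["finalState"] = List::create(
          _["s"] = s, _["lambda"] = lambda, _["Pi"] = Pi, _["Z"] = Z,
          _["xi"] = xi, _["alpha"] = alpha));
}
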