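// Multi-trait linear/threshold animal model by single-site Gibbs sampling.
//
// State is kept as the residual matrix e (N x t) on the liability scale:
// e(i,j) = l(i,j) - mu(i,j), mu(i,j) = b_j[cg(i,j)] + a(i,j), where l is the
// observed phenotype (linear), the latent liability (binary) or an augmented
// value (missing). Location effects are updated by Gauss-Seidel sweeps in a
// fixed order; (co)variance matrices by inverted-Wishart draws. All random
// numbers come from R's RNG so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart draw via Bartlett decomposition, scale V, df > p - 1.
static arma::mat rwishart(double df, const arma::mat& V) {
  const int p = V.n_rows;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverted-Wishart draw with density |S|^(nu/2) |X|^(-(nu+p+1)/2) exp(-tr(S X^-1)/2).
static arma::mat riwishart(double df, const arma::mat& S) {
  return arma::inv_sympd(rwishart(df, arma::inv_sympd(S)));
}

// N(m, sd^2) truncated to (lo, Inf); Robert's exponential rejection in the
// far tail, inverse CDF otherwise. Stable for |lo - m|/sd up to ~8 and beyond.
static double rtnorm_lower_cpp(double m, double sd, double lo) {
  double a = (lo - m) / sd;
  if (a < 5.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = pa + unif_rand() * (1.0 - pa);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return m + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (unif_rand() <= rho) return m + sd * z;
  }
}

static double rtnorm_upper_cpp(double m, double sd, double hi) {
  return 2.0 * m - rtnorm_lower_cpp(m, sd, 2.0 * m - hi);
}

// [[Rcpp::export(name = ".rtnorm_cpp")]]
NumericVector rtnorm_cpp(int n, double mean, double sd, double lower, double upper) {
  NumericVector out(n);
  bool lo = std::isfinite(lower), hi = std::isfinite(upper);
  for (int k = 0; k < n; ++k) {
    if (lo && !hi) out[k] = rtnorm_lower_cpp(mean, sd, lower);
    else if (hi && !lo) out[k] = rtnorm_upper_cpp(mean, sd, upper);
    else if (!lo && !hi) out[k] = mean + sd * norm_rand();
    else {
      // two-sided by inverse CDF (adequate away from extreme joint tails)
      double pa = R::pnorm((lower - mean) / sd, 0, 1, 1, 0);
      double pb = R::pnorm((upper - mean) / sd, 0, 1, 1, 0);
      double u = pa + unif_rand() * (pb - pa);
      out[k] = mean + sd * R::qnorm(u, 0, 1, 1, 0);
    }
  }
  return out;
}

// Tabular-method numerator relationship matrix. sire/dam are 1-based indices
// into the (topologically ordered) animal vector, 0 = unknown parent.
// [[Rcpp::export(name = ".tabular_a_cpp")]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree is not topologically ordered");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = A(j, i) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

struct SparseSym {
  // CSC arrays of a symmetric N x N matrix
  const int* i; const int* p; const double* x; int n;
  arma::vec diagval;
};

// out (t-vector) = sum over column c of P: x * a.row(rowidx); a is N x t
// column-major with leading dimension N
static inline void col_accum(const SparseSym& P, const double* a, int N,
                             int t, int c, double* out) {
  for (int j = 0; j < t; ++j) out[j] = 0.0;
  for (int k = P.p[c]; k < P.p[c + 1]; ++k) {
    const double v = P.x[k];
    const int r = P.i[k];
    for (int j = 0; j < t; ++j) out[j] += v * a[(size_t)j * N + r];
  }
}

// in-place lower Cholesky of a small t x t matrix (column-major, t <= 16)
static inline void chol_small(double* C, int t) {
  for (int j = 0; j < t; ++j) {
    double d = C[j * t + j];
    for (int k = 0; k < j; ++k) d -= C[k * t + j] * C[k * t + j];
    if (d <= 0.0) stop("conditional precision not positive-definite");
    const double lj = std::sqrt(d);
    C[j * t + j] = lj;
    for (int i = j + 1; i < t; ++i) {
      double s = C[j * t + i];
      for (int k = 0; k < j; ++k) s -= C[k * t + i] * C[k * t + j];
      C[j * t + i] = s / lj;
    }
  }
}

// solve L y = b in place (L lower from chol_small, stored column-major)
static inline void forwardsolve_small(const double* L, double* b, int t) {
  for (int i = 0; i < t; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[k * t + i] * b[k];
    b[i] = s / L[i * t + i];
  }
}

// solve L' y = b in place
static inline void backsolve_small(const double* L, double* b, int t) {
  for (int i = t - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < t; ++k) s -= L[i * t + k] * b[k];
    b[i] = s / L[i * t + i];
  }
}

// [[Rcpp::export(name = ".gibbs_mt_cpp")]]
List gibbs_mt_cpp(NumericMatrix y_in,        // N x t, NA = missing; binary coded 1/2
                  IntegerMatrix cg_in,       // N x t, 1-based level, 0 = none
                  IntegerVector ncg,         // levels per trait
                  LogicalVector binary,      // per trait
                  IntegerVector Pi, IntegerVector Pp, NumericVector Px,
                  bool genetic,
                  NumericMatrix Sg_in, double nug,
                  NumericMatrix Sr_in, double nur,
                  int n_iter, int burn_in, int thin,
                  List init, bool store_effects) {
  const int N = y_in.nrow(), t = y_in.ncol();
  const arma::mat Sg(Sg_in.begin(), t, t), Sr(Sr_in.begin(), t, t);

  SparseSym P;
  P.n = N;
  if (genetic) {
    P.i = INTEGER(Pi); P.p = INTEGER(Pp); P.x = REAL(Px);
    P.diagval.set_size(N);
    for (int c = 0; c < N; ++c) {
      double d = 0.0;
      for (int k = P.p[c]; k < P.p[c + 1]; ++k)
        if (P.i[k] == c) { d = P.x[k]; break; }
      if (d <= 0.0) stop("relationship inverse has non-positive diagonal");
      P.diagval[c] = d;
    }
  }

  // observation bookkeeping
  arma::umat obs(N, t, arma::fill::zeros);   // 1 = category/value observed
  std::vector<int> rset;                     // animals with >= 1 observation
  for (int i = 0; i < N; ++i) {
    bool any = false;
    for (int j = 0; j < t; ++j)
      if (!NumericMatrix::is_na(y_in(i, j))) { obs(i, j) = 1; any = true; }
    if (any) rset.push_back(i);
  }
  const int nR = rset.size();
  std::vector<char> in_rset(N, 0);
  for (int i : rset) in_rset[i] = 1;
  bool any_aug = false;
  for (int j = 0; j < t && !any_aug; ++j) if (binary[j]) any_aug = true;
  for (int r = 0; r < nR && !any_aug; ++r)
    for (int j = 0; j < t; ++j)
      if (!obs(rset[r], j)) { any_aug = true; break; }

  // per (trait, level) row lists for CG updates
  std::vector<std::vector<std::vector<int>>> lev(t);
  for (int j = 0; j < t; ++j) {
    lev[j].assign(ncg[j], std::vector<int>());
    for (int i = 0; i < N; ++i) {
      int k = cg_in(i, j);
      if (k > 0 && obs(i, j)) lev[j][k - 1].push_back(i);
    }
  }

  // state
  arma::mat a(N, t, arma::fill::zeros);
  std::vector<arma::vec> b(t);
  for (int j = 0; j < t; ++j) b[j] = arma::vec(std::max(ncg[j], 1), arma::fill::zeros);
  arma::mat G0 = Sg, R0 = Sr;
  if (init.containsElementNamed("G0")) G0 = as<arma::mat>(init["G0"]);
  if (init.containsElementNamed("R0")) R0 = as<arma::mat>(init["R0"]);
  if (init.containsElementNamed("a"))  a  = as<arma::mat>(init["a"]);
  if (init.containsElementNamed("b")) {
    List bl = init["b"];
    for (int j = 0; j < t; ++j) b[j] = as<arma::vec>(bl[j]);
  }

  // residuals: e = l - mu; liabilities start at +-0.5, missing at 0
  arma::mat e(N, t, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < t; ++j) {
      double mu = a(i, j) + (cg_in(i, j) > 0 ? b[j][cg_in(i, j) - 1] : 0.0);
      if (obs(i, j)) {
        double l = binary[j] ? (y_in(i, j) == 2.0 ? 0.5 : -0.5) : y_in(i, j);
        e(i, j) = l - mu;
      } else e(i, j) = 0.0;
    }
  if (init.containsElementNamed("e")) e = as<arma::mat>(init["e"]);

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  arma::cube G0s(t, t, std::max(n_keep, 1), arma::fill::zeros);
  arma::cube R0s(t, t, std::max(n_keep, 1), arma::fill::zeros);
  arma::mat a_mean(N, t, arma::fill::zeros);
  std::vector<arma::vec> b_mean(t);
  for (int j = 0; j < t; ++j) b_mean[j] = arma::vec(std::max(ncg[j], 1), arma::fill::zeros);
  int kept = 0;

  arma::mat W(t, t), Ginv(t, t);
  std::vector<double> sbuf(t), rhsbuf(t), Cbuf(t * t);

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    W = arma::inv_sympd(R0);
    if (genetic) Ginv = arma::inv_sympd(G0);

    // --- contemporary-group (fixed) effects: flat prior scalar updates
    for (int j = 0; j < t; ++j) {
      for (int k = 0; k < ncg[j]; ++k) {
        const std::vector<int>& rows = lev[j][k];
        if (rows.empty()) continue;
        double sum_we = 0.0;
        for (int idx : rows) {
          double we = 0.0;
          for (int jj = 0; jj < t; ++jj) we += W(j, jj) * e(idx, jj);
          sum_we += we;
        }
        const double bold = b[j][k];
        const double Cjj = rows.size() * W(j, j);
        const double mean = (sum_we + Cjj * bold) / Cjj;
        const double bnew = mean + norm_rand() / std::sqrt(Cjj);
        b[j][k] = bnew;
        const double d = bnew - bold;
        for (int idx : rows) e(idx, j) -= d;
      }
    }

    // --- breeding values: per-animal t-block updates
    if (genetic) {
      const double* amem = a.memptr();
      double* s = sbuf.data();
      double* rhs = rhsbuf.data();
      double* C = Cbuf.data();
      for (int i = 0; i < N; ++i) {
        col_accum(P, amem, N, t, i, s);        // s = sum_i' P(i,i') a_i'
        const double pii = P.diagval[i];
        bool inR = in_rset[i];
        // rhs = -Ginv (s - pii a_i) [+ W (e_i + a_i)]; C = pii Ginv [+ W]
        for (int j = 0; j < t; ++j) {
          double rj = 0.0;
          for (int jj = 0; jj < t; ++jj) {
            rj -= Ginv.at(j, jj) * (s[jj] - pii * a.at(i, jj));
            if (inR) rj += W.at(j, jj) * (e.at(i, jj) + a.at(i, jj));
            C[jj * t + j] = pii * Ginv.at(j, jj) + (inR ? W.at(j, jj) : 0.0);
          }
          rhs[j] = rj;
        }
        chol_small(C, t);
        forwardsolve_small(C, rhs, t);         // rhs <- L^-1 rhs
        for (int j = 0; j < t; ++j) rhs[j] += norm_rand();
        backsolve_small(C, rhs, t);            // rhs <- L'^-1 (.) = new a_i
        for (int j = 0; j < t; ++j) {
          if (inR) e.at(i, j) -= rhs[j] - a.at(i, j);
          a.at(i, j) = rhs[j];
        }
      }
    }

    // --- augmentation: missing phenotypes and binary liabilities
    if (any_aug)
    for (int r = 0; r < nR; ++r) {
      const int i = rset[r];
      for (int j = 0; j < t; ++j) {
        if (obs(i, j) && !binary[j]) continue;
        const double v = 1.0 / W(j, j);
        double we = 0.0;
        for (int jj = 0; jj < t; ++jj)
          if (jj != j) we += W(j, jj) * e(i, jj);
        const double m = -v * we;
        const double sd = std::sqrt(v);
        if (!obs(i, j)) {
          e(i, j) = m + sd * norm_rand();
        } else {
          // binary: liability above/below threshold 0 <=> e >< -mu
          const double mu = a(i, j) + (cg_in(i, j) > 0 ? b[j][cg_in(i, j) - 1] : 0.0);
          e(i, j) = (y_in(i, j) == 2.0)
            ? rtnorm_lower_cpp(m, sd, -mu)
            : rtnorm_upper_cpp(m, sd, -mu);
        }
      }
    }

    // --- residual covariance
    {
      arma::mat Se(t, t, arma::fill::zeros);
      for (int r = 0; r < nR; ++r) {
        const int i = rset[r];
        for (int j = 0; j < t; ++j)
          for (int jj = j; jj < t; ++jj)
            Se.at(j, jj) += e.at(i, j) * e.at(i, jj);
      }
      for (int j = 0; j < t; ++j)
        for (int jj = 0; jj < j; ++jj) Se.at(j, jj) = Se.at(jj, j);
      R0 = riwishart(nur + nR, Sr + Se);
      // identifiability: binary residual variances fixed at 1 by rescaling
      for (int j = 0; j < t; ++j) {
        if (!binary[j]) continue;
        const double sc = 1.0 / std::sqrt(R0(j, j));
        for (int jj = 0; jj < t; ++jj) { R0(j, jj) *= sc; R0(jj, j) *= sc; }
        R0(j, j) = 1.0;
        a.col(j) *= sc;
        e.col(j) *= sc;
        b[j] *= sc;
      }
    }

    // --- genetic covariance
    if (genetic) {
      arma::mat Sa(t, t, arma::fill::zeros);
      const double* amem = a.memptr();
      double* s = sbuf.data();
      for (int c = 0; c < N; ++c) {
        col_accum(P, amem, N, t, c, s);
        for (int j = 0; j < t; ++j)
          for (int jj = 0; jj < t; ++jj)
            Sa.at(j, jj) += a.at(c, j) * s[jj];
      }
      Sa = 0.5 * (Sa + Sa.t());
      G0 = riwishart(nug + N, Sg + Sa);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      G0s.slice(kept) = G0;
      R0s.slice(kept) = R0;
      if (store_effects) {
        a_mean += a;
        for (int j = 0; j < t; ++j) b_mean[j] += b[j];
      }
      ++kept;
    }
  }

  if (store_effects && kept > 0) {
    a_mean /= kept;
    for (int j = 0; j < t; ++j) b_mean[j] /= kept;
  }

  List bl(t), bml(t);
  for (int j = 0; j < t; ++j) { bl[j] = b[j]; bml[j] = b_mean[j]; }
  return List::create(
    _["G0"] = G0s, _["R0"] = R0s, _["n_kept"] = kept,
    _["a_mean"] = a_mean, _["b_mean"] = bml,
    _["state"] = List::create(_["G0"] = G0, _["R0"] = R0, _["a"] = a,
                              _["b"] = bl, _["e"] = e),
    _["n_records"] = nR);
}
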