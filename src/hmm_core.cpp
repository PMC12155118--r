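// Scaled hidden-Markov recursions. All state-space loops live here because
// they are O(N K^2) per pass and run thousands of times during EM / MCMC.
#include <Rcpp.h>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// Probability recursions on long, well-separated series generate floods of
// denormalized doubles whose hardware handling is ~100x slower than normal
// arithmetic and whose value is far below every tolerance in the package.
// Scoped flush-to-zero: enabled inside the hot entry points, restored on
// exit so the rest of the R process is untouched.
struct FtzScope {
#ifdef __SSE2__
  unsigned int csr;
  FtzScope() : csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FtzScope() { _mm_setcsr(csr); }
#endif
};

static const double LOG2PI = std::log(2.0 * M_PI);

// shifted emission weight with subnormal flush: exp() results below ~1e-290
// are rounded to zero so the recursions never touch denormalized floats
// (which stall by orders of magnitude on common hardware); the discarded
// mass is below any tolerance used anywhere in the package
static inline double exp_flush(double logx) {
  return logx < -667.0 ? 0.0 : std::exp(logx);
}
static inline double flushz(double x) {
  return x < 1e-290 ? 0.0 : x;
}

// emission log-densities: Normal(w | mu_k, sigma_k)
static void fill_logB(const NumericVector& w, const NumericVector& mu,
                      const NumericVector& sigma, NumericMatrix& logB) {
  int N = w.size(), K = mu.size();
  for (int k = 0; k < K; ++k) {
    double s = sigma[k];
    double c = -0.5 * LOG2PI - std::log(s);
    for (int n = 0; n < N; ++n) {
      double z = (w[n] - mu[k]) / s;
      logB(n, k) = c - 0.5 * z * z;
    }
  }
}

// scaled forward pass; returns loglik, optionally keeps normalized
// filtered probabilities in ahat
static double forward_scaled(const NumericMatrix& logB,
                             const NumericMatrix& Pi,
                             const NumericVector& rho,
                             NumericMatrix* ahat_out) {
  int N = logB.nrow(), K = logB.ncol();
  std::vector<double> a(K), anew(K), b(K);
  double loglik = 0.0;
  for (int n = 0; n < N; ++n) {
    double m = logB(n, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(n, k));
    for (int k = 0; k < K; ++k) b[k] = exp_flush(logB(n, k) - m);
    double c = 0.0;
    if (n == 0) {
      for (int k = 0; k < K; ++k) { anew[k] = rho[k] * b[k]; c += anew[k]; }
    } else {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += a[j] * Pi(j, k);
        anew[k] = s * b[k];
        c += anew[k];
      }
    }
    if (!(c > 0.0) || !std::isfinite(c))
      stop("forward recursion underflow/overflow at step %d", n + 1);
    for (int k = 0; k < K; ++k) a[k] = flushz(anew[k] / c);
    if (ahat_out) for (int k = 0; k < K; ++k) (*ahat_out)(n, k) = a[k];
    loglik += std::log(c) + m;
  }
  return loglik;
}

// [[Rcpp::export(name = ".forward_ll_cpp")]]
double forward_ll_cpp(NumericMatrix logB, NumericMatrix Pi,
                      NumericVector rho) {
  FtzScope ftz;
  return forward_scaled(logB, Pi, rho, nullptr);
}

// full forward-backward: loglik, smoothed gamma (N x K), summed xi (K x K),
// filtered probabilities
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericMatrix Pi, NumericVector rho) {
  FtzScope ftz;
  int N = logB.nrow(), K = logB.ncol();
  NumericMatrix ahat(N, K), gamma(N, K), xi(K, K);
  // redo forward keeping the per-step scales and shifted emissions
  NumericMatrix b(N, K);
  std::vector<double> cvec(N), mvec(N);
  double loglik = 0.0;
  {
    std::vector<double> a(K), anew(K);
    for (int n = 0; n < N; ++n) {
      double m = logB(n, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, logB(n, k));
      mvec[n] = m;
      for (int k = 0; k < K; ++k) b(n, k) = exp_flush(logB(n, k) - m);
      double c = 0.0;
      if (n == 0) {
        for (int k = 0; k < K; ++k) { anew[k] = rho[k] * b(n, k); c += anew[k]; }
      } else {
        for (int k = 0; k < K; ++k) {
          double s = 0.0;
          for (int j = 0; j < K; ++j) s += a[j] * Pi(j, k);
          anew[k] = s * b(n, k);
          c += anew[k];
        }
      }
      if (!(c > 0.0) || !std::isfinite(c))
        stop("forward recursion underflow/overflow at step %d", n + 1);
      cvec[n] = c;
      for (int k = 0; k < K; ++k) { a[k] = flushz(anew[k] / c); ahat(n, k) = a[k]; }
      loglik += std::log(c) + m;
    }
  }
  // backward
  std::vector<double> beta(K, 1.0), bnew(K);
  for (int k = 0; k < K; ++k) gamma(N - 1, k) = ahat(N - 1, k);
  for (int n = N - 2; n >= 0; --n) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += Pi(j, k) * b(n + 1, k) * beta[k];
      bnew[j] = flushz(s / cvec[n + 1]);
    }
    double gsum = 0.0;
    for (int j = 0; j < K; ++j) {
      gamma(n, j) = ahat(n, j) * bnew[j];
      gsum += gamma(n, j);
    }
    // renormalize against scaled-arithmetic drift
    for (int j = 0; j < K; ++j) gamma(n, j) /= gsum;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += ahat(n, j) * Pi(j, k) * b(n + 1, k) * beta[k] / cvec[n + 1];
    for (int j = 0; j < K; ++j) beta[j] = bnew[j];
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi, _["filtered"] = ahat);
}

// Viterbi in log space; ties broken toward the lower state index
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix Pi,
                          NumericVector rho) {
  int N = logB.nrow(), K = logB.ncol();
  NumericMatrix logPi(K, K);
  NumericVector logrho(K);
  for (int k = 0; k < K; ++k)
    logrho[k] = rho[k] > 0 ? std::log(rho[k]) : R_NegInf;
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logPi(j, k) = Pi(j, k) > 0 ? std::log(Pi(j, k)) : R_NegInf;
  NumericMatrix delta(N, K);
  IntegerMatrix psi(N, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logrho[k] + logB(0, k);
  for (int n = 1; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      double best = delta(n - 1, 0) + logPi(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(n - 1, j) + logPi(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(n, k) = best + logB(n, k);
      psi(n, k) = arg;
    }
  IntegerVector path(N);
  int arg = 0;
  double best = delta(N - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(N - 1, k) > best) { best = delta(N - 1, k); arg = k; }
  path[N - 1] = arg;
  for (int n = N - 2; n >= 0; --n) path[n] = psi(n + 1, path[n + 1]);
  return path + 1; // 1-based states
}

// forward filtering backward sampling; uniforms supplied by the caller so
// the draw is governed by R's RNG
// [[Rcpp::export(name = ".ffbs_cpp")]]
IntegerVector ffbs_cpp(NumericMatrix logB, NumericMatrix Pi,
                       NumericVector rho, NumericVector u) {
  FtzScope ftz;
  int N = logB.nrow(), K = logB.ncol();
  if (u.size() != N) stop("need one uniform per observation");
  NumericMatrix ahat(N, K);
  forward_scaled(logB, Pi, rho, &ahat);
  IntegerVector s(N);
  // sample s_N
  {
    double cum = 0.0; int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += ahat(N - 1, k);
      if (u[N - 1] <= cum) { pick = k; break; }
    }
    s[N - 1] = pick;
  }
  std::vector<double> p(K);
  for (int n = N - 2; n >= 0; --n) {
    int nxt = s[n + 1];
    double tot = 0.0;
    for (int j = 0; j < K; ++j) { p[j] = ahat(n, j) * Pi(j, nxt); tot += p[j]; }
    double cum = 0.0; int pick = K - 1;
    for (int j = 0; j < K; ++j) {
      cum += p[j] / tot;
      if (u[n] <= cum) { pick = j; break; }
    }
    s[n] = pick;
  }
  return s + 1;
}

// complete Baum-Welch loop for Gaussian-emission HMMs
// [[Rcpp::export(name = ".em_cpp")]]
List em_cpp(NumericVector w, NumericVector rho0, NumericMatrix Pi0,
            NumericVector mu0, NumericVector sigma0, bool shared_sigma,
            double tol, int max_iter, double sigma_floor) {
  FtzScope ftz;
  int N = w.size(), K = mu0.size();
  NumericVector rho = clone(rho0), mu = clone(mu0), sigma = clone(sigma0);
  NumericMatrix Pi = clone(Pi0);
  NumericMatrix logB(N, K);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false, degenerate = false;
  double ll_prev = R_NegInf;
  NumericVector occ(K);
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    fill_logB(w, mu, sigma, logB);
    List fb = fb_cpp(logB, Pi, rho);
    double ll = fb["loglik"];
    NumericMatrix gamma = fb["gamma"], xi = fb["xi"];
    trace.push_back(ll);
    // occupancy and degeneracy screen
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int n = 0; n < N; ++n) s += gamma(n, k);
      occ[k] = s;
    }
    for (int k = 0; k < K; ++k)
      if (occ[k] < 1.0) { degenerate = true; break; }
    if (degenerate) break;
    if (iter > 0 && std::fabs(ll - ll_prev) <
        tol * (std::fabs(ll_prev) + 1e-12)) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // M-step
    for (int k = 0; k < K; ++k) rho[k] = gamma(0, k);
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi(j, k);
      if (rs > 0)
        for (int k = 0; k < K; ++k) Pi(j, k) = xi(j, k) / rs;
      // rs == 0: state j never followed by anything; keep its old row
    }
    for (int k = 0; k < K; ++k) {
      double sw = 0.0;
      for (int n = 0; n < N; ++n) sw += gamma(n, k) * w[n];
      mu[k] = sw / occ[k];
    }
    if (shared_sigma) {
      double ss = 0.0;
      for (int k = 0; k < K; ++k)
        for (int n = 0; n < N; ++n) {
          double d = w[n] - mu[k];
          ss += gamma(n, k) * d * d;
        }
      double s = std::sqrt(ss / N);
      if (s < sigma_floor) s = sigma_floor;
      for (int k = 0; k < K; ++k) sigma[k] = s;
    } else {
      for (int k = 0; k < K; ++k) {
        double ss = 0.0;
        for (int n = 0; n < N; ++n) {
          double d = w[n] - mu[k];
          ss += gamma(n, k) * d * d;
        }
        double s = std::sqrt(ss / occ[k]);
        if (s < sigma_floor) s = sigma_floor;
        sigma[k] = s;
      }
    }
  }
  return List::create(_["rho"] = rho, _["Pi"] = Pi, _["mu"] = mu,
                      _["sigma"] = sigma,
                      _["loglik_trace"] = NumericVector(trace.begin(),
                                                        trace.end()),
                      _["converged"] = converged,
                      _["degenerate"] = degenerate,
                      _["n_iter"] = iter + 1,
                      _["occupancy"] = occ);
}
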