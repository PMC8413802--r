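// EM core for the binary latent class model. One call runs EM from a
// given start to convergence (absolute log-likelihood change < tol).
// Rows carry weights so callers can aggregate duplicate response
// patterns; conditional probabilities are clamped to [eps, 1-eps] so the
// log-likelihood stays finite at the boundary.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".em_core")]]
List em_core(const IntegerMatrix& y, const NumericVector& wt,
             NumericVector pi0, const NumericMatrix& rho0, double tol,
             int max_iter, double eps) {
  const int n = y.nrow(), J = y.ncol(), K = pi0.size();
  const double wtot = std::accumulate(wt.begin(), wt.end(), 0.0);

  // row-major copy of y for contiguous access in the inner loops
  std::vector<unsigned char> yt(static_cast<size_t>(n) * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i)
      yt[static_cast<size_t>(i) * J + j] = static_cast<unsigned char>(y(i, j));

  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> rho(static_cast<size_t>(J) * K); // [j*K + k]
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) rho[static_cast<size_t>(j) * K + k] = rho0(j, k);

  NumericMatrix tau(n, K);
  std::vector<double> logA(static_cast<size_t>(J) * K),
      logB(static_cast<size_t>(J) * K), logpi(K), ld(K), trow(K), nk(K),
      rho_num(static_cast<size_t>(J) * K);
  std::vector<double> ll_trace;
  ll_trace.reserve(256);

  double ll = 0.0, ll_old = R_NegInf;
  bool converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    for (int k = 0; k < K; ++k) logpi[k] = std::log(pi[k]);
    for (size_t jk = 0; jk < rho.size(); ++jk) {
      double r = rho[jk];
      if (r < eps) r = eps;
      if (r > 1.0 - eps) r = 1.0 - eps;
      logA[jk] = std::log(r);
      logB[jk] = std::log1p(-r);
    }
    ll = 0.0;
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(rho_num.begin(), rho_num.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const unsigned char* yr = &yt[static_cast<size_t>(i) * J];
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double s = logpi[k];
        const double* A = logA.data() + k;
        const double* B = logB.data() + k;
        for (int j = 0; j < J; ++j) s += yr[j] ? A[j * K] : B[j * K];
        ld[k] = s;
        if (s > m) m = s;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        trow[k] = std::exp(ld[k] - m);
        tot += trow[k];
      }
      const double w = wt[i];
      ll += w * (m + std::log(tot));
      for (int k = 0; k < K; ++k) {
        const double t = trow[k] / tot;
        tau(i, k) = t;
        const double wt_t = w * t;
        nk[k] += wt_t;
        for (int j = 0; j < J; ++j)
          if (yr[j]) rho_num[static_cast<size_t>(j) * K + k] += wt_t;
      }
    }
    ll_trace.push_back(ll);
    if (std::fabs(ll - ll_old) < tol) { converged = true; break; }
    ll_old = ll;
    for (int k = 0; k < K; ++k) {
      pi[k] = nk[k] / wtot;
      for (int j = 0; j < J; ++j) {
        double r = rho_num[static_cast<size_t>(j) * K + k] / nk[k];
        if (r < eps) r = eps;
        if (r > 1.0 - eps) r = 1.0 - eps;
        rho[static_cast<size_t>(j) * K + k] = r;
      }
    }
  }

  NumericMatrix rho_out(J, K);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) rho_out(j, k) = rho[static_cast<size_t>(j) * K + k];
  return List::create(
      _["pi"] = NumericVector(pi.begin(), pi.end()), _["rho"] = rho_out,
      _["loglik"] = ll, _["posterior"] = tau, _["converged"] = converged,
      _["iterations"] = iter,
      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
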