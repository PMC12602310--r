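#include <Rcpp.h>
using namespace Rcpp;

// Mean-squared displacement of a binary units x bins state matrix:
// MSD_{n,t} = Hamming(S_{t+n}, S_t) / N, averaged over the lags in n_range,
// for every t with all lags available.
// [[Rcpp::export(name = ".msd_core")]]
NumericVector msd_core(IntegerMatrix S, IntegerVector n_range) {
  const int N = S.nrow(), Tn = S.ncol();
  int nmax = 0;
  for (int j = 0; j < n_range.size(); ++j)
    if (n_range[j] > nmax) nmax = n_range[j];
  const int Tt = Tn - nmax;
  if (Tt < 1) stop("lag range exceeds the number of time bins");
  for (int j = 0; j < S.size(); ++j)
    if (S[j] != 0 && S[j] != 1) stop("state matrix must be binary");
  NumericVector acc(Tt);
  for (int j = 0; j < n_range.size(); ++j) {
    const int n = n_range[j];
    for (int t = 0; t < Tt; ++t) {
      int h = 0;
      const int* a = &S(0, t);
      const int* b = &S(0, t + n);
      for (int i = 0; i < N; ++i) h += (a[i] != b[i]);
      acc[t] += (double)h / N;
    }
  }
  return acc / (double)n_range.size();
}

// Sequential exponential-recovery hazard thinning of candidate spike times:
// a spike at time t is kept with probability 1 - exp(-(t - t_last)/tau).
// [[Rcpp::export(name = ".hazard_thin")]]
LogicalVector hazard_thin(NumericVector tt, NumericVector u, double tau_s) {
  const int n = tt.size();
  LogicalVector keep(n);
  double t_last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (u[i] < 1.0 - std::exp(-(tt[i] - t_last) / tau_s)) {
      keep[i] = true;
      t_last = tt[i];
    }
  }
  return keep;
}
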