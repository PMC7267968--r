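#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit-duration dynamic programming for a strictly sequential HSMM.
// A trial of M time points is partitioned as m_1 + ... + m_N = M with
// m_i >= 0 (m_i = 0 means state i is skipped).  The probability of one
// partitioning is prod_i G_i(m_i) * prod_{j in segment i} P(F_j | state i);
// the trial likelihood sums this over all partitionings.  All work is done
// in log space.
//
// Conventions shared by the routines below:
//   logB  : M x N matrix of per-time-point emission log densities
//   logG  : N x (Dmax+1) matrix, logG(i, d) = log P(duration = d) for
//           state i+1, d = 0 .. Dmax (column d+1 in R)
//   dcap  : per-state duration cap; durations beyond it carry negligible
//           gamma mass and are pruned from the recursions.  If pruning
//           leaves a trial with no feasible partitioning the trial is
//           recomputed without caps.
//   alpha : alpha[i][t] = log P(states 1..i exactly cover time points 1..t)
//   beta  : beta[i][t]  = log P(states i+1..N exactly cover t+1..M)
// so that the trial log likelihood is alpha[N][M] == beta[0][0].

// log(sum(exp(v))) over a term buffer, max-shifted for stability
static inline double logsumexp_buf(const std::vector<double>& v, int n) {
  double m = R_NegInf;
  for (int k = 0; k < n; ++k) if (v[k] > m) m = v[k];
  if (m == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

namespace {

struct TrialWork {
  int M, N;
  std::vector<int> cap;       // effective per-state duration cap
  std::vector<double> cs;     // (M+1) x N cumulative emission log sums
  std::vector<double> alpha;  // (N+1) x (M+1)
  std::vector<double> beta;   // (N+1) x (M+1)
  std::vector<double> buf;    // term buffer for log-sum-exp
  double loglik;

  inline double seg(int i, int s, int e) const {
    // emission log sum for state i (1-based) over time points s..e; 0 if e < s
    if (e < s) return 0.0;
    return cs[e * N + (i - 1)] - cs[(s - 1) * N + (i - 1)];
  }

  void set_caps(const IntegerVector& dcap, bool uncapped) {
    cap.resize(N);
    for (int i = 0; i < N; ++i)
      cap[i] = uncapped ? M : (dcap[i] < M ? dcap[i] : M);
  }

  // logB rows row0 .. row0+M-1 of the batch matrix hold this trial
  void forward(const NumericMatrix& logB, int row0,
               const NumericMatrix& logG) {
    const int Mp = M + 1;
    cs.assign(Mp * N, 0.0);
    for (int t = 1; t <= M; ++t)
      for (int i = 0; i < N; ++i)
        cs[t * N + i] = cs[(t - 1) * N + i] + logB(row0 + t - 1, i);
    buf.resize(Mp);
    alpha.assign((N + 1) * Mp, R_NegInf);
    alpha[0] = 0.0;  // alpha[0][0]
    for (int i = 1; i <= N; ++i) {
      const double* ap = &alpha[(i - 1) * Mp];
      double* an = &alpha[i * Mp];
      for (int t = 0; t <= M; ++t) {
        int dmax = t < cap[i - 1] ? t : cap[i - 1];
        int n = 0;
        for (int d = 0; d <= dmax; ++d) {
          double prev = ap[t - d];
          if (prev == R_NegInf) continue;
          buf[n++] = prev + logG(i - 1, d) + seg(i, t - d + 1, t);
        }
        an[t] = logsumexp_buf(buf, n);
      }
    }
    loglik = alpha[N * Mp + M];
  }

  void backward(const NumericMatrix& logG) {
    const int Mp = M + 1;
    beta.assign((N + 1) * Mp, R_NegInf);
    beta[N * Mp + M] = 0.0;
    for (int i = N; i >= 1; --i) {
      const double* bn = &beta[i * Mp];
      double* bp = &beta[(i - 1) * Mp];
      for (int t = 0; t <= M; ++t) {
        int dmax = M - t < cap[i - 1] ? M - t : cap[i - 1];
        int n = 0;
        for (int d = 0; d <= dmax; ++d) {
          double nxt = bn[t + d];
          if (nxt == R_NegInf) continue;
          buf[n++] = logG(i - 1, d) + seg(i, t + 1, t + d) + nxt;
        }
        bp[t] = logsumexp_buf(buf, n);
      }
    }
  }

  // State occupancies via posterior boundary positions.  With c_i the
  // cumulative number of time points after state i (c_0 = 0, c_N = M),
  // state i occupies time point j iff c_{i-1} < j <= c_i, so
  //   gamma[j][i] = P(c_{i-1} <= j-1) - P(c_i <= j-1)
  // and P(c_i = t) = exp(alpha[i][t] + beta[i][t] - loglik).
  void occupancy(NumericMatrix& gamma, int row0) const {
    const int Mp = M + 1;
    std::vector<double> cum(N + 1, 0.0);  // running P(c_i <= j-1)
    std::vector<double> post((N + 1) * Mp);
    for (int i = 0; i <= N; ++i)
      for (int t = 0; t <= M; ++t) {
        double v = alpha[i * Mp + t] + beta[i * Mp + t] - loglik;
        post[i * Mp + t] = (v == R_NegInf) ? 0.0 : std::exp(v);
      }
    for (int j = 1; j <= M; ++j) {
      for (int i = 0; i <= N; ++i) cum[i] += post[i * Mp + (j - 1)];
      double rowsum = 0.0;
      for (int i = 1; i <= N; ++i) {
        double g = cum[i - 1] - cum[i];
        if (g < 0.0) g = 0.0;
        if (g > 1.0) g = 1.0;
        gamma(row0 + j - 1, i - 1) = g;
        rowsum += g;
      }
      if (rowsum > 0)
        for (int i = 0; i < N; ++i) gamma(row0 + j - 1, i) /= rowsum;
    }
  }

  // Posterior over the duration spent in each state: eta[i][d] sums, over
  // all partitionings, the probability that state i occupies exactly d
  // time points.  Accumulated (+=) into eta for M-step pooling.
  void duration_posterior(NumericMatrix& eta, const NumericMatrix& logG) {
    const int Mp = M + 1;
    for (int i = 1; i <= N; ++i) {
      const double* ap = &alpha[(i - 1) * Mp];
      const double* bn = &beta[i * Mp];
      int dmax = cap[i - 1];
      for (int d = 0; d <= dmax; ++d) {
        int n = 0;
        for (int t = 0; t + d <= M; ++t) {
          double a = ap[t];
          if (a == R_NegInf) continue;
          double b = bn[t + d];
          if (b == R_NegInf) continue;
          buf[n++] = a + seg(i, t + 1, t + d) + b;
        }
        double acc = logsumexp_buf(buf, n);
        if (acc != R_NegInf)
          eta(i - 1, d) += std::exp(acc + logG(i - 1, d) - loglik);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".dp_forward_batch")]]
NumericVector dp_forward_batch(NumericMatrix logB, IntegerVector lengths,
                               NumericMatrix logG, IntegerVector dcap) {
  int n_trials = lengths.size();
  NumericVector ll(n_trials);
  TrialWork w;
  w.N = logB.ncol();
  if (dcap.size() != w.N) stop("dcap must have one entry per state");
  int row0 = 0;
  for (int k = 0; k < n_trials; ++k) {
    w.M = lengths[k];
    if (w.M < 1) stop("empty trial");
    if (w.M + 1 > logG.ncol()) stop("logG has too few duration columns");
    w.set_caps(dcap, false);
    w.forward(logB, row0, logG);
    if (w.loglik == R_NegInf) {   // pruning removed every partitioning
      w.set_caps(dcap, true);
      w.forward(logB, row0, logG);
    }
    ll[k] = w.loglik;
    row0 += w.M;
  }
  return ll;
}

// [[Rcpp::export(name = ".dp_estep_batch")]]
List dp_estep_batch(NumericMatrix logB, IntegerVector lengths,
                    NumericMatrix logG, IntegerVector dcap) {
  int n_trials = lengths.size();
  int N = logB.ncol();
  int Dmax = logG.ncol() - 1;
  if (dcap.size() != N) stop("dcap must have one entry per state");
  NumericVector ll(n_trials);
  NumericMatrix gamma(logB.nrow(), N);
  NumericMatrix eta(N, Dmax + 1);
  TrialWork w;
  w.N = N;
  int row0 = 0;
  for (int k = 0; k < n_trials; ++k) {
    w.M = lengths[k];
    if (w.M < 1) stop("empty trial");
    if (w.M > Dmax) stop("logG has too few duration columns");
    w.set_caps(dcap, false);
    w.forward(logB, row0, logG);
    if (w.loglik == R_NegInf) {
      w.set_caps(dcap, true);
      w.forward(logB, row0, logG);
    }
    if (w.loglik == R_NegInf) stop("trial has zero likelihood");
    w.backward(logG);
    ll[k] = w.loglik;
    w.occupancy(gamma, row0);
    w.duration_posterior(eta, logG);
    row0 += w.M;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["eta"] = eta);
}

// [[Rcpp::export(name = ".dp_trial_durations")]]
NumericMatrix dp_trial_durations(NumericMatrix logB, NumericMatrix logG) {
  // per-state posterior duration distribution for one trial (rows: states,
  // columns: d = 0..M), each row summing to 1; no pruning here
  int M = logB.nrow(), N = logB.ncol();
  TrialWork w;
  w.N = N;
  w.M = M;
  IntegerVector full(N, M);
  w.set_caps(full, true);
  w.forward(logB, 0, logG);
  w.backward(logG);
  NumericMatrix eta(N, M + 1);
  w.duration_posterior(eta, logG);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int d = 0; d <= M; ++d) s += eta(i, d);
    if (s > 0) for (int d = 0; d <= M; ++d) eta(i, d) /= s;
  }
  return eta;
}
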