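#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a discrete HMM.  Observations are
// 1-based integer codes.  `A` and `B` may be sub-stochastic (variational
// geometric-mean parameters), so rows are never renormalised here; only the
// per-step scaling constant c_t is divided out.

static void forward_fill(const IntegerVector& obs, const NumericMatrix& A,
                         const NumericMatrix& B, const NumericVector& start,
                         bool transition_first, NumericMatrix& alpha,
                         NumericVector& c) {
  const int T = obs.size(), K = A.nrow();
  std::vector<double> pred(K);
  for (int t = 0; t < T; ++t) {
    if (t == 0 && !transition_first) {
      for (int k = 0; k < K; ++k) pred[k] = start[k];
    } else {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += (t == 0 ? start[j] : alpha(t - 1, j)) * A(j, k);
        pred[k] = s;
      }
    }
    const int o = obs[t] - 1;
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      const double v = B(k, o) * pred[k];
      alpha(t, k) = v;
      ct += v;
    }
    if (!(ct > 0.0))
      stop("observation at trial %d has probability zero under every state",
           t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    c[t] = ct;
  }
}

// [[Rcpp::export]]
List cpp_forward(IntegerVector obs, NumericMatrix A, NumericMatrix B,
                 NumericVector start, bool transition_first) {
  const int T = obs.size(), K = A.nrow();
  NumericMatrix alpha(T, K);
  NumericVector c(T);
  forward_fill(obs, A, B, start, transition_first, alpha, c);
  return List::create(_["alpha"] = alpha, _["c"] = c);
}

// Scaled backward messages for the last `depth` timesteps; row r of the
// returned matrix is time T - depth + r (1-based).  beta at the final time is
// all ones; each step divides by the forward scaling constant of the later
// time so that alpha * beta sums to one.
// [[Rcpp::export]]
NumericMatrix cpp_backward(IntegerVector obs, NumericMatrix A, NumericMatrix B,
                           NumericVector c, int depth) {
  const int T = obs.size(), K = A.nrow();
  NumericMatrix beta(depth, K);
  for (int k = 0; k < K; ++k) beta(depth - 1, k) = 1.0;
  for (int r = depth - 2; r >= 0; --r) {
    const int tnext = T - depth + r + 1;  // 0-based index of the later time
    const int o = obs[tnext] - 1;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(j, k) * B(k, o) * beta(r + 1, k);
      beta(r, j) = s / c[tnext];
    }
  }
  return beta;
}

// Full scaled forward-backward over a window: filtered messages, scaling
// constants, backward messages, smoothed marginals and (optionally) the
// dual-slice marginals xi.  Slice t of xi (1-based) is the joint over times
// (t-1, t); slice 1 links the start belief to time 1 and is only defined when
// transition_first is true (otherwise it is filled with NA).
// [[Rcpp::export]]
List cpp_fb(IntegerVector obs, NumericMatrix A, NumericMatrix B,
            NumericVector start, bool transition_first, bool want_xi) {
  const int T = obs.size(), K = A.nrow();
  NumericMatrix alpha(T, K);
  NumericVector c(T);
  forward_fill(obs, A, B, start, transition_first, alpha, c);
  NumericMatrix beta = cpp_backward(obs, A, B, c, T);

  NumericMatrix gamma(T, K);
  // beta at the final time is all-ones, so the smoothed marginal there IS the
  // filtered posterior; copy it rather than renormalising (keeps fixed-lag
  // n = 1 exactly equal to filtering).
  for (int k = 0; k < K; ++k) gamma(T - 1, k) = alpha(T - 1, k);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    if (!(s > 0.0))
      stop("smoothed marginal at trial %d is numerically degenerate", t + 1);
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

  List out = List::create(_["alpha"] = alpha, _["c"] = c, _["beta"] = beta,
                          _["gamma"] = gamma, _["loglik"] = loglik);
  if (want_xi) {
    NumericVector xi(Dimension(K, K, T));
    std::fill(xi.begin(), xi.end(), NA_REAL);
    const int t0 = transition_first ? 0 : 1;
    for (int t = t0; t < T; ++t) {
      const int o = obs[t] - 1;
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double bk = B(k, o) * beta(t, k) / c[t];
        for (int j = 0; j < K; ++j) {
          const double aprev = (t == 0) ? start[j] : alpha(t - 1, j);
          const double v = aprev * A(j, k) * bk;
          xi[t * K * K + k * K + j] = v;
          s += v;
        }
      }
      if (!(s > 0.0))
        stop("dual-slice marginal at trial %d is numerically degenerate",
             t + 1);
      for (int i = 0; i < K * K; ++i) xi[t * K * K + i] /= s;
    }
    out["xi"] = xi;
  }
  return out;
}
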