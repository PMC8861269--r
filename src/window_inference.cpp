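// Policy-window belief updating: the planner's hot loop.
// Gradient descent on variational free energy for the future time points of
// every enumerated policy simultaneously, with policies grouped by the
// action occupying each window slot so the message products run as dense
// matrix multiplies. Same update rule as the R reference path
// (state_prediction_error + belief_iteration), exercised against it in the
// test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline void softmax_cols(const mat& V, mat& S) {
  rowvec m = max(V, 0);
  S = exp(V.each_row() - m);
  rowvec s = sum(S, 0);
  S.each_row() /= s;
}

// lnB, lnBt: n x n x n_actions log transition tables (forward and
//            transposed-renormalized backward), already floored.
// anchor:    posterior state expectation at the current time point.
// pol:       depth x n_policies matrix of 1-based action indices.
// init_s:    n x n_policies x depth cube of initial beliefs per policy and
//            window slot (beliefs persist across planning cycles; pass
//            uniform to cold start).
// Returns converged window beliefs S (n x n_policies x depth) and, when
// record_trace, the per-iteration beliefs (n x n_policies*depth x n_iter,
// slot-major columns).
// [[Rcpp::export]]
Rcpp::List window_inference_cpp(const arma::cube& lnB, const arma::cube& lnBt,
                                const arma::vec& anchor, const arma::imat& pol,
                                const arma::cube& init_s,
                                int n_iter, double step, bool record_trace) {
  const double LOGF = std::exp(-32.0);
  const int n = lnB.n_rows, n_act = lnB.n_slices;
  const int depth = pol.n_rows, npol = pol.n_cols;

  std::vector<std::vector<uvec>> grp(depth);
  for (int d = 0; d < depth; ++d) {
    grp[d].resize(n_act);
    irowvec row = pol.row(d);
    for (int u = 0; u < n_act; ++u) grp[d][u] = find(row.t() == u + 1);
  }

  cube S(n, npol, depth), V(n, npol, depth);
  for (int d = 0; d < depth; ++d) {
    mat s0 = clamp(init_s.slice(d), LOGF, 1.0);
    rowvec cs = sum(s0, 0);
    s0.each_row() /= cs;
    S.slice(d) = s0;
    V.slice(d) = log(s0);
  }
  cube trace;
  if (record_trace) trace.set_size(n, npol * depth, n_iter);

  std::vector<vec> first_msg(n_act);
  for (int u = 0; u < n_act; ++u) first_msg[u] = lnB.slice(u) * anchor;

  mat eps(n, npol), Sd(n, npol);
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < depth; ++d) {
      // forward message through the slot-d action
      if (d == 0) {
        for (int u = 0; u < n_act; ++u) {
          const uvec& idx = grp[0][u];
          if (idx.n_elem) eps.cols(idx) = repmat(first_msg[u], 1, idx.n_elem);
        }
      } else {
        for (int u = 0; u < n_act; ++u) {
          const uvec& idx = grp[d][u];
          if (idx.n_elem) eps.cols(idx) = lnB.slice(u) * S.slice(d - 1).cols(idx);
        }
      }
      // backward message from slot d+1 (none at the window end)
      if (d < depth - 1) {
        for (int u = 0; u < n_act; ++u) {
          const uvec& idx = grp[d + 1][u];
          if (idx.n_elem) eps.cols(idx) += lnBt.slice(u) * S.slice(d + 1).cols(idx);
        }
      }
      eps -= log(clamp(S.slice(d), LOGF, 1.0));
      eps.each_row() -= mean(eps, 0);
      V.slice(d) += step * eps;
      softmax_cols(V.slice(d), Sd);
      S.slice(d) = Sd;
    }
    if (record_trace)
      for (int d = 0; d < depth; ++d)
        trace.slice(it).cols(d * npol, (d + 1) * npol - 1) = S.slice(d);
  }
  return Rcpp::List::create(Rcpp::Named("S") = S,
                            Rcpp::Named("trace") = trace);
}
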