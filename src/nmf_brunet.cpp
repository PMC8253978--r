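#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence D(V || WH), with 0*log(0) = 0.
static double kl_divergence(const mat& V, const mat& WH, double eps) {
  double d = 0.0;
  const uword n = V.n_elem;
  const double* v = V.memptr();
  const double* wh = WH.memptr();
  for (uword i = 0; i < n; ++i) {
    double w = wh[i] < eps ? eps : wh[i];
    if (v[i] > 0.0) d += v[i] * std::log(v[i] / w) - v[i];
    d += w;
  }
  return d;
}

// Canonical cluster labels from H: argmax metagene per column, relabeled in
// order of first appearance so two labelings describe the same partition iff
// the canonical vectors are identical.
static uvec canonical_labels(const mat& H) {
  const uword n = H.n_cols;
  uvec lab(n);
  std::vector<int> remap(H.n_rows, -1);
  int next = 0;
  for (uword j = 0; j < n; ++j) {
    uword r = H.col(j).index_max();
    if (remap[r] < 0) remap[r] = next++;
    lab(j) = static_cast<uword>(remap[r]);
  }
  return lab;
}

// Multiplicative KL updates (Brunet-style NMF). Stops when the sample
// connectivity (partition from dominant metagenes) is unchanged for
// `patience` consecutive checks made every `check_every` iterations, or at
// max_iter. Divergence is recorded at every check.
// [[Rcpp::export]]
Rcpp::List nmf_brunet_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                          int max_iter, int check_every, int patience,
                          double eps) {
  std::vector<double> trace;
  uvec prev = canonical_labels(H);
  int stable = 0;
  bool converged = false;
  int iter = 0;

  mat WH(V.n_rows, V.n_cols), Q(V.n_rows, V.n_cols);
  const uword nel = V.n_elem;
  // Q = V / (WH + eps), single fused pass over the big arrays
  auto ratio = [&]() {
    const double* v = V.memptr();
    const double* wh = WH.memptr();
    double* q = Q.memptr();
    for (uword i = 0; i < nel; ++i) q[i] = v[i] / (wh[i] + eps);
  };
  for (iter = 1; iter <= max_iter; ++iter) {
    WH = W * H;
    ratio();
    H %= (W.t() * Q);
    H.each_col() /= (sum(W, 0).t() + eps);

    WH = W * H;
    ratio();
    W %= (Q * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);

    if (iter % check_every == 0) {
      if (!W.is_finite() || !H.is_finite())
        Rcpp::stop("NaN/Inf in multiplicative update at iteration %d "
                   "(epsilon guard insufficient for this input)", iter);
      trace.push_back(kl_divergence(V, W * H, eps));
      uvec lab = canonical_labels(H);
      if (lab.n_elem == prev.n_elem && all(lab == prev)) {
        if (++stable >= patience) { converged = true; break; }
      } else {
        stable = 0;
        prev = lab;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;
  double final_div = kl_divergence(V, W * H, eps);
  if (trace.empty() || trace.back() != final_div) trace.push_back(final_div);

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("divergence") = final_div,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
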