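// Cross-validated shrinkage-LDA accuracy, the inner loop of the
// time-resolved decoding analyses.  Data layout: cube X with dimensions
// channels x trials x timepoints, binary trial labels, and a list of
// train/test folds (1-based trial indices).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Ledoit-Wolf shrinkage toward scaled identity; Xc holds centred
// observations as columns (p x n).
static mat lw_shrink(const mat& Xc) {
  const double p = Xc.n_rows, n = Xc.n_cols;
  mat S = (Xc * Xc.t()) / n;
  double mu = trace(S) / p;
  double S2 = accu(square(S));
  double d2 = (S2 - p * mu * mu) / p;
  mat SX = S * Xc;
  double sum_dev = 0.0;
  for (uword i = 0; i < Xc.n_cols; ++i) {
    double xx = dot(Xc.col(i), Xc.col(i));
    double xSx = dot(Xc.col(i), SX.col(i));
    sum_dev += xx * xx - 2.0 * xSx + S2;
  }
  double b2 = sum_dev / (n * n) / p;
  if (b2 > d2) b2 = d2;
  double lambda = (d2 > 0.0) ? b2 / d2 : 1.0;
  mat Sig = (1.0 - lambda) * S;
  Sig.diag() += lambda * mu;
  return Sig;
}

// [[Rcpp::export]]
arma::mat cpp_cv_lda(const arma::cube& X, const arma::ivec& labels,
                     const Rcpp::List& folds) {
  const uword n_time = X.n_slices, n_folds = folds.size();
  mat acc(n_folds, n_time);
  std::vector<uvec> train_idx(n_folds), test_idx(n_folds);
  for (uword f = 0; f < n_folds; ++f) {
    Rcpp::List fold = folds[f];
    train_idx[f] = Rcpp::as<uvec>(fold["train"]) - 1;
    test_idx[f] = Rcpp::as<uvec>(fold["test"]) - 1;
  }
  for (uword t = 0; t < n_time; ++t) {
    const mat M = X.slice(t);  // channels x trials
    for (uword f = 0; f < n_folds; ++f) {
      const uvec& tr = train_idx[f];
      const uvec& te = test_idx[f];
      uvec y_tr(tr.n_elem);
      for (uword i = 0; i < tr.n_elem; ++i) y_tr[i] = labels[tr[i]] > 0;
      const uvec i1 = tr(find(y_tr == 1)), i0 = tr(find(y_tr == 0));
      if (i0.n_elem < 2 || i1.n_elem < 2)
        Rcpp::stop("each class needs >= 2 training trials in every fold");
      vec m0 = mean(M.cols(i0), 1), m1 = mean(M.cols(i1), 1);
      mat Xc(M.n_rows, tr.n_elem);
      Xc.cols(0, i0.n_elem - 1) = M.cols(i0);
      Xc.cols(0, i0.n_elem - 1).each_col() -= m0;
      Xc.cols(i0.n_elem, tr.n_elem - 1) = M.cols(i1);
      Xc.cols(i0.n_elem, tr.n_elem - 1).each_col() -= m1;
      mat Sig = lw_shrink(Xc);
      vec w;
      if (!solve(w, Sig, m1 - m0, solve_opts::likely_sympd + solve_opts::no_approx))
        w = pinv(Sig) * (m1 - m0);
      const double thr = 0.5 * dot(w, m0 + m1);
      uword correct = 0;
      for (uword i = 0; i < te.n_elem; ++i) {
        const bool pred1 = dot(M.col(te[i]), w) > thr;
        if (pred1 == (labels[te[i]] > 0)) ++correct;
      }
      acc(f, t) = double(correct) / te.n_elem;
    }
  }
  return acc;
}
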