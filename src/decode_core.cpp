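// Per-timepoint LDA decoding core. Mirrors the R reference fit_lda():
// pooled within-class covariance with pseudo-inverse fallback, empirical
// priors, argmax prediction with earliest-class tie break.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
using namespace arma;

static double lda_accuracy_t(const mat& xtr, const uvec& y, const mat& xte,
                             const uvec& yte, int n_class) {
  const int n = xtr.n_rows;
  const int p = xtr.n_cols;
  mat m(p, n_class, fill::zeros);
  vec nc(n_class, fill::zeros);
  for (int i = 0; i < n; ++i) {
    m.col(y[i]) += xtr.row(i).t();
    nc[y[i]] += 1.0;
  }
  for (int c = 0; c < n_class; ++c) m.col(c) /= nc[c];
  mat g = xtr.t() * xtr;
  for (int c = 0; c < n_class; ++c) g -= nc[c] * (m.col(c) * m.col(c).t());
  g /= (double)(n - n_class);
  mat si;
  if (!inv_sympd(si, g)) {
    // rank-deficient pooled covariance: eigen pseudo-inverse
    vec ev;
    mat vv;
    eig_sym(ev, vv, symmatu(g));
    double tol = std::max(ev.max(), 0.0) * p *
      std::numeric_limits<double>::epsilon();
    si.zeros(p, p);
    for (int j = 0; j < p; ++j) {
      if (ev[j] > tol) si += (vv.col(j) * vv.col(j).t()) / ev[j];
    }
  }
  mat w = si * m;
  rowvec b(n_class);
  for (int c = 0; c < n_class; ++c) {
    b[c] = -0.5 * dot(m.col(c), w.col(c)) + std::log(nc[c] / (double)n);
  }
  mat s = xte * w;
  s.each_row() += b;
  int correct = 0;
  for (size_t i = 0; i < s.n_rows; ++i) {
    double best = s(i, 0);
    int bi = 0;
    for (int c = 1; c < n_class; ++c) {
      if (s(i, c) > best) { best = s(i, c); bi = c; }
    }
    if ((unsigned)bi == yte[i]) ++correct;
  }
  return (double)correct / (double)s.n_rows;
}

// Accuracy over time for one fold: train/test cubes are
// [trials x channels x samples]; y / yte are 0-based class indices.
// [[Rcpp::export]]
arma::vec lda_timecourse_cpp(const arma::cube& train, const arma::uvec& y,
                             const arma::cube& test, const arma::uvec& yte,
                             int n_class) {
  const int n_t = train.n_slices;
  vec acc(n_t);
  for (int t = 0; t < n_t; ++t) {
    acc[t] = lda_accuracy_t(train.slice(t), y, test.slice(t), yte, n_class);
  }
  return acc;
}

// Searchlight accuracies for one fold: for each channel, decode on the
// channel subset given by `neighbors` (list of 0-based index vectors).
// Returns channels x samples.
// [[Rcpp::export]]
arma::mat lda_searchlight_cpp(const arma::cube& train, const arma::uvec& y,
                              const arma::cube& test, const arma::uvec& yte,
                              const Rcpp::List& neighbors, int n_class) {
  const int n_t = train.n_slices;
  const int n_ch = neighbors.size();
  mat acc(n_ch, n_t);
  std::vector<uvec> idx(n_ch);
  for (int ch = 0; ch < n_ch; ++ch) idx[ch] = Rcpp::as<uvec>(neighbors[ch]);
  for (int t = 0; t < n_t; ++t) {
    const mat& xtr = train.slice(t);
    const mat& xte = test.slice(t);
    for (int ch = 0; ch < n_ch; ++ch) {
      acc(ch, t) = lda_accuracy_t(xtr.cols(idx[ch]), y, xte.cols(idx[ch]),
                                  yte, n_class);
    }
  }
  return acc;
}
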