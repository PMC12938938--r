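// L1-metric kNN with deterministic tie handling, and the INCA subset sweep
// (incremental L1 distance accumulation over nested ranked-prefix subsets).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// kNN with L1 distance. Neighbors ordered by (distance, training index);
// vote ties broken by the best-ranked neighbor carrying the tied label.
// y is 0-based; returns 0-based predictions.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_knn_l1(const arma::mat& Xtr, Rcpp::IntegerVector y,
                               const arma::mat& Xte, int k) {
  const int ntr = Xtr.n_rows, nte = Xte.n_rows;
  if (k > ntr) k = ntr;
  int K = 0;
  for (int i = 0; i < ntr; ++i) K = std::max(K, y[i] + 1);
  Rcpp::IntegerVector pred(nte);
  std::vector<int> ord(ntr);
  for (int q = 0; q < nte; ++q) {
    rowvec xq = Xte.row(q);
    vec d(ntr);
    for (int i = 0; i < ntr; ++i)
      d(i) = accu(abs(Xtr.row(i) - xq));
    for (int i = 0; i < ntr; ++i) ord[i] = i;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) {
                        if (d(a) != d(b)) return d(a) < d(b);
                        return a < b;
                      });
    std::vector<int> votes(K, 0), first(K, ntr + 1);
    for (int j = 0; j < k; ++j) {
      const int lab = y[ord[j]];
      votes[lab]++;
      if (first[lab] > j) first[lab] = j;
    }
    int best = -1;
    for (int lab = 0; lab < K; ++lab) {
      if (votes[lab] == 0) continue;
      if (best < 0 || votes[lab] > votes[best] ||
          (votes[lab] == votes[best] && first[lab] < first[best]))
        best = lab;
    }
    pred[q] = best;
  }
  return pred;
}

// Misclassification curve over nested top-a subsets of ranked features.
// X: standardized training matrix, y/fold/id 0-based. For each subset size
// a in [iv, fv] the error is the k-nearest-neighbour (L1) cross-validated
// misclassification rate under the supplied fold plan. Distances are
// accumulated incrementally since top-a subsets are nested.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_inca_sweep(const arma::mat& X, Rcpp::IntegerVector y,
                                   Rcpp::IntegerVector id, int iv, int fv,
                                   Rcpp::IntegerVector fold, int k) {
  const int N = X.n_rows;
  int K = 0;
  for (int i = 0; i < N; ++i) K = std::max(K, y[i] + 1);
  mat D(N, N, fill::zeros);
  Rcpp::NumericVector mcv(fv - iv + 1);
  std::vector<int> ord(N);
  for (int a = 1; a <= fv; ++a) {
    const vec xc = X.col(id[a - 1]);
    for (int j = 0; j < N; ++j)
      D.col(j) += abs(xc - xc(j));
    if (a < iv) continue;
    int errs = 0;
    for (int i = 0; i < N; ++i) {
      if (k == 1) {
        int best = -1; double bd = datum::inf;
        for (int j = 0; j < N; ++j) {
          if (fold[j] == fold[i]) continue;
          if (D(j, i) < bd) { bd = D(j, i); best = j; }
        }
        if (best < 0 || y[best] != y[i]) ++errs;
      } else {
        int m = 0;
        for (int j = 0; j < N; ++j)
          if (fold[j] != fold[i]) ord[m++] = j;
        const int kk = std::min(k, m);
        std::partial_sort(ord.begin(), ord.begin() + kk, ord.begin() + m,
                          [&](int a2, int b2) {
                            if (D(a2, i) != D(b2, i)) return D(a2, i) < D(b2, i);
                            return a2 < b2;
                          });
        std::vector<int> votes(K, 0), first(K, N + 1);
        for (int j = 0; j < kk; ++j) {
          const int lab = y[ord[j]];
          votes[lab]++;
          if (first[lab] > j) first[lab] = j;
        }
        int best = -1;
        for (int lab = 0; lab < K; ++lab) {
          if (votes[lab] == 0) continue;
          if (best < 0 || votes[lab] > votes[best] ||
              (votes[lab] == votes[best] && first[lab] < first[best]))
            best = lab;
        }
        if (best != y[i]) ++errs;
      }
    }
    mcv[a - iv] = (double)errs / N;
  }
  return mcv;
}
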