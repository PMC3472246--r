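#include <Rcpp.h>
using namespace Rcpp;

// Per-gene leave-one-out KNN accuracy over a training set.
//
// X: n_train x n_genes matrix of log2 fold-changes.
// labels: 0/1 group codes, length n_train.
// K: neighbour count (odd, so two-class votes cannot tie).
//
// For each gene and each held-out mutant, the K nearest other training
// mutants by absolute fold-change difference vote on its group; distance
// ties keep the earlier mutant in input order. Returns the fraction of
// training mutants classified correctly, per gene.
// [[Rcpp::export]]
NumericVector loocv_knn_accuracy(NumericMatrix X, IntegerVector labels,
                                 int K) {
  const int n = X.nrow();
  const int G = X.ncol();
  if (labels.size() != n) stop("labels must match rows of X");
  if (K >= n) stop("K must be smaller than the training-set size");
  NumericVector acc(G);
  std::vector<double> best_d(K);
  std::vector<int> best_j(K);

  for (int g = 0; g < G; ++g) {
    int correct = 0;
    const double *col = &X(0, g);
    for (int i = 0; i < n; ++i) {
      int filled = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double d = std::fabs(col[j] - col[i]);
        if (filled < K) {
          // insertion keeping (distance, index) ascending; strict
          // comparison preserves earlier indices on ties
          int pos = filled;
          while (pos > 0 && best_d[pos - 1] > d) {
            best_d[pos] = best_d[pos - 1];
            best_j[pos] = best_j[pos - 1];
            --pos;
          }
          best_d[pos] = d;
          best_j[pos] = j;
          ++filled;
        } else if (d < best_d[K - 1]) {
          int pos = K - 1;
          while (pos > 0 && best_d[pos - 1] > d) {
            best_d[pos] = best_d[pos - 1];
            best_j[pos] = best_j[pos - 1];
            --pos;
          }
          best_d[pos] = d;
          best_j[pos] = j;
        }
      }
      int votes = 0;
      for (int k = 0; k < K; ++k) votes += labels[best_j[k]];
      int pred = (2 * votes > K) ? 1 : 0;
      if (pred == labels[i]) ++correct;
    }
    acc[g] = static_cast<double>(correct) / n;
  }
  return acc;
}
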