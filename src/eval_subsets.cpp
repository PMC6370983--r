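// Hot loop of the semi-exhaustive search: evaluate many feature subsets by
// stratified-CV KNN AUC. Semantics mirror the R reference route
// (evaluate_subset): correlation distance (|u - v| for single-feature
// subsets, d = 1 when either vector has zero variance), neighbour ties
// broken by ascending training-row index, Mann-Whitney AUC with half-credit
// ties.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct FoldView {
  std::vector<double> X;  // column-major n x p normalized matrix
  int n = 0, p = 0;
  std::vector<int> train, test;  // 0-based row indices
};

// Mann-Whitney AUC with 0.5 tie credit; assumes both classes present.
double pair_auc(const std::vector<double>& s, const std::vector<int>& y) {
  double wins = 0.0;
  long npos = 0, nneg = 0;
  const int n = static_cast<int>(s.size());
  for (int i = 0; i < n; ++i) (y[i] == 1 ? npos : nneg)++;
  for (int i = 0; i < n; ++i) {
    if (y[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (y[j] == 1) continue;
      if (s[i] > s[j]) wins += 1.0;
      else if (s[i] == s[j]) wins += 0.5;
    }
  }
  return wins / (static_cast<double>(npos) * static_cast<double>(nneg));
}

}  // namespace

// folds: list of list(Xn = n x p numeric matrix, train = 0-based int vec,
//        test = 0-based int vec); y: full-length 0/1 labels;
// subsets: m x nsub 0-based column-index matrix; k: neighbour count.
// Returns nsub x nfolds matrix of fold AUCs.
// [[Rcpp::export]]
NumericMatrix eval_subsets_cpp(List folds, IntegerVector y,
                               IntegerMatrix subsets, int k) {
  const int nfolds = folds.size();
  const int m = subsets.nrow();
  const int nsub = subsets.ncol();

  std::vector<FoldView> fv(nfolds);
  for (int f = 0; f < nfolds; ++f) {
    List fl = folds[f];
    NumericMatrix Xn = fl["Xn"];
    fv[f].n = Xn.nrow();
    fv[f].p = Xn.ncol();
    fv[f].X.assign(Xn.begin(), Xn.end());
    fv[f].train = as<std::vector<int>>(fl["train"]);
    fv[f].test = as<std::vector<int>>(fl["test"]);
    if (k > static_cast<int>(fv[f].train.size()))
      stop("eval_subsets_cpp: k exceeds training-fold size");
  }
  std::vector<int> yy = as<std::vector<int>>(y);

  NumericMatrix out(nsub, nfolds);

  // scratch buffers reused across subsets
  std::vector<double> cent;   // centered rows on the subset, n x m
  std::vector<double> rsd;    // row "sd" (root sum of squared deviations)
  std::vector<double> bestd(k);
  std::vector<int> besty(k);

  for (int s = 0; s < nsub; ++s) {
    const int* sub = &subsets(0, s);
    for (int f = 0; f < nfolds; ++f) {
      const FoldView& v = fv[f];
      const int n = v.n;
      cent.assign(static_cast<size_t>(n) * m, 0.0);
      rsd.assign(n, 0.0);
      if (m >= 2) {
        for (int r = 0; r < n; ++r) {
          double mu = 0.0;
          for (int c = 0; c < m; ++c) mu += v.X[sub[c] * n + r];
          mu /= m;
          double ss = 0.0;
          for (int c = 0; c < m; ++c) {
            const double d = v.X[sub[c] * n + r] - mu;
            cent[static_cast<size_t>(r) * m + c] = d;
            ss += d * d;
          }
          rsd[r] = std::sqrt(ss);
        }
      } else {
        for (int r = 0; r < n; ++r) cent[r] = v.X[sub[0] * n + r];
      }

      const int nte = static_cast<int>(v.test.size());
      const int ntr = static_cast<int>(v.train.size());
      std::vector<double> scores(nte);
      std::vector<int> ylab(nte);
      for (int t = 0; t < nte; ++t) {
        const int te = v.test[t];
        int filled = 0;
        for (int u = 0; u < ntr; ++u) {
          const int tr = v.train[u];
          double d;
          if (m == 1) {
            d = std::fabs(cent[te] - cent[tr]);
          } else if (rsd[te] > 0.0 && rsd[tr] > 0.0) {
            double dot = 0.0;
            const double* a = &cent[static_cast<size_t>(te) * m];
            const double* b = &cent[static_cast<size_t>(tr) * m];
            for (int c = 0; c < m; ++c) dot += a[c] * b[c];
            d = 1.0 - dot / (rsd[te] * rsd[tr]);
          } else {
            d = 1.0;
          }
          // maintain k best (d, index); iteration order = ascending index,
          // so on ties the earlier index stays ahead (strict < to displace)
          if (filled < k) {
            int pos = filled;
            while (pos > 0 && bestd[pos - 1] > d) {
              bestd[pos] = bestd[pos - 1];
              besty[pos] = besty[pos - 1];
              --pos;
            }
            bestd[pos] = d;
            besty[pos] = yy[tr];
            ++filled;
          } else if (d < bestd[k - 1]) {
            int pos = k - 1;
            while (pos > 0 && bestd[pos - 1] > d) {
              bestd[pos] = bestd[pos - 1];
              besty[pos] = besty[pos - 1];
              --pos;
            }
            bestd[pos] = d;
            besty[pos] = yy[tr];
          }
        }
        double vote = 0.0;
        for (int b = 0; b < k; ++b) vote += besty[b];
        scores[t] = vote / k;
        ylab[t] = yy[te];
      }
      out(s, f) = pair_auc(scores, ylab);
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
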