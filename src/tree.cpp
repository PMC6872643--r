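#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

double entropyFromCounts(const std::vector<int>& cnt, int total) {
  if (total <= 0) return 0.0;
  double h = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    if (cnt[k] > 0) {
      double p = static_cast<double>(cnt[k]) / total;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// Greedy binary CART-style builder maximizing information gain.
// Thresholds are midpoints between consecutive distinct values; "<= goes left".
// Ties broken toward the lowest feature index, then lowest threshold (scan order).
struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;  // 0-based class codes
  int K, minLeaf, maxDepth;
  std::vector<int> feature, nSamples, leftChild, rightChild, leafClass;
  std::vector<double> threshold, gain;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int minLeaf_,
          int maxDepth_)
      : X(X_), y(y_), K(K_), minLeaf(minLeaf_), maxDepth(maxDepth_) {}

  int addNode(int n) {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    nSamples.push_back(n);
    gain.push_back(0.0);
    leftChild.push_back(-1);
    rightChild.push_back(-1);
    leafClass.push_back(-1);
    return static_cast<int>(feature.size()) - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    const int n = static_cast<int>(idx.size());
    const int node = addNode(n);
    std::vector<int> cnt(K, 0);
    for (int i : idx) cnt[y[i]]++;
    const double hParent = entropyFromCounts(cnt, n);
    const bool canSplit =
        hParent > 0.0 && n >= 2 * minLeaf && (maxDepth <= 0 || depth < maxDepth);

    int bestF = -1;
    double bestGain = 0.0, bestThr = 0.0;
    if (canSplit) {
      const int p = X.ncol();
      std::vector<std::pair<double, int> > vals;
      std::vector<int> lc(K), rc(K);
      std::vector<int> buckets;
      for (int j = 0; j < p; ++j) {
        // counting-bucket fast path for small nonnegative integer counts
        // (the common case for annotation tables); identical splits and
        // midpoint thresholds to the generic sort path below
        double mn = X(idx[0], j), mx = mn;
        bool smallInt = true;
        for (int i : idx) {
          const double v = X(i, j);
          if (v < mn) mn = v;
          if (v > mx) mx = v;
          if (v != std::floor(v)) smallInt = false;
        }
        if (mn == mx) continue;
        if (smallInt && mx - mn <= 64.0) {
          const int V = static_cast<int>(mx - mn) + 1;
          buckets.assign(static_cast<size_t>(V) * K, 0);
          for (int i : idx)
            buckets[(static_cast<int>(X(i, j) - mn)) * K + y[i]]++;
          std::fill(lc.begin(), lc.end(), 0);
          int nl = 0;
          double prevVal = mn;
          for (int b = 0; b < V - 1; ++b) {
            int bn_ = 0;
            for (int k = 0; k < K; ++k) {
              lc[k] += buckets[b * K + k];
              bn_ += buckets[b * K + k];
            }
            nl += bn_;
            if (bn_ == 0) continue;  // value b+mn not observed
            prevVal = mn + b;
            // next observed value
            int b2 = b + 1;
            while (b2 < V) {
              int c2 = 0;
              for (int k = 0; k < K; ++k) c2 += buckets[b2 * K + k];
              if (c2 > 0) break;
              ++b2;
            }
            if (b2 >= V) break;
            if (nl < minLeaf || n - nl < minLeaf) continue;
            for (int k = 0; k < K; ++k) rc[k] = cnt[k] - lc[k];
            const double g =
                hParent - (nl * entropyFromCounts(lc, nl) +
                           (n - nl) * entropyFromCounts(rc, n - nl)) /
                              n;
            if (g > bestGain + 1e-12) {
              bestGain = g;
              bestF = j;
              bestThr = 0.5 * (prevVal + (mn + b2));
            }
          }
          continue;
        }
        vals.clear();
        vals.reserve(n);
        for (int i : idx) vals.push_back(std::make_pair(X(i, j), y[i]));
        std::sort(vals.begin(), vals.end());
        std::fill(lc.begin(), lc.end(), 0);
        for (int i = 1; i < n; ++i) {
          lc[vals[i - 1].second]++;
          if (vals[i].first == vals[i - 1].first) continue;
          if (i < minLeaf || n - i < minLeaf) continue;
          for (int k = 0; k < K; ++k) rc[k] = cnt[k] - lc[k];
          const double g =
              hParent - (i * entropyFromCounts(lc, i) +
                         (n - i) * entropyFromCounts(rc, n - i)) /
                            n;
          if (g > bestGain + 1e-12) {
            bestGain = g;
            bestF = j;
            bestThr = 0.5 * (vals[i - 1].first + vals[i].first);
          }
        }
      }
    }

    if (bestF < 0 || bestGain <= 1e-12) {
      int best = 0;
      for (int k = 1; k < K; ++k)
        if (cnt[k] > cnt[best]) best = k;
      leafClass[node] = best;
      return node;
    }

    feature[node] = bestF;
    threshold[node] = bestThr;
    gain[node] = bestGain;
    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx) {
      if (X(i, bestF) <= bestThr)
        li.push_back(i);
      else
        ri.push_back(i);
    }
    leftChild[node] = build(li, depth + 1);
    rightChild[node] = build(ri, depth + 1);
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, int K, int minLeaf,
                   int maxDepth) {
  const int n = X.nrow();
  Builder b(X, y, K, minLeaf, maxDepth);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  b.build(idx, 0);
  const int m = static_cast<int>(b.feature.size());
  IntegerVector feature(m), nSamples(m), left(m), right(m), leafClass(m);
  NumericVector threshold(m), gain(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = b.feature[i] < 0 ? NA_INTEGER : b.feature[i] + 1;
    nSamples[i] = b.nSamples[i];
    left[i] = b.leftChild[i] < 0 ? NA_INTEGER : b.leftChild[i] + 1;
    right[i] = b.rightChild[i] < 0 ? NA_INTEGER : b.rightChild[i] + 1;
    leafClass[i] = b.leafClass[i] < 0 ? NA_INTEGER : b.leafClass[i] + 1;
    threshold[i] = b.threshold[i];
    gain[i] = b.gain[i];
  }
  return List::create(
      Named("feature") = feature, Named("threshold") = threshold,
      Named("n") = nSamples, Named("gain") = gain, Named("left") = left,
      Named("right") = right, Named("leafClass") = leafClass);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector leafClass, NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      const int j = feature[node] - 1;
      node = (X(i, j) <= threshold[node]) ? left[node] - 1 : right[node] - 1;
    }
    out[i] = leafClass[node];
  }
  return out;
}
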