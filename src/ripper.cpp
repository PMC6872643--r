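#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Greedy FOIL-gain rule growth over numeric <=/>= conditions.
// Candidate thresholds are the observed feature values among currently covered
// rows. Tie-breaking: lowest feature index, ">=" before "<=", lowest threshold
// (guaranteed by scan order plus strict-improvement replacement).
// Growth stops when the rule covers no negatives or no condition has positive
// gain. `init` gives the initially covered rows (all TRUE for a fresh rule;
// a grown rule's coverage when revising an existing rule).
// [[Rcpp::export]]
List cpp_grow_rule(NumericMatrix X, LogicalVector pos, LogicalVector init) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<char> covered(n);
  int p0 = 0, n0 = 0;
  for (int i = 0; i < n; ++i) {
    covered[i] = init[i] ? 1 : 0;
    if (covered[i]) {
      if (pos[i])
        p0++;
      else
        n0++;
    }
  }
  std::vector<int> condF, condOp;  // op: 1 = ">=", 2 = "<="
  std::vector<double> condT;
  const double eps = 1e-12;

  while (p0 > 0 && n0 > 0) {
    const double base = std::log2(static_cast<double>(p0) / (p0 + n0));
    double bestGain = eps, bestThr = 0.0;
    int bestF = -1, bestOp = 0, bp = 0, bn = 0;
    std::vector<std::pair<double, int> > v;
    std::vector<int> bposv, bnegv;
    for (int j = 0; j < p; ++j) {
      // counting-bucket fast path for small nonnegative integer counts;
      // identical candidates and tie order to the generic sort path below
      double mn = 0, mx = 0;
      bool smallInt = true, first = true;
      for (int i = 0; i < n; ++i) {
        if (!covered[i]) continue;
        const double val = X(i, j);
        if (first) {
          mn = mx = val;
          first = false;
        } else {
          if (val < mn) mn = val;
          if (val > mx) mx = val;
        }
        if (val != std::floor(val)) smallInt = false;
      }
      if (mn == mx) continue;
      if (smallInt && mx - mn <= 256.0) {
        const int V = static_cast<int>(mx - mn) + 1;
        bposv.assign(V, 0);
        bnegv.assign(V, 0);
        for (int i = 0; i < n; ++i) {
          if (!covered[i]) continue;
          const int b = static_cast<int>(X(i, j) - mn);
          if (pos[i])
            bposv[b]++;
          else
            bnegv[b]++;
        }
        // ">= t" over observed values ascending, skipping the minimum
        int cp = p0, cn = n0;  // coverage of ">= current value"
        for (int b = 0; b < V; ++b) {
          if (b > 0 && (bposv[b] > 0 || bnegv[b] > 0)) {
            if (cp > 0) {
              const double g =
                  cp * (std::log2(static_cast<double>(cp) / (cp + cn)) - base);
              if (g > bestGain + eps) {
                bestGain = g;
                bestF = j;
                bestOp = 1;
                bestThr = mn + b;
                bp = cp;
                bn = cn;
              }
            }
          }
          cp -= bposv[b];
          cn -= bnegv[b];
        }
        // "<= t" over observed values ascending, skipping the maximum
        cp = 0;
        cn = 0;
        for (int b = 0; b < V - 1; ++b) {
          cp += bposv[b];
          cn += bnegv[b];
          if (bposv[b] == 0 && bnegv[b] == 0) continue;
          if (cp > 0) {
            const double g =
                cp * (std::log2(static_cast<double>(cp) / (cp + cn)) - base);
            if (g > bestGain + eps) {
              bestGain = g;
              bestF = j;
              bestOp = 2;
              bestThr = mn + b;
              bp = cp;
              bn = cn;
            }
          }
        }
        continue;
      }
      v.clear();
      v.reserve(p0 + n0);
      for (int i = 0; i < n; ++i)
        if (covered[i]) v.push_back(std::make_pair(X(i, j), pos[i] ? 1 : 0));
      std::sort(v.begin(), v.end());
      const int m = static_cast<int>(v.size());
      std::vector<int> prefPos(m + 1, 0);
      for (int i = 0; i < m; ++i) prefPos[i + 1] = prefPos[i] + v[i].second;
      // ">= t" for each distinct t except the minimum (which is a no-op)
      int i = 0;
      while (i < m) {
        const double t = v[i].first;
        int j2 = i;
        while (j2 < m && v[j2].first == t) ++j2;
        if (i > 0) {
          const int pp = prefPos[m] - prefPos[i];
          const int nn = (m - i) - pp;
          if (pp > 0) {
            const double g =
                pp * (std::log2(static_cast<double>(pp) / (pp + nn)) - base);
            if (g > bestGain + eps) {
              bestGain = g;
              bestF = j;
              bestOp = 1;
              bestThr = t;
              bp = pp;
              bn = nn;
            }
          }
        }
        i = j2;
      }
      // "<= t" for each distinct t except the maximum
      i = 0;
      while (i < m) {
        const double t = v[i].first;
        int j2 = i;
        while (j2 < m && v[j2].first == t) ++j2;
        if (j2 < m) {
          const int pp = prefPos[j2];
          const int nn = j2 - pp;
          if (pp > 0) {
            const double g =
                pp * (std::log2(static_cast<double>(pp) / (pp + nn)) - base);
            if (g > bestGain + eps) {
              bestGain = g;
              bestF = j;
              bestOp = 2;
              bestThr = t;
              bp = pp;
              bn = nn;
            }
          }
        }
        i = j2;
      }
    }
    if (bestF < 0) break;
    condF.push_back(bestF + 1);
    condOp.push_back(bestOp);
    condT.push_back(bestThr);
    for (int i = 0; i < n; ++i) {
      if (!covered[i]) continue;
      const double x = X(i, bestF);
      const bool keep = (bestOp == 1) ? (x >= bestThr) : (x <= bestThr);
      if (!keep) covered[i] = 0;
    }
    p0 = bp;
    n0 = bn;
  }

  const int k = static_cast<int>(condF.size());
  CharacterVector ops(k);
  for (int i = 0; i < k; ++i) ops[i] = (condOp[i] == 1) ? ">=" : "<=";
  LogicalVector cov(n);
  for (int i = 0; i < n; ++i) cov[i] = covered[i] != 0;
  return List::create(Named("feature") = IntegerVector(condF.begin(), condF.end()),
                      Named("op") = ops,
                      Named("threshold") = NumericVector(condT.begin(), condT.end()),
                      Named("covered") = cov, Named("p") = p0, Named("n") = n0);
}
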