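// Tree-pattern signatures and permutation testing for coevolving-pair
// detection. A column's signature is the partition of the tips into maximal
// monophyletic blocks of uniform (reduced) state; pair agreement is one minus
// the normalized transfer distance between the two partitions, computed
// exactly by optimal block matching (Hungarian assignment on the
// block-overlap matrix, with closed forms for tiny block counts).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct SigWork {
  std::vector<int> uni;        // uniform state per subtree (-2 unset, -1 mixed)
  std::vector<int> nodeBlock;  // block id propagated down
};

// Block partition of tips for one column.
// edge rows are in postorder (children before parents), ape numbering
// (tips 1..ntip). Fills 0-based block id per tip into blockOf.
static int column_signature(const int* states, const IntegerMatrix& edge,
                            int ntip, int nnode, SigWork& w,
                            std::vector<int>& blockOf) {
  const int nedge = edge.nrow();
  w.uni.assign(nnode + 1, -2);
  for (int i = 0; i < ntip; ++i) w.uni[i + 1] = states[i];
  for (int k = 0; k < nedge; ++k) {
    int par = edge(k, 0), ch = edge(k, 1);
    int cs = w.uni[ch];
    if (w.uni[par] == -2) w.uni[par] = cs;
    else if (w.uni[par] != cs) w.uni[par] = -1;
  }
  int root = edge(nedge - 1, 0);
  w.nodeBlock.assign(nnode + 1, -1);
  int nextBlock = 0;
  if (w.uni[root] >= 0) w.nodeBlock[root] = nextBlock++;
  for (int k = nedge - 1; k >= 0; --k) {  // parents before children
    int par = edge(k, 0), ch = edge(k, 1);
    if (w.nodeBlock[par] >= 0) w.nodeBlock[ch] = w.nodeBlock[par];
    else if (w.uni[ch] >= 0) w.nodeBlock[ch] = nextBlock++;
  }
  blockOf.resize(ntip);
  for (int i = 0; i < ntip; ++i) blockOf[i] = w.nodeBlock[i + 1];
  return nextBlock;
}

struct HungWork {
  std::vector<double> u, v, minv, a;
  std::vector<int> p, way;
  std::vector<char> used;
};

// Hungarian algorithm (minimum cost square assignment), O(n^3); a is n x n
// row-major. Returns the minimum cost.
static double hungarian_min(const std::vector<double>& a, int n, HungWork& w) {
  const double INF = 1e18;
  w.u.assign(n + 1, 0); w.v.assign(n + 1, 0);
  w.p.assign(n + 1, 0); w.way.assign(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    w.p[0] = i;
    int j0 = 0;
    w.minv.assign(n + 1, INF);
    w.used.assign(n + 1, 0);
    do {
      w.used[j0] = 1;
      int i0 = w.p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (w.used[j]) continue;
        double cur = a[(i0 - 1) * n + (j - 1)] - w.u[i0] - w.v[j];
        if (cur < w.minv[j]) { w.minv[j] = cur; w.way[j] = j0; }
        if (w.minv[j] < delta) { delta = w.minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (w.used[j]) { w.u[w.p[j]] += delta; w.v[j] -= delta; }
        else w.minv[j] -= delta;
      }
      j0 = j1;
    } while (w.p[j0] != 0);
    do { int j1 = w.way[j0]; w.p[j0] = w.p[j1]; j0 = j1; } while (j0);
  }
  double cost = 0;
  for (int j = 1; j <= n; ++j) cost += a[(w.p[j] - 1) * n + (j - 1)];
  return cost;
}

// maximal total overlap between two block partitions of the same tips
static double max_overlap(const std::vector<int>& b1, int k1,
                          const std::vector<int>& b2, int k2, HungWork& w) {
  const int ntip = (int)b1.size();
  if (k1 <= 1 || k2 <= 1) {
    // single block on one side: best match is the largest block of the other
    const std::vector<int>& b = (k1 <= 1) ? b2 : b1;
    int k = (k1 <= 1) ? k2 : k1;
    std::vector<int> cnt(k, 0);
    for (int x : b) ++cnt[x];
    return (double)*std::max_element(cnt.begin(), cnt.end());
  }
  int n = std::max(k1, k2);
  std::vector<double> ov(n * n, 0.0);
  for (int i = 0; i < ntip; ++i) ov[b1[i] * n + b2[i]] += 1.0;
  if (k1 == 2 && k2 == 2) {
    double d1 = ov[0] + ov[n + 1], d2 = ov[1] + ov[n];
    return d1 > d2 ? d1 : d2;
  }
  double big = (double)ntip;
  w.a.assign(n * n, big);
  for (int i = 0; i < n * n; ++i) w.a[i] = big - ov[i];
  double mincost = hungarian_min(w.a, n, w);
  return n * big - mincost;
}

static double pair_score(const std::vector<int>& b1, int k1,
                         const std::vector<int>& b2, int k2, int ntip,
                         HungWork& w) {
  if (ntip < 2) return 1.0;
  double W = max_overlap(b1, k1, b2, k2, w);
  return 1.0 - ((double)ntip - W) / ((double)ntip - 1.0);
}

// [[Rcpp::export(name = ".cpp_column_signature")]]
IntegerVector cpp_column_signature(IntegerVector states, IntegerMatrix edge,
                                   int ntip, int nnode) {
  SigWork sw;
  std::vector<int> blockOf;
  column_signature(states.begin(), edge, ntip, nnode, sw, blockOf);
  return IntegerVector(blockOf.begin(), blockOf.end());
}

// [[Rcpp::export(name = ".cpp_partition_score")]]
double cpp_partition_score(IntegerVector b1, IntegerVector b2) {
  std::vector<int> x1(b1.begin(), b1.end()), x2(b2.begin(), b2.end());
  int k1 = *std::max_element(x1.begin(), x1.end()) + 1;
  int k2 = *std::max_element(x2.begin(), x2.end()) + 1;
  HungWork hw;
  return pair_score(x1, k1, x2, k2, (int)x1.size(), hw);
}

// All-pairs co-segregation scores and per-pair permutation p-values.
// states: ntip x ncol reduced classes (>= 0; gaps pre-mapped to a class).
// Uses R's RNG (seed with set.seed before calling).
// [[Rcpp::export(name = ".cpp_coevo_pairs")]]
List cpp_coevo_pairs(IntegerMatrix states, IntegerMatrix edge, int nnode,
                     int nperm) {
  const int ntip = states.nrow(), ncol = states.ncol();
  SigWork sw;
  HungWork hw;
  std::vector<std::vector<int>> sig(ncol);
  std::vector<int> nb(ncol);
  std::vector<int> colstates(ntip);
  for (int j = 0; j < ncol; ++j) {
    for (int i = 0; i < ntip; ++i) colstates[i] = states(i, j);
    nb[j] = column_signature(colstates.data(), edge, ntip, nnode, sw, sig[j]);
  }
  NumericMatrix score(ncol, ncol), greater(ncol, ncol), ties(ncol, ncol);
  std::fill(greater.begin(), greater.end(), NA_REAL);
  std::fill(ties.begin(), ties.end(), NA_REAL);
  std::vector<int> perm(ntip), permsig;
  for (int i = 0; i < ncol; ++i) {
    for (int j = i + 1; j < ncol; ++j) {
      double obs = pair_score(sig[i], nb[i], sig[j], nb[j], ntip, hw);
      score(i, j) = score(j, i) = obs;
      int g = 0, t0 = 0;
      for (int r = 0; r < nperm; ++r) {
        for (int t = 0; t < ntip; ++t) perm[t] = states(t, j);
        for (int t = ntip - 1; t > 0; --t) {
          int u = (int)(unif_rand() * (t + 1));
          if (u > t) u = t;
          std::swap(perm[t], perm[u]);
        }
        int kb = column_signature(perm.data(), edge, ntip, nnode, sw, permsig);
        double s = pair_score(sig[i], nb[i], permsig, kb, ntip, hw);
        if (s > obs + 1e-12) ++g;
        else if (s >= obs - 1e-12) ++t0;
      }
      greater(i, j) = greater(j, i) = g;
      ties(i, j) = ties(j, i) = t0;
    }
    checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["greater"] = greater,
                      _["ties"] = ties);
}
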