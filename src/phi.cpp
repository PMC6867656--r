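#include <Rcpp.h>
using namespace Rcpp;

// Refined incompatibility of two aligned columns, given as integer state
// codes 0..3 (negative = missing; taxa with missing data at either column
// are dropped pairwise). The score is the cycle rank E - V + C of the
// bipartite graph whose vertices are the observed states at each column and
// whose edges are the observed state combinations; it equals the minimum
// number of extra state changes needed for the two characters to co-evolve
// on a single tree, and is zero iff they are compatible.
static int pair_score(const int *a, const int *b, int n) {
  bool pair_seen[16];
  for (int i = 0; i < 16; ++i) pair_seen[i] = false;
  bool sa[4] = {false, false, false, false};
  bool sb[4] = {false, false, false, false};
  int E = 0;
  for (int t = 0; t < n; ++t) {
    int x = a[t], y = b[t];
    if (x < 0 || y < 0) continue;
    if (!pair_seen[4 * x + y]) {
      pair_seen[4 * x + y] = true;
      ++E;
      sa[x] = true;
      sb[y] = true;
    }
  }
  int V = 0;
  for (int s = 0; s < 4; ++s) {
    if (sa[s]) ++V;
    if (sb[s]) ++V;
  }
  if (E == 0) return 0;
  // connected components by union-find over 8 possible vertices
  int parent[8];
  for (int i = 0; i < 8; ++i) parent[i] = i;
  for (int x = 0; x < 4; ++x) {
    for (int y = 0; y < 4; ++y) {
      if (!pair_seen[4 * x + y]) continue;
      int u = x, v = 4 + y;
      while (parent[u] != u) u = parent[u];
      while (parent[v] != v) v = parent[v];
      if (u != v) parent[u] = v;
    }
  }
  int C = 0;
  for (int i = 0; i < 8; ++i) {
    bool used = (i < 4) ? sa[i] : sb[i - 4];
    if (!used) continue;
    int r = i;
    while (parent[r] != r) r = parent[r];
    if (r == i) ++C;
    else {
      // root may itself be a non-self-parent in path; count roots only
    }
  }
  // the loop above counts i whose find-root is i, i.e. component roots
  return E - V + C;
}

// [[Rcpp::export]]
int incompat_pair_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("columns must have equal length");
  return pair_score(a.begin(), b.begin(), a.size());
}

// Pairwise incompatibility matrix for a taxa-by-sites integer matrix.
// [[Rcpp::export]]
IntegerMatrix incompat_matrix_cpp(IntegerMatrix m) {
  int n = m.nrow(), k = m.ncol();
  IntegerMatrix out(k, k);
  std::vector<int> buf(n);
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      int s = pair_score(&m(0, i), &m(0, j), n);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

// Mean incompatibility over site pairs at most `window` apart in a given
// ordering. `ord` is a permutation of 0..k-1: ord[p] is the site occupying
// rank p. Returns NA_REAL when no eligible pair exists.
static double band_mean(const IntegerMatrix &M, const int *ord, int k,
                        int window) {
  double sum = 0.0;
  long cnt = 0;
  for (int p = 0; p < k; ++p) {
    int qmax = p + window;
    if (qmax > k - 1) qmax = k - 1;
    for (int q = p + 1; q <= qmax; ++q) {
      sum += M(ord[p], ord[q]);
      ++cnt;
    }
  }
  if (cnt == 0) return NA_REAL;
  return sum / cnt;
}

// [[Rcpp::export]]
double phi_band_mean_cpp(IntegerMatrix M, IntegerVector ord, int window) {
  return band_mean(M, ord.begin(), ord.size(), window);
}

// Permutation statistics: perms is an n_perm x k matrix of 0-based site
// orderings; returns one band-mean statistic per row.
// [[Rcpp::export]]
NumericVector phi_perm_stats_cpp(IntegerMatrix M, IntegerMatrix perms,
                                 int window) {
  int n_perm = perms.nrow(), k = perms.ncol();
  NumericVector out(n_perm);
  std::vector<int> ord(k);
  for (int r = 0; r < n_perm; ++r) {
    for (int c = 0; c < k; ++c) ord[c] = perms(r, c);
    out[r] = band_mean(M, ord.data(), k, window);
  }
  return out;
}
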