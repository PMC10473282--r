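#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Generic Louvain on a dense symmetric (modularity) matrix B.
// Maximizes sum_ij B(i,j) * delta(c_i, c_j) by greedy local moving followed
// by community aggregation, iterated until no move improves the objective.
// Node visiting order is shuffled with R's RNG (unif_rand), so results are
// reproducible under set.seed() and differ across seeded restarts.
// Candidate communities are scanned in ascending index order and the best
// strictly positive gain wins; ties go to the lowest community index.

static void shuffle_order(std::vector<int>& ord) {
  const int n = (int)ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One level of local moving; comm holds 0-based labels, modified in place.
// Returns true if at least one move was made.
static bool local_move(const NumericMatrix& B, std::vector<int>& comm,
                       const double min_gain) {
  const int n = B.nrow();
  bool any_move = false, improved = true;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<double> w(n);
  const double* bp = B.begin();
  int sweeps = 0;
  while (improved && sweeps++ < 200) {
    improved = false;
    shuffle_order(ord);
    for (int oi = 0; oi < n; ++oi) {
      const int i = ord[oi];
      std::fill(w.begin(), w.end(), 0.0);
      // B is symmetric: read column i contiguously instead of row i
      const double* col = bp + (size_t)i * n;
      for (int j = 0; j < n; ++j) w[comm[j]] += col[j];
      w[comm[i]] -= col[i];
      const int c_old = comm[i];
      const double base = w[c_old];
      int best = c_old;
      double best_gain = 0.0;
      for (int c = 0; c < n; ++c) {
        if (c == c_old) continue;
        const double gain = w[c] - base;
        if (gain > best_gain + min_gain) {
          best_gain = gain;
          best = c;
        }
      }
      if (best != c_old && best_gain > min_gain) {
        comm[i] = best;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

// Relabel communities to 0..k-1 in order of first appearance; returns k.
static int compact_labels(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int k = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return k;
}

// [[Rcpp::export]]
List cpp_louvain(NumericMatrix B) {
  const int n = B.nrow();
  if (B.ncol() != n) stop("modularity matrix must be square");
  const double min_gain = 1e-12;
  RNGScope scope;

  std::vector<int> assign(n);          // original node -> current community
  for (int i = 0; i < n; ++i) assign[i] = i;
  NumericMatrix cur = clone(B);

  for (int level = 0; level < 100; ++level) {
    const int m = cur.nrow();
    std::vector<int> comm(m);
    for (int i = 0; i < m; ++i) comm[i] = i;
    const bool moved = local_move(cur, comm, min_gain);
    if (!moved) break;
    const int k = compact_labels(comm);
    for (int v = 0; v < n; ++v) assign[v] = comm[assign[v]];
    if (k == m) break;                 // moves only permuted labels; done
    NumericMatrix agg(k, k);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j)
        agg(comm[i], comm[j]) += cur(i, j);
    cur = agg;
  }

  compact_labels(assign);
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (assign[i] == assign[j]) q += B(i, j);

  IntegerVector membership(n);
  for (int i = 0; i < n; ++i) membership[i] = assign[i] + 1;
  return List::create(_["membership"] = membership, _["q"] = q);
}
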