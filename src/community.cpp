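// Randomized Newman-modularity maximization and degree-preserving edge
// rewiring for small dense binary graphs (nodes = individuals).
//
// The maximizer is a Louvain-style multi-level scheme: local moving with a
// randomized node visit order, aggregation, repeat; followed by a
// Kernighan-Lin-style single-node refinement pass on the original graph.
// Run-to-run variability comes solely from the visit order, drawn from R's
// RNG so that set.seed() makes whole scans reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;
typedef std::vector<std::vector<double> > WList;

static void shuffle_order(std::vector<int>& ord) {
  int n = ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One sweep of local moving; returns number of nodes moved.
static int local_move_pass(const AdjList& adj, const WList& w,
                           const std::vector<double>& k, double two_m,
                           std::vector<int>& comm,
                           std::vector<double>& tot) {
  int n = adj.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  shuffle_order(ord);
  std::vector<double> kin(n, 0.0);
  std::vector<int> touched;
  int moved = 0;
  for (int oi = 0; oi < n; ++oi) {
    int v = ord[oi];
    int cv = comm[v];
    touched.clear();
    for (size_t e = 0; e < adj[v].size(); ++e) {
      int c = comm[adj[v][e]];
      if (kin[c] == 0.0) touched.push_back(c);
      kin[c] += w[v][e];
    }
    tot[cv] -= k[v];
    double best_gain = kin[cv] - k[v] * tot[cv] / two_m;  // gain of staying
    int best_c = cv;
    for (size_t t = 0; t < touched.size(); ++t) {
      int c = touched[t];
      if (c == cv) continue;
      double gain = kin[c] - k[v] * tot[c] / two_m;
      if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
    }
    tot[best_c] += k[v];
    if (best_c != cv) { comm[v] = best_c; ++moved; }
    for (size_t t = 0; t < touched.size(); ++t) kin[touched[t]] = 0.0;
    if (kin[cv] != 0.0) kin[cv] = 0.0;
  }
  return moved;
}

static double modularity_value(const AdjList& adj, const WList& w,
                               const std::vector<double>& k, double two_m,
                               const std::vector<int>& comm) {
  int n = adj.size();
  int nc = 0;
  for (int i = 0; i < n; ++i) if (comm[i] + 1 > nc) nc = comm[i] + 1;
  std::vector<double> in(nc, 0.0), tot(nc, 0.0);
  for (int v = 0; v < n; ++v) {
    tot[comm[v]] += k[v];
    for (size_t e = 0; e < adj[v].size(); ++e)
      if (comm[adj[v][e]] == comm[v]) in[comm[v]] += w[v][e];
  }
  double q = 0.0;
  for (int c = 0; c < nc; ++c)
    q += in[c] / two_m - (tot[c] / two_m) * (tot[c] / two_m);
  return q;
}

static void relabel(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
}

static std::vector<int> louvain_once(const AdjList& adj, const WList& w,
                                     const std::vector<double>& k,
                                     double two_m, int n);

// [[Rcpp::export]]
List louvain_cpp(NumericMatrix A, int restarts = 3) {
  int n = A.nrow();
  AdjList adj(n);
  WList w(n);
  std::vector<double> k(n, 0.0);
  double two_m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double a = A(i, j);
      if (i != j && a != 0.0) {
        adj[i].push_back(j);
        w[i].push_back(a);
        k[i] += a;
        two_m += a;
      }
    }
  if (two_m <= 0.0) {
    IntegerVector memb(n);
    for (int i = 0; i < n; ++i) memb[i] = i + 1;
    return List::create(_["membership"] = memb, _["Q"] = 0.0);
  }

  std::vector<int> node2final;
  double best_q = -2.0;
  for (int rs = 0; rs < (restarts > 0 ? restarts : 1); ++rs) {
    std::vector<int> cand = louvain_once(adj, w, k, two_m, n);
    double q = modularity_value(adj, w, k, two_m, cand);
    if (q > best_q + 1e-14) { best_q = q; node2final = cand; }
  }
  relabel(node2final);
  IntegerVector memb(n);
  for (int i = 0; i < n; ++i) memb[i] = node2final[i] + 1;
  return List::create(_["membership"] = memb, _["Q"] = best_q);
}

// Interleaved two-phase maximization, iterated to a fixpoint:
// (a) Kernighan-Lin-style single-node moves on the original graph in
//     randomized order until stable;
// (b) merge phase: aggregate communities and run randomized local moving
//     on the community graph (a move there merges whole communities).
// Repeat until neither phase changes the partition.
static std::vector<int> louvain_once(const AdjList& adj, const WList& w,
                                     const std::vector<double>& k,
                                     double two_m, int n) {
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;
  for (int outer = 0; outer < 100; ++outer) {
    relabel(comm);
    int ncomm = 0;
    for (int i = 0; i < n; ++i) if (comm[i] + 1 > ncomm) ncomm = comm[i] + 1;
    std::vector<double> tot(ncomm > n ? ncomm : n, 0.0);
    for (int i = 0; i < n; ++i) tot[comm[i]] += k[i];
    int moved_nodes = 0;
    for (int pass = 0; pass < 200; ++pass) {
      int moved = local_move_pass(adj, w, k, two_m, comm, tot);
      moved_nodes += moved;
      if (moved == 0) break;
    }
    relabel(comm);
    ncomm = 0;
    for (int i = 0; i < n; ++i) if (comm[i] + 1 > ncomm) ncomm = comm[i] + 1;
    if (ncomm <= 1) break;
    // aggregate: community graph with summed inter-community weights.
    // Internal weight is constant across merge decisions and so may be
    // dropped, provided the community degrees nk keep it.
    std::vector<std::vector<double> > wmat(ncomm,
                                           std::vector<double>(ncomm, 0.0));
    std::vector<double> nk(ncomm, 0.0);
    for (int v = 0; v < n; ++v) {
      nk[comm[v]] += k[v];
      for (size_t e = 0; e < adj[v].size(); ++e)
        wmat[comm[v]][comm[adj[v][e]]] += w[v][e];
    }
    AdjList cadj(ncomm); WList cw(ncomm);
    for (int a = 0; a < ncomm; ++a)
      for (int b = 0; b < ncomm; ++b)
        if (a != b && wmat[a][b] > 0.0) {
          cadj[a].push_back(b);
          cw[a].push_back(wmat[a][b]);
        }
    std::vector<int> agg(ncomm);
    for (int a = 0; a < ncomm; ++a) agg[a] = a;
    std::vector<double> ctot = nk;
    int merged = 0;
    for (int pass = 0; pass < 200; ++pass) {
      int moved = local_move_pass(cadj, cw, nk, two_m, agg, ctot);
      merged += moved;
      if (moved == 0) break;
    }
    for (int i = 0; i < n; ++i) comm[i] = agg[comm[i]];
    if (moved_nodes == 0 && merged == 0) break;
  }
  return comm;
}

// Degree-preserving rewiring by double-edge swaps: pick two edges
// (a,b),(c,d), replace with (a,d),(c,b), rejecting self-loops and
// multi-edges. `nswap` successful swaps relocate 2*nswap edge slots.
// [[Rcpp::export]]
List rewire_cpp(NumericMatrix A, int nswap, int max_tries_per_swap = 100) {
  int n = A.nrow();
  NumericMatrix B = clone(A);
  std::vector<int> efrom, eto;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (B(i, j) != 0.0) { efrom.push_back(i); eto.push_back(j); }
  int m = efrom.size();
  int done = 0;
  if (m >= 2) {
    long long tries = 0, max_tries = (long long)max_tries_per_swap *
      (nswap > 0 ? nswap : 1);
    while (done < nswap && tries < max_tries) {
      ++tries;
      int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
      int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = efrom[e1], b = eto[e1], c = efrom[e2], d = eto[e2];
      if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
      // propose (a,d) and (c,b)
      if (a == d || c == b) continue;
      if (B(a, d) != 0.0 || B(c, b) != 0.0) continue;
      B(a, b) = B(b, a) = 0.0;
      B(c, d) = B(d, c) = 0.0;
      B(a, d) = B(d, a) = 1.0;
      B(c, b) = B(b, c) = 1.0;
      efrom[e1] = a < d ? a : d; eto[e1] = a < d ? d : a;
      efrom[e2] = c < b ? c : b; eto[e2] = c < b ? b : c;
      ++done;
    }
  }
  return List::create(_["adjacency"] = B, _["swaps"] = done);
}
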