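// Grid minimum free energy path search.
//
// mfep_search_cpp: MEPSA-style node-by-node flooding to find the smallest
// attainable maximum node energy between the endpoints, then a Dijkstra pass
// restricted to nodes at or below that level to minimise the sum of node
// energies (the lexicographic (max, sum) objective; ties broken by node
// index).  mfep_exhaustive_cpp is the independent branch-and-bound
// enumeration oracle for small grids (requires non-negative energies for the
// sum prune to be exact).
#include <Rcpp.h>
#include <queue>
#include <climits>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void neighbours(int node, int nr, int nc, bool eight, int* out,
                       int& n_out) {
  int r = node % nr, c = node / nr;
  n_out = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      if (dr == 0 && dc == 0) continue;
      if (!eight && dr != 0 && dc != 0) continue;
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      out[n_out++] = cc * nr + rr;
    }
}

// [[Rcpp::export]]
List mfep_search_cpp(NumericMatrix F, int start, int end, bool eight) {
  int nr = F.nrow(), nc = F.ncol(), n = nr * nc;
  const double* f = F.begin();
  std::vector<char> masked(n, 0);
  for (int i = 0; i < n; ++i) masked[i] = !std::isfinite(f[i]);
  if (masked[start] || masked[end])
    return List::create(_["reachable"] = false);

  // Stage 1: flooding for the minimax level.  Repeatedly accept the
  // lowest-energy frontier node (ties by index); when the end node is
  // accepted the running maximum accepted energy is the minimax level.
  typedef std::pair<double, int> PD;
  std::priority_queue<PD, std::vector<PD>, std::greater<PD> > pq;
  std::vector<char> accepted(n, 0);
  pq.push(PD(f[start], start));
  double level = R_NegInf;
  bool reachable = false;
  int nb[8], n_nb;
  while (!pq.empty()) {
    PD top = pq.top(); pq.pop();
    int node = top.second;
    if (accepted[node]) continue;
    accepted[node] = 1;
    if (top.first > level) level = top.first;
    if (node == end) { reachable = true; break; }
    neighbours(node, nr, nc, eight, nb, n_nb);
    for (int k = 0; k < n_nb; ++k)
      if (!accepted[nb[k]] && !masked[nb[k]]) pq.push(PD(f[nb[k]], nb[k]));
  }
  if (!reachable) return List::create(_["reachable"] = false);

  // Stage 2: Dijkstra on node-energy sums over nodes with F <= level.
  // Exact ties on the sum are broken by hop count (then by pop order on
  // node index), so the flat-surface path is the Chebyshev-shortest one
  // and the result is deterministic.
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1), hop(n, INT_MAX);
  std::vector<char> done(n, 0);
  typedef std::pair<std::pair<double, int>, int> QD; // ((sum, hops), node)
  std::priority_queue<QD, std::vector<QD>, std::greater<QD> > dq;
  dist[start] = f[start];
  hop[start] = 1;
  dq.push(QD(std::make_pair(dist[start], 1), start));
  while (!dq.empty()) {
    QD top = dq.top(); dq.pop();
    int node = top.second;
    if (done[node]) continue;
    done[node] = 1;
    if (node == end) break;
    neighbours(node, nr, nc, eight, nb, n_nb);
    for (int k = 0; k < n_nb; ++k) {
      int m = nb[k];
      if (masked[m] || f[m] > level || done[m]) continue;
      double nd = dist[node] + f[m];
      int nh = hop[node] + 1;
      if (nd < dist[m] || (nd == dist[m] && nh < hop[m])) {
        dist[m] = nd;
        hop[m] = nh;
        parent[m] = node;
        dq.push(QD(std::make_pair(nd, nh), m));
      }
    }
  }
  std::vector<int> path;
  for (int node = end; node != -1; node = parent[node]) path.push_back(node);
  std::reverse(path.begin(), path.end());
  IntegerVector out(path.begin(), path.end());
  return List::create(_["reachable"] = true, _["path"] = out + 1,
                      _["max_energy"] = level, _["sum_energy"] = dist[end]);
}

// Independent oracle for small grids, in two exhaustive phases.
//
// Phase 1 (minimax level): try every distinct node energy as a threshold,
// in increasing order, and test start-end connectivity over nodes at or
// below it by depth-first search; the smallest connecting threshold is the
// minimax level tau.  Phase 2: every start-end path within the tau
// subgraph attains maximum exactly tau (a smaller maximum would contradict
// the minimality of tau), so the lexicographic objective reduces to the
// minimum node-energy sum there; enumerate simple paths in the subgraph by
// depth-first search, pruning on the running sum, which is exact for
// non-negative energies.
struct SumDFS {
  const double* f;
  int nr, nc, end;
  bool eight;
  double tau, best_sum;
  std::vector<char> onpath, allowed;
  std::vector<int> cur, best;
  void dfs(int node, double csum) {
    if (csum >= best_sum) return;
    if (node == end) {
      best_sum = csum; best = cur;
      return;
    }
    int nb[8], n_nb;
    neighbours(node, nr, nc, eight, nb, n_nb);
    for (int k = 0; k < n_nb; ++k) {
      int m = nb[k];
      if (onpath[m] || !allowed[m]) continue;
      onpath[m] = 1;
      cur.push_back(m);
      dfs(m, csum + f[m]);
      cur.pop_back();
      onpath[m] = 0;
    }
  }
};

static bool connected_below(const double* f, int nr, int nc, bool eight,
                            int start, int end, double tau) {
  if (f[start] > tau || f[end] > tau) return false;
  std::vector<char> seen(nr * nc, 0);
  std::vector<int> stack;
  stack.push_back(start);
  seen[start] = 1;
  int nb[8], n_nb;
  while (!stack.empty()) {
    int node = stack.back(); stack.pop_back();
    if (node == end) return true;
    neighbours(node, nr, nc, eight, nb, n_nb);
    for (int k = 0; k < n_nb; ++k)
      if (!seen[nb[k]] && f[nb[k]] <= tau) {
        seen[nb[k]] = 1;
        stack.push_back(nb[k]);
      }
  }
  return false;
}

// [[Rcpp::export]]
List mfep_exhaustive_cpp(NumericMatrix F, int start, int end, bool eight) {
  int n = F.size();
  const double* f = F.begin();
  for (int i = 0; i < n; ++i)
    if (f[i] < 0) stop("exhaustive oracle requires non-negative energies");
  std::vector<double> levels(f, f + n);
  std::sort(levels.begin(), levels.end());
  double tau = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (connected_below(f, F.nrow(), F.ncol(), eight, start, end,
                        levels[i])) {
      tau = levels[i];
      break;
    }
  }
  if (!std::isfinite(tau)) return List::create(_["reachable"] = false);
  SumDFS b;
  b.f = f; b.nr = F.nrow(); b.nc = F.ncol();
  b.end = end; b.eight = eight; b.tau = tau;
  b.best_sum = R_PosInf;
  b.onpath.assign(n, 0);
  b.allowed.assign(n, 0);
  for (int i = 0; i < n; ++i) b.allowed[i] = f[i] <= tau;
  b.onpath[start] = 1;
  b.cur.push_back(start);
  b.dfs(start, f[start]);
  IntegerVector out(b.best.begin(), b.best.end());
  return List::create(_["reachable"] = true, _["path"] = out + 1,
                      _["max_energy"] = tau, _["sum_energy"] = b.best_sum);
}
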