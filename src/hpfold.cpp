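// Core loops: tabular Q-learning over the prefix-tree state space, greedy
// decoding of a converged table, and exact ground-state enumeration by pruned
// depth-first search over self-avoiding walks.
//
// All randomness comes from R's RNG stream (unif_rand), and every placement
// step draws exactly two uniforms (explore check, then an index draw even
// when there is a single candidate), so the pure-R reference episode runner
// reproduces this loop bitwise under the same seed.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <string>
#include <cstdint>

using namespace Rcpp;

// directions 0..3 = +x, +y, -x, -y; absolute actions a1..a4 = L, U, R, D
static const int DX[4] = {1, 0, -1, 0};
static const int DY[4] = {0, 1, 0, -1};
static const int ABS4_DIR[4] = {2, 1, 0, 3};
static const int ABS3_DIR[3] = {2, 1, 0};
static const int REL3_TURN[3] = {1, 0, 3}; // turn-left, straight, turn-right
static const char DIR_CHAR[4] = {'R', 'U', 'L', 'D'};

enum Geometry { REL3, ABS3, ABS4 };
enum StateMode { FULL, PARTIAL };

static Geometry parse_geometry(const std::string& g) {
  if (g == "relative3") return REL3;
  if (g == "absolute3") return ABS3;
  if (g == "absolute4") return ABS4;
  stop("unknown action geometry: %s", g);
  return REL3;
}

static inline int action_dir(Geometry geo, int l, int prev_dir) {
  switch (geo) {
  case REL3: return (prev_dir + REL3_TURN[l]) & 3;
  case ABS3: return ABS3_DIR[l];
  default:   return ABS4_DIR[l];
  }
}

// uniform index in [0, m); exactly one RNG draw
static inline int draw_index(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

typedef std::unordered_map<int64_t, std::array<double, 4> > QMap;

static inline double qval(const QMap& q, int64_t s, int a) {
  QMap::const_iterator it = q.find(s);
  return it == q.end() ? 0.0 : it->second[a];
}

static inline double qmax(const QMap& q, int64_t s, int b) {
  QMap::const_iterator it = q.find(s);
  if (it == q.end()) return 0.0;
  double m = it->second[0];
  for (int a = 1; a < b; ++a) if (it->second[a] > m) m = it->second[a];
  return m;
}

// energy of a (possibly overlapping) set of coordinates: -(number of H-H
// pairs with |i-j| >= 2 at unit lattice distance)
static int energy_pairs(const std::vector<int>& x, const std::vector<int>& y,
                        const std::vector<int>& isH, int n) {
  int e = 0;
  for (int i = 0; i < n - 2; ++i) {
    if (!isH[i]) continue;
    for (int j = i + 2; j < n; ++j) {
      if (!isH[j]) continue;
      int d = std::abs(x[i] - x[j]) + std::abs(y[i] - y[j]);
      if (d == 1) --e;
    }
  }
  return e;
}

struct EpisodeScratch {
  int n, b, side;
  Geometry geo;
  StateMode mode;
  std::vector<int> grid;     // stamp grid, (2n-1)^2
  std::vector<int> x, y;
  std::vector<int64_t> off;  // off[i] = (b^i - 1)/(b - 1)
  int stamp;
  EpisodeScratch(int n_, int b_, Geometry geo_, StateMode mode_)
    : n(n_), b(b_), side(2 * n_ - 1), geo(geo_), mode(mode_),
      grid(side * side, -1), x(n_), y(n_), off(n_ + 1), stamp(0) {
    off[0] = 0;
    for (int i = 1; i <= n; ++i) off[i] = off[i - 1] * b + 1;
  }
  inline int cell(int cx, int cy) const { return (cx + n - 1) * side + (cy + n - 1); }
};

struct EpisodeResult {
  int energy;          // terminal energy (pairwise), valid when complete
  bool complete;       // residue n placed (no dead end)
  bool legal;          // complete and self-avoiding
  int invalid_steps;   // flexible: number of overlapping placements
  std::string moves;   // absolute direction letters, length n-1 when complete
};

// One episode. When `learn` is false the table is left untouched and
// `epsilon` should be 0 (greedy test rollout). `reselect`: under the rigid
// criterion, handle invalid actions by fresh epsilon-greedy re-draws over
// the full action set instead of masking; after 32 rejections (possible only
// when every maximizer is blocked and epsilon is small) fall back to one
// uniform draw among the valid actions.
static EpisodeResult run_episode_cpp(EpisodeScratch& sc, QMap& q,
                                     const std::vector<int>& isH,
                                     bool rigid, bool reselect, bool tie_first,
                                     double alpha, double gamma,
                                     double epsilon, bool learn) {
  const int n = sc.n, b = sc.b;
  EpisodeResult res;
  res.energy = 0; res.complete = false; res.legal = false;
  res.invalid_steps = 0; res.moves.clear();

  ++sc.stamp;
  sc.x[0] = 0; sc.y[0] = 0;
  sc.grid[sc.cell(0, 0)] = sc.stamp;

  int64_t s = 1, k = 1;     // state index and 1-based ordinal at current depth
  int prev_dir = 0;
  bool overlapped = false;

  int cand[4], cdir[4];
  for (int i = 2; i <= n; ++i) {
    // candidate actions; under masking, occupied target cells are removed
    int m = 0;
    int nvalid = 0, vcand[4];
    for (int l = 0; l < b; ++l) {
      int d = action_dir(sc.geo, l, prev_dir);
      int nx = sc.x[i - 2] + DX[d], ny = sc.y[i - 2] + DY[d];
      bool occupied = sc.grid[sc.cell(nx, ny)] == sc.stamp;
      if (!occupied) vcand[nvalid++] = l;
      if (!rigid || reselect || !occupied) { cand[m] = l; cdir[m] = d; ++m; }
    }
    if (rigid && nvalid == 0) return res; // dead end: terminate, no bonus

    int l, d;
    if (rigid && reselect) {
      int attempts = 0;
      for (;;) {
        double u = unif_rand();
        int pick;
        if (u < epsilon) {
          pick = draw_index(b);
        } else {
          double best = qval(q, s, 0);
          for (int a = 1; a < b; ++a) {
            double v = qval(q, s, a);
            if (v > best) best = v;
          }
          int ties[4], nt = 0;
          for (int a = 0; a < b; ++a) if (qval(q, s, a) == best) ties[nt++] = a;
          pick = tie_first ? ties[0] : ties[draw_index(nt)];
        }
        int dd = action_dir(sc.geo, pick, prev_dir);
        int nx = sc.x[i - 2] + DX[dd], ny = sc.y[i - 2] + DY[dd];
        if (sc.grid[sc.cell(nx, ny)] != sc.stamp) { l = pick; d = dd; break; }
        if (++attempts >= 32) {
          l = vcand[draw_index(nvalid)];
          d = action_dir(sc.geo, l, prev_dir);
          break;
        }
      }
    } else {
      double u = unif_rand();
      int pick;
      if (u < epsilon) {
        pick = draw_index(m);
      } else {
        double best = qval(q, s, cand[0]);
        for (int t = 1; t < m; ++t) {
          double v = qval(q, s, cand[t]);
          if (v > best) best = v;
        }
        int ties[4], nt = 0;
        for (int t = 0; t < m; ++t) if (qval(q, s, cand[t]) == best) ties[nt++] = t;
        pick = tie_first ? ties[0] : ties[draw_index(nt)];
      }
      l = cand[pick]; d = cdir[pick];
    }

    int nx = sc.x[i - 2] + DX[d], ny = sc.y[i - 2] + DY[d];
    bool occupied = sc.grid[sc.cell(nx, ny)] == sc.stamp;
    if (occupied) { overlapped = true; ++res.invalid_steps; }
    sc.x[i - 1] = nx; sc.y[i - 1] = ny;
    sc.grid[sc.cell(nx, ny)] = sc.stamp;

    int64_t s_next = (sc.mode == PARTIAL)
      ? 1 + 4 * (int64_t)(i - 2) + (l + 1)
      : sc.off[i - 1] + b * (k - 1) + (l + 1);

    bool terminal = (i == n);
    if (learn) {
      double r;
      if (terminal) {
        res.energy = energy_pairs(sc.x, sc.y, isH, n);
        r = -res.energy; // |E|
      } else {
        r = (!rigid && occupied) ? -10.0 : 0.0;
      }
      double target = terminal ? r : r + gamma * qmax(q, s_next, b);
      std::array<double, 4>& row = q[s];
      row[l] += alpha * (target - row[l]);
    } else if (terminal) {
      res.energy = energy_pairs(sc.x, sc.y, isH, n);
    }

    res.moves.push_back(DIR_CHAR[d]);
    s = s_next;
    k = (sc.mode == PARTIAL) ? 0 : b * (k - 1) + (l + 1);
    prev_dir = d;
  }
  res.complete = true;
  res.legal = !overlapped;
  return res;
}

// [[Rcpp::export]]
List cpp_train(IntegerVector isH_, int episodes, double alpha, double gamma,
               double epsilon, int test_interval, bool rigid, bool reselect,
               std::string state_mode, std::string geometry,
               bool sample_training, bool tie_first, int target_energy,
               bool has_target, bool return_q, int pool_cap) {
  int n = isH_.size();
  if (n < 2) stop("training needs a chain of at least 2 residues");
  Geometry geo = parse_geometry(geometry);
  StateMode mode = (state_mode == "partial") ? PARTIAL : FULL;
  int b = (geo == ABS4) ? 4 : 3;
  if (mode == PARTIAL && geo != ABS4)
    stop("the partial state space uses the 4 absolute actions");
  // int64 prefix-tree indices stay exact while b^n < 2^62
  if (mode == FULL && ((b == 3 && n > 33) || (b == 4 && n > 26)))
    stop("full-state training supports n <= 33 (3-action) / n <= 26 (4-action)");

  std::vector<int> isH(isH_.begin(), isH_.end());
  EpisodeScratch sc(n, b, geo, mode);
  QMap q;

  std::vector<int> curve_ep, curve_e;
  std::vector<int> curve_legal, curve_best;
  int best_legal = 1; // energies are <= 0; 1 marks "none yet"
  int first_hit = -1;
  int dead_ends = 0;
  int pool_E = 1;
  std::vector<std::string> pool;
  bool pool_truncated = false;

  for (int ep = 1; ep <= episodes; ++ep) {
    EpisodeResult tr = run_episode_cpp(sc, q, isH, rigid, reselect, tie_first,
                                       alpha, gamma, epsilon, true);
    if (!tr.complete) ++dead_ends;

    if (test_interval > 0 && ep % test_interval == 0) {
      // the periodic sample is either the training episode just run or a
      // fresh greedy rollout with learning frozen
      EpisodeResult te = sample_training
        ? tr
        : run_episode_cpp(sc, q, isH, rigid, reselect, tie_first,
                          alpha, gamma, 0.0, false);
      curve_ep.push_back(ep);
      curve_e.push_back(te.complete ? te.energy : NA_INTEGER);
      curve_legal.push_back(te.legal ? 1 : 0);
      if (te.legal) {
        if (best_legal == 1 || te.energy < best_legal) best_legal = te.energy;
        if (has_target && first_hit < 0 && te.energy <= target_energy)
          first_hit = ep;
        if (pool_E == 1 || te.energy < pool_E) {
          pool_E = te.energy;
          pool.clear();
          pool_truncated = false;
        }
        if (te.energy == pool_E) {
          bool seen = false;
          for (size_t t = 0; t < pool.size(); ++t)
            if (pool[t] == te.moves) { seen = true; break; }
          if (!seen) {
            if ((int)pool.size() < pool_cap) pool.push_back(te.moves);
            else pool_truncated = true;
          }
        }
      }
      curve_best.push_back(best_legal == 1 ? NA_INTEGER : best_legal);
    }
    if (ep % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List qout = R_NilValue;
  double q_absmax = 0.0;
  if (!q.empty()) {
    for (QMap::const_iterator it = q.begin(); it != q.end(); ++it)
      for (int a = 0; a < b; ++a)
        if (std::abs(it->second[a]) > q_absmax) q_absmax = std::abs(it->second[a]);
  }
  if (return_q) {
    size_t m = q.size();
    NumericVector st(m);
    NumericMatrix qm(m, b);
    size_t r = 0;
    for (QMap::const_iterator it = q.begin(); it != q.end(); ++it, ++r) {
      st[r] = (double)it->first;
      for (int a = 0; a < b; ++a) qm(r, a) = it->second[a];
    }
    qout = List::create(_["state"] = st, _["q"] = qm);
  }

  return List::create(
    _["curve"] = DataFrame::create(
      _["episode"] = curve_ep, _["test_energy"] = curve_e,
      _["legal"] = LogicalVector(curve_legal.begin(), curve_legal.end()),
      _["cumulative_best"] = curve_best),
    _["best_energy"] = best_legal == 1 ? NA_INTEGER : best_legal,
    _["first_hit_episode"] = first_hit < 0 ? NA_INTEGER : first_hit,
    _["pool_moves"] = wrap(pool),
    _["pool_energy"] = pool_E == 1 ? NA_INTEGER : pool_E,
    _["pool_truncated"] = pool_truncated,
    _["dead_ends"] = dead_ends,
    _["n_states_visited"] = (double)q.size(),
    _["q_absmax"] = q_absmax,
    _["qtable"] = qout);
}

// Greedy decoding of a (state -> values) table: depth-first expansion
// following every argmax-tied action, up to `cap` leaves.
// [[Rcpp::export]]
List cpp_extract_pool(NumericVector states, NumericMatrix qmat,
                      IntegerVector isH_, std::string state_mode,
                      std::string geometry, int cap) {
  int n = isH_.size();
  Geometry geo = parse_geometry(geometry);
  StateMode mode = (state_mode == "partial") ? PARTIAL : FULL;
  int b = (geo == ABS4) ? 4 : 3;
  std::vector<int> isH(isH_.begin(), isH_.end());

  QMap q;
  for (int r = 0; r < states.size(); ++r) {
    std::array<double, 4> row = {{0, 0, 0, 0}};
    for (int a = 0; a < qmat.ncol(); ++a) row[a] = qmat(r, a);
    q[(int64_t)states[r]] = row;
  }

  std::vector<int64_t> off(n + 1);
  off[0] = 0;
  for (int i = 1; i <= n; ++i) off[i] = off[i - 1] * b + 1;

  struct Node { int64_t s, k; int depth, prev_dir; std::string moves; };
  std::vector<Node> stack;
  Node root; root.s = 1; root.k = 1; root.depth = 1; root.prev_dir = 0;
  stack.push_back(root);

  std::vector<std::string> leaves;
  std::vector<int> leaf_E, leaf_legal;
  bool truncated = false;

  while (!stack.empty()) {
    Node nd = stack.back();
    stack.pop_back();
    if (nd.depth == n) {
      if ((int)leaves.size() >= cap) { truncated = true; break; }
      // decode absolute moves to coordinates, score
      std::vector<int> x(n), y(n);
      bool legal = true;
      x[0] = 0; y[0] = 0;
      for (int i = 1; i < n; ++i) {
        int d = 0;
        switch (nd.moves[i - 1]) {
        case 'R': d = 0; break; case 'U': d = 1; break;
        case 'L': d = 2; break; case 'D': d = 3; break;
        }
        x[i] = x[i - 1] + DX[d]; y[i] = y[i - 1] + DY[d];
        for (int j = 0; j < i; ++j)
          if (x[j] == x[i] && y[j] == y[i]) { legal = false; break; }
      }
      leaves.push_back(nd.moves);
      leaf_E.push_back(energy_pairs(x, y, isH, n));
      leaf_legal.push_back(legal ? 1 : 0);
      continue;
    }
    double best = qval(q, nd.s, 0);
    for (int a = 1; a < b; ++a) {
      double v = qval(q, nd.s, a);
      if (v > best) best = v;
    }
    for (int l = b - 1; l >= 0; --l) { // push in reverse for left-to-right DFS
      if (qval(q, nd.s, l) != best) continue;
      Node ch;
      ch.depth = nd.depth + 1;
      int d = action_dir(geo, l, nd.prev_dir);
      ch.prev_dir = d;
      ch.moves = nd.moves;
      ch.moves.push_back(DIR_CHAR[d]);
      if (mode == PARTIAL) {
        ch.s = 1 + 4 * (int64_t)(nd.depth - 1) + (l + 1);
        ch.k = 0;
      } else {
        ch.s = off[nd.depth] + b * (nd.k - 1) + (l + 1);
        ch.k = b * (nd.k - 1) + (l + 1);
      }
      stack.push_back(ch);
    }
  }

  return List::create(_["moves"] = wrap(leaves),
                      _["energy"] = wrap(leaf_E),
                      _["legal"] = wrap(leaf_legal),
                      _["truncated"] = truncated);
}

// ---------------------------------------------------------------------------
// Exact ground-state oracle: DFS over self-avoiding walks with optional
// 8-fold symmetry reduction (first step fixed to +x, first turn fixed to +y)
// and admissible branch-and-bound pruning.

struct EnumState {
  int n;
  std::vector<int> isH;
  std::vector<int> grid;     // residue index + 1, 0 = empty; padded one cell
  std::vector<int> x, y;     // beyond the reachable (2n-1)^2 square so that
  std::vector<int> remH2;    // neighbour scans never leave the array
  bool sym, prune;
  int forbid;                // step direction never taken (-1 = none)
  double cap;
  double explored;
  bool truncated;
  int best;
  double count;
  EnumState(int n_) : n(n_), grid((2 * n_ + 1) * (2 * n_ + 1), 0),
                      x(n_), y(n_), remH2(n_ + 1, 0) {}
  inline int cell(int cx, int cy) const {
    return (cx + n) * (2 * n + 1) + (cy + n);
  }
};

// restrict_dir >= 0 forbids that step direction (e.g. 3 = never step -y,
// the partially directed walks reachable with absolute L/U/R actions)
// i: 0-based index of the next residue to place; turned: whether the walk has
// left the +x axis yet (symmetry reduction)
static void enum_dfs(EnumState& es, int i, int e, bool turned) {
  if (es.truncated) return;
  if (i == es.n) {
    if (e < es.best) { es.best = e; es.count = 1; }
    else if (e == es.best) es.count += 1;
    return;
  }
  if (es.prune) {
    // remaining contacts <= 2 per unplaced H (+1 if the tail end is H):
    // a placed chain residue has at most 2 free non-chain neighbours
    int bound = es.remH2[i] + (es.isH[es.n - 1] && i < es.n ? 1 : 0);
    if (e - bound > es.best) return;
  }
  for (int d = 0; d < 4; ++d) {
    if (d == es.forbid) continue;
    if (es.sym && !turned) {
      if (d == 2 || d == 3) continue;       // first turn fixed to +y
      if (i == 1 && d != 0) continue;       // first step fixed to +x
    }
    int nx = es.x[i - 1] + DX[d], ny = es.y[i - 1] + DY[d];
    int c = es.cell(nx, ny);
    if (es.grid[c]) continue;
    es.explored += 1;
    if (es.cap > 0 && es.explored > es.cap) { es.truncated = true; return; }
    int de = 0;
    if (es.isH[i]) {
      for (int dd = 0; dd < 4; ++dd) {
        int oc = es.grid[es.cell(nx + DX[dd], ny + DY[dd])];
        if (oc && oc - 1 != i - 1 && es.isH[oc - 1]) --de; // |i-j| >= 2, both H
      }
    }
    es.x[i] = nx; es.y[i] = ny;
    es.grid[c] = i + 1;
    enum_dfs(es, i + 1, e + de, turned || d != 0);
    es.grid[c] = 0;
    if (es.truncated) return;
  }
}

// [[Rcpp::export]]
List cpp_enumerate(IntegerVector isH_, bool symmetry_reduce, bool bound_prune,
                   double node_cap, int forbid_dir) {
  int n = isH_.size();
  EnumState es(n);
  es.isH.assign(isH_.begin(), isH_.end());
  for (int i = n - 1; i >= 0; --i)
    es.remH2[i] = es.remH2[i + 1] + (es.isH[i] ? 2 : 0);
  es.sym = symmetry_reduce;
  es.prune = bound_prune;
  es.forbid = forbid_dir;
  es.cap = node_cap;
  es.explored = 0;
  es.truncated = false;
  es.best = 1; // sentinel above any reachable energy
  es.count = 0;
  if (n == 1) {
    es.best = 0; es.count = 1;
  } else {
    es.x[0] = 0; es.y[0] = 0;
    es.grid[es.cell(0, 0)] = 1;
    enum_dfs(es, 1, 0, false);
  }
  return List::create(_["min_energy"] = es.best,
                      _["optimum_count"] = es.count,
                      _["explored"] = es.explored,
                      _["truncated"] = es.truncated);
}
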