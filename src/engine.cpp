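#include <Rcpp.h>
using namespace Rcpp;

// Core of the three-stage metanorms game and its evolutionary update.
// Strategies are 3-bit levels 0..7 for boldness and vengefulness
// (value = level / 7). All randomness comes from R's RNG so runs are
// bit-reproducible under set.seed().
//
// Fixed event order (reproducibility contract):
//   stage 1: all agents in index order;
//   stage 2: defection events in defector index order, observers in
//            adjacency order;
//   stage 3: nested inside each unpunished observation, common
//            neighbours in adjacency order.

namespace {

struct Adjacency {
  int n;
  std::vector<std::vector<int>> nb; // 0-based neighbour lists
  explicit Adjacency(const List& adj) {
    n = adj.size();
    nb.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector v = adj[i];
      nb[i].assign(v.begin(), v.end());
    }
  }
};

// One round of the game. Adds payoffs into `pay_acc`; returns event counts.
inline void play_round_core(const Adjacency& A,
                            const std::vector<int>& blev,
                            const std::vector<int>& vlev,
                            const double* pc, // T,H,E,P,ME,MP
                            std::vector<double>& pay_acc,
                            std::vector<int>& mark,
                            int& n_defect, int& n_punish, int& n_meta) {
  const int n = A.n;
  const double T = pc[0], H = pc[1], E = pc[2], P = pc[3], ME = pc[4],
               MP = pc[5];
  std::vector<double> s(n);
  std::vector<char> defect(n, 0);

  // stage 1: defection decisions (s is also the observability draw)
  int nd = 0;
  for (int i = 0; i < n; ++i) {
    s[i] = R::unif_rand();
    if (blev[i] / 7.0 > s[i]) {
      defect[i] = 1;
      ++nd;
    }
  }
  n_defect += nd;
  if (nd > 0) {
    for (int i = 0; i < n; ++i) {
      // a defector gains T; every other agent is hurt by each defection
      int others = nd - (defect[i] ? 1 : 0);
      pay_acc[i] += H * others;
      if (defect[i]) pay_acc[i] += T;
    }
  }

  // stages 2 and 3, per defection event
  for (int i = 0; i < n; ++i) {
    if (!defect[i]) continue;
    const double si = s[i];
    for (int l : A.nb[i]) mark[l] = i + 1; // flag N(i)
    for (int j : A.nb[i]) {
      if (R::unif_rand() >= si) continue; // j did not observe
      if (R::unif_rand() < vlev[j] / 7.0) {
        // j punishes i
        pay_acc[j] += E;
        pay_acc[i] += P;
        ++n_punish;
      } else {
        // observed, unpunished: common neighbours may meta-punish j
        for (int l : A.nb[j]) {
          if (mark[l] != i + 1) continue; // l must also neighbour i
          if (R::unif_rand() >= si) continue;
          if (R::unif_rand() < vlev[l] / 7.0) {
            pay_acc[l] += ME;
            pay_acc[j] += MP;
            ++n_meta;
          }
        }
      }
    }
    for (int l : A.nb[i]) mark[l] = 0;
  }
}

// roulette-wheel pick over pool payoffs, fitness = payoff - pool minimum;
// all-zero fitness degenerates to a uniform draw
inline int roulette_pick(const std::vector<int>& pool,
                         const std::vector<double>& pay) {
  double mn = R_PosInf;
  for (int c : pool) mn = std::min(mn, pay[c]);
  double tot = 0.0;
  for (int c : pool) tot += pay[c] - mn;
  if (tot <= 0.0) {
    int k = (int)std::floor(R::unif_rand() * pool.size());
    if (k >= (int)pool.size()) k = pool.size() - 1;
    return pool[k];
  }
  double u = R::unif_rand() * tot, acc = 0.0;
  for (int c : pool) {
    acc += pay[c] - mn;
    if (u < acc) return c;
  }
  return pool.back();
}

inline int mutate_level(int lev, double mu) {
  for (int bit = 0; bit < 3; ++bit)
    if (R::unif_rand() < mu) lev ^= (1 << bit);
  return lev;
}

inline void evolve_core(const Adjacency& A,
                        const std::vector<int>& blev,
                        const std::vector<int>& vlev,
                        const std::vector<double>& pay,
                        double mu, bool include_self,
                        std::vector<int>& bnew, std::vector<int>& vnew) {
  const int n = A.n;
  std::vector<int> pool;
  for (int i = 0; i < n; ++i) {
    pool = A.nb[i];
    if (include_self || pool.empty()) pool.push_back(i);
    int parent = roulette_pick(pool, pay);
    bnew[i] = mutate_level(blev[parent], mu);
    vnew[i] = mutate_level(vlev[parent], mu);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_play_round(List adj, IntegerVector blev, IntegerVector vlev,
                    NumericVector payoffs) {
  Adjacency A(adj);
  std::vector<int> b(blev.begin(), blev.end()), v(vlev.begin(), vlev.end());
  std::vector<double> acc(A.n, 0.0);
  std::vector<int> mark(A.n, 0);
  int nd = 0, np = 0, nm = 0;
  play_round_core(A, b, v, payoffs.begin(), acc, mark, nd, np, nm);
  return List::create(_["payoff"] = NumericVector(acc.begin(), acc.end()),
                      _["n_defect"] = nd, _["n_punish"] = np,
                      _["n_meta"] = nm);
}

// Monte-Carlo driver: population-mean payoff per round plus per-agent means.
// [[Rcpp::export]]
List cpp_play_rounds(List adj, IntegerVector blev, IntegerVector vlev,
                     NumericVector payoffs, int nrounds) {
  Adjacency A(adj);
  std::vector<int> b(blev.begin(), blev.end()), v(vlev.begin(), vlev.end());
  std::vector<int> mark(A.n, 0);
  NumericVector round_mean(nrounds);
  std::vector<double> agent_sum(A.n, 0.0), acc;
  int nd = 0, np = 0, nm = 0;
  for (int r = 0; r < nrounds; ++r) {
    acc.assign(A.n, 0.0);
    play_round_core(A, b, v, payoffs.begin(), acc, mark, nd, np, nm);
    double tot = 0.0;
    for (int i = 0; i < A.n; ++i) {
      tot += acc[i];
      agent_sum[i] += acc[i];
    }
    round_mean[r] = tot / A.n;
  }
  NumericVector agent_mean(A.n);
  for (int i = 0; i < A.n; ++i) agent_mean[i] = agent_sum[i] / nrounds;
  return List::create(_["round_mean"] = round_mean,
                      _["agent_mean"] = agent_mean);
}

// [[Rcpp::export]]
IntegerMatrix cpp_evolve(List adj, IntegerVector blev, IntegerVector vlev,
                         NumericVector payoff, double mu, bool include_self) {
  Adjacency A(adj);
  std::vector<int> b(blev.begin(), blev.end()), v(vlev.begin(), vlev.end());
  std::vector<double> pay(payoff.begin(), payoff.end());
  std::vector<int> bn(A.n), vn(A.n);
  evolve_core(A, b, v, pay, mu, include_self, bn, vn);
  IntegerMatrix out(A.n, 2);
  for (int i = 0; i < A.n; ++i) {
    out(i, 0) = bn[i];
    out(i, 1) = vn[i];
  }
  return out;
}

// Full generation loop. blev0/vlev0 of length 0 request a uniform random
// initialization over the 64 joint strategies. Returns per-generation
// population means (length generations + 1, entry 1 = initial state) and
// optional full strategy snapshots every `snapshot_stride` generations.
// [[Rcpp::export]]
List cpp_run_simulation(List adj, IntegerVector blev0, IntegerVector vlev0,
                        NumericVector payoffs, double mu, int rounds,
                        int generations, bool include_self,
                        int snapshot_stride) {
  Adjacency A(adj);
  const int n = A.n;
  std::vector<int> b(n), v(n), bn(n), vn(n), mark(n, 0);
  if (blev0.size() == 0) {
    for (int i = 0; i < n; ++i) {
      b[i] = (int)std::floor(R::unif_rand() * 8.0) & 7;
      v[i] = (int)std::floor(R::unif_rand() * 8.0) & 7;
    }
  } else {
    std::copy(blev0.begin(), blev0.end(), b.begin());
    std::copy(vlev0.begin(), vlev0.end(), v.begin());
  }
  NumericVector mean_b(generations + 1), mean_v(generations + 1);
  auto record = [&](int g) {
    double sb = 0.0, sv = 0.0;
    for (int i = 0; i < n; ++i) {
      sb += b[i];
      sv += v[i];
    }
    mean_b[g] = sb / (7.0 * n);
    mean_v[g] = sv / (7.0 * n);
  };
  record(0);

  std::vector<IntegerMatrix> snaps;
  std::vector<int> snap_gen;
  if (snapshot_stride > 0) {
    IntegerMatrix s0(n, 2);
    for (int i = 0; i < n; ++i) {
      s0(i, 0) = b[i];
      s0(i, 1) = v[i];
    }
    snaps.push_back(s0);
    snap_gen.push_back(0);
  }

  std::vector<double> acc(n);
  int nd = 0, np = 0, nm = 0;
  for (int g = 1; g <= generations; ++g) {
    acc.assign(n, 0.0); // payoffs reset at generation start
    for (int r = 0; r < rounds; ++r)
      play_round_core(A, b, v, payoffs.begin(), acc, mark, nd, np, nm);
    evolve_core(A, b, v, acc, mu, include_self, bn, vn);
    b.swap(bn);
    v.swap(vn);
    record(g);
    if (snapshot_stride > 0 && g % snapshot_stride == 0) {
      IntegerMatrix s(n, 2);
      for (int i = 0; i < n; ++i) {
        s(i, 0) = b[i];
        s(i, 1) = v[i];
      }
      snaps.push_back(s);
      snap_gen.push_back(g);
    }
    if (g % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["mean_b"] = mean_b, _["mean_v"] = mean_v,
                          _["n_defect"] = nd, _["n_punish"] = np,
                          _["n_meta"] = nm);
  if (snapshot_stride > 0) {
    out["snapshots"] = wrap(snaps);
    out["snapshot_generation"] = wrap(snap_gen);
  }
  return out;
}
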