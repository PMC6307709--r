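// Agent-based Monte Carlo engine for the threshold q-voter model on the
// complete graph with random sequential updating.
//
// Randomness comes from four independent substreams (target choice, response
// kind, panel sampling, independence coin), each a splitmix64-seeded
// xorshift128+ generator derived from one user seed. Substreams keep the
// draw sequences aligned across runs that differ only in the initial
// configuration, which makes the global-flip mirror symmetry of the
// dynamics exactly testable.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

namespace {

struct Xorshift128p {
  uint64_t s0, s1;
  void seed_from(uint64_t x) {
    // splitmix64 expansion of the seed into generator state
    auto next = [&x]() {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = next();
    s1 = next();
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double runif() { // uniform in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { // uniform integer in 0..n-1
    return static_cast<int>(runif() * n);
  }
};

struct Streams {
  Xorshift128p target, kind, panel, coin;
  explicit Streams(uint64_t seed) {
    target.seed_from(seed * 4ULL + 1ULL);
    kind.seed_from(seed * 4ULL + 2ULL);
    panel.seed_from(seed * 4ULL + 3ULL);
    coin.seed_from(seed * 4ULL + 4ULL);
  }
};

// One elementary update; returns the change in n_up (-1, 0, +1).
// idx is a scratch permutation of agent ids with pos its inverse
// (pos[id] = index in idx), used for O(q) panel sampling.
inline int elementary_step(std::vector<int>& op, int N, int q, int r, int w,
                           double p, double z, Streams& st,
                           std::vector<int>& idx, std::vector<int>& pos,
                           bool mirror_coin) {
  const int tgt = st.target.below(N);
  const double u_kind = st.kind.runif();
  const int s_tgt = op[tgt];

  if (u_kind >= 1.0 - p * z) { // independence: panel ignored
    double u = st.coin.runif();
    if (mirror_coin) u = 1.0 - u;
    const int s_new = (u < 0.5) ? 1 : -1;
    if (s_new != s_tgt) {
      op[tgt] = s_new;
      return s_new == 1 ? 1 : -1;
    }
    return 0;
  }

  // sample q distinct non-target agents: move the target id to the back,
  // then a partial Fisher-Yates over the remaining N-1 slots
  const int last = N - 1;
  const int tp = pos[tgt];
  std::swap(idx[tp], idx[last]);
  pos[idx[tp]] = tp;
  pos[idx[last]] = last;
  int n_same = 0;
  for (int j = 0; j < q; ++j) {
    const int k = j + st.panel.below(last - j);
    std::swap(idx[j], idx[k]);
    pos[idx[j]] = j;
    pos[idx[k]] = k;
    if (op[idx[j]] == s_tgt) ++n_same;
  }

  bool flip = false;
  if (u_kind < 1.0 - p) { // conformity: >= r opponents in the panel
    flip = (q - n_same) >= r;
  } else {                // anticonformity: >= w panelists share the opinion
    flip = n_same >= w;
  }
  if (flip) {
    op[tgt] = -s_tgt;
    return op[tgt] == 1 ? 1 : -1;
  }
  return 0;
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
Rcpp::List mc_run_cpp(Rcpp::IntegerVector opinions, int q, int r, int w,
                      double p, double z, double duration_mcs,
                      double burn_in_mcs, int thin, double seed,
                      bool record_histogram, bool mirror_coin) {
  const int N = opinions.size();
  std::vector<int> op(opinions.begin(), opinions.end());
  std::vector<int> idx(N), pos(N);
  for (int i = 0; i < N; ++i) { idx[i] = i; pos[i] = i; }

  int n_up = 0;
  for (int i = 0; i < N; ++i) n_up += (op[i] == 1);

  Streams st(static_cast<uint64_t>(seed));

  const long total_mcs = static_cast<long>(duration_mcs);
  const long burn_mcs = static_cast<long>(burn_in_mcs);
  std::vector<double> t_out, m_out;
  std::vector<double> hist(record_histogram ? N + 1 : 0, 0.0);

  t_out.reserve(total_mcs / thin + 2);
  m_out.reserve(total_mcs / thin + 2);

  // sample at t = 0 if there is no burn-in
  if (burn_mcs == 0) {
    t_out.push_back(0.0);
    m_out.push_back((2.0 * n_up - N) / N);
  }

  for (long mcs = 1; mcs <= total_mcs; ++mcs) {
    for (int s = 0; s < N; ++s)
      n_up += elementary_step(op, N, q, r, w, p, z, st, idx, pos, mirror_coin);
    if (mcs > burn_mcs) {
      if ((mcs - burn_mcs) % thin == 0) {
        t_out.push_back(static_cast<double>(mcs));
        m_out.push_back((2.0 * n_up - N) / N);
      }
      if (record_histogram) hist[n_up] += 1.0;
    }
    if (mcs % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("t_mcs") = Rcpp::wrap(t_out),
      Rcpp::Named("m") = Rcpp::wrap(m_out),
      Rcpp::Named("final_opinions") = Rcpp::IntegerVector(op.begin(), op.end()));
  if (record_histogram) out["histogram"] = Rcpp::wrap(hist);
  return out;
}

// Repeated single elementary steps from a fixed configuration; counts the
// outcomes (down-move, no change, up-move) to compare against the analytic
// lambda rates.
// [[Rcpp::export(name = ".mc_step_trials_cpp")]]
Rcpp::IntegerVector mc_step_trials_cpp(int n_up, int N, int q, int r, int w,
                                       double p, double z, int trials,
                                       double seed) {
  std::vector<int> op(N);
  for (int i = 0; i < N; ++i) op[i] = (i < n_up) ? 1 : -1;
  std::vector<int> idx(N), pos(N);
  for (int i = 0; i < N; ++i) { idx[i] = i; pos[i] = i; }
  Streams st(static_cast<uint64_t>(seed));

  int counts[3] = {0, 0, 0}; // down, stay, up
  for (int tr = 0; tr < trials; ++tr) {
    std::vector<int> op_trial = op;
    const int d = elementary_step(op_trial, N, q, r, w, p, z, st, idx, pos, false);
    ++counts[d + 1];
    if ((tr & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::IntegerVector::create(Rcpp::Named("down") = counts[0],
                                     Rcpp::Named("stay") = counts[1],
                                     Rcpp::Named("up") = counts[2]);
}
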