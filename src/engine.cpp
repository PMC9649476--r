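// Stochastic asynchronous Boolean network engine.
//
// Rules arrive compiled to postfix bytecode (triples op, arg1, arg2):
//   op 1 = VAR  (arg1 = node index, freshest within-step value)
//   op 2 = THR  (arg1 = node index, arg2 = delay d): 1 iff the node was 1 at
//          all committed steps t-1 .. t-d (steps before 0 read step 0)
//   op 3 = NOT  (pops 1)
//   op 4 = AND  (arg1 = arity, pops arity)
//   op 5 = OR   (arg1 = arity, pops arity)
//
// Update schemes: random_order (every node once per step, fresh uniform
// permutation, sequential within the step) and single_node (one uniformly
// chosen node per step). Threshold terms always read committed whole-step
// rows, so delay semantics are scheme-independent.
//
// RNG: splitmix64, one generator per repetition seeded with seed + rep
// index, so repetitions are independently reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Program {
  std::vector<int> code;     // flattened triples
  std::vector<int> offset;   // triple offset per rule
  std::vector<int> len;      // number of triples per rule
};

inline int eval_rule(const Program& prog, int rule, const uint8_t* cur,
                     const std::vector<uint8_t>& hist, int n, int t) {
  int stack[128];
  int sp = 0;
  const int* c = prog.code.data() + 3 * prog.offset[rule];
  int m = prog.len[rule];
  for (int k = 0; k < m; ++k) {
    int op = c[3 * k], a1 = c[3 * k + 1], a2 = c[3 * k + 2];
    switch (op) {
    case 1:
      stack[sp++] = cur[a1];
      break;
    case 2: {
      int v = 1;
      for (int d = 1; d <= a2; ++d) {
        int s = t - d;
        if (s < 0) s = 0;
        if (!hist[static_cast<size_t>(s) * n + a1]) { v = 0; break; }
      }
      stack[sp++] = v;
      break;
    }
    case 3:
      stack[sp - 1] = 1 - stack[sp - 1];
      break;
    case 4: {
      int v = 1;
      for (int j = 0; j < a1; ++j) v &= stack[sp - 1 - j];
      sp -= a1;
      stack[sp++] = v;
      break;
    }
    case 5: {
      int v = 0;
      for (int j = 0; j < a1; ++j) v |= stack[sp - 1 - j];
      sp -= a1;
      stack[sp++] = v;
      break;
    }
    default:
      stop("engine: unknown opcode");
    }
  }
  return stack[0];
}

struct Clamps {
  // per node: -1 = none, 0 = KO, 1 = OE; start/end step range (inclusive)
  std::vector<int> mode, start, end;
  explicit Clamps(int n) : mode(n, -1), start(n, 0), end(n, 0) {}
  inline int value_at(int node, int t) const {
    if (mode[node] >= 0 && t >= start[node] && t <= end[node])
      return mode[node];
    return -1;
  }
};

// one repetition; fills hist ((steps+1) x n, row-major by step) and
// optionally records the update order (steps x n, or steps x 1 for
// single_node)
void run_rep(const Program& prog, int n, const std::vector<uint8_t>& init,
             int steps, int scheme, const Clamps& cl,
             const std::vector<double>& act, uint64_t seed,
             std::vector<uint8_t>& hist, std::vector<int>* order_out) {
  SplitMix64 rng(seed);
  for (int i = 0; i < n; ++i) {
    int c = cl.value_at(i, 0);
    hist[i] = (c >= 0) ? static_cast<uint8_t>(c) : init[i];
  }
  std::vector<uint8_t> cur(n);
  std::vector<int> perm(n);
  for (int t = 1; t <= steps; ++t) {
    const uint8_t* prev = hist.data() + static_cast<size_t>(t - 1) * n;
    std::copy(prev, prev + n, cur.begin());
    if (scheme == 0) {  // random_order
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i)
        std::swap(perm[i], perm[rng.below(i + 1)]);
      for (int k = 0; k < n; ++k) {
        int i = perm[k];
        int c = cl.value_at(i, t);
        int v;
        if (c >= 0) {
          v = c;
        } else {
          v = eval_rule(prog, i, cur.data(), hist, n, t);
          if (v == 1 && act[i] < 1.0) v = (rng.unif() < act[i]) ? 1 : 0;
        }
        cur[i] = static_cast<uint8_t>(v);
      }
      if (order_out)
        std::copy(perm.begin(), perm.end(),
                  order_out->begin() + static_cast<size_t>(t - 1) * n);
    } else {  // single_node
      int i = rng.below(n);
      int c = cl.value_at(i, t);
      int v;
      if (c >= 0) {
        v = c;
      } else {
        v = eval_rule(prog, i, cur.data(), hist, n, t);
        if (v == 1 && act[i] < 1.0) v = (rng.unif() < act[i]) ? 1 : 0;
      }
      cur[i] = static_cast<uint8_t>(v);
      if (order_out) (*order_out)[t - 1] = i;
    }
    // clamp dominance on the committed row (covers nodes not updated this
    // step and clamps that begin mid-simulation)
    for (int i = 0; i < n; ++i) {
      int c = cl.value_at(i, t);
      if (c >= 0) cur[i] = static_cast<uint8_t>(c);
    }
    std::copy(cur.begin(), cur.end(),
              hist.begin() + static_cast<size_t>(t) * n);
  }
}

Program make_program(IntegerVector code, IntegerVector offsets,
                     IntegerVector lens) {
  Program p;
  p.code.assign(code.begin(), code.end());
  p.offset.assign(offsets.begin(), offsets.end());
  p.len.assign(lens.begin(), lens.end());
  return p;
}

Clamps make_clamps(int n, IntegerVector cnode, IntegerVector cmode,
                   IntegerVector cstart, IntegerVector cend) {
  Clamps cl(n);
  for (int k = 0; k < cnode.size(); ++k) {
    int i = cnode[k];
    cl.mode[i] = cmode[k];
    cl.start[i] = cstart[k];
    cl.end[i] = cend[k];
  }
  return cl;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_one(IntegerVector code, IntegerVector offsets,
                      IntegerVector lens, int n_nodes, IntegerVector init,
                      int steps, int scheme, double seed,
                      IntegerVector clamp_node, IntegerVector clamp_mode,
                      IntegerVector clamp_start, IntegerVector clamp_end,
                      NumericVector activity, bool record_order) {
  Program prog = make_program(code, offsets, lens);
  Clamps cl = make_clamps(n_nodes, clamp_node, clamp_mode, clamp_start,
                          clamp_end);
  std::vector<double> act(activity.begin(), activity.end());
  std::vector<uint8_t> init8(init.begin(), init.end());
  std::vector<uint8_t> hist(static_cast<size_t>(steps + 1) * n_nodes);
  int ocols = (scheme == 0) ? n_nodes : 1;
  std::vector<int> order;
  if (record_order) order.assign(static_cast<size_t>(steps) * ocols, 0);
  run_rep(prog, n_nodes, init8, steps, scheme, cl, act,
          static_cast<uint64_t>(seed), hist, record_order ? &order : nullptr);
  IntegerMatrix traj(steps + 1, n_nodes);
  for (int t = 0; t <= steps; ++t)
    for (int i = 0; i < n_nodes; ++i)
      traj(t, i) = hist[static_cast<size_t>(t) * n_nodes + i];
  List out = List::create(_["trajectory"] = traj);
  if (record_order) {
    IntegerMatrix om(steps, ocols);
    for (int t = 0; t < steps; ++t)
      for (int j = 0; j < ocols; ++j)
        om(t, j) = order[static_cast<size_t>(t) * ocols + j];
    out["order"] = om;
  }
  return out;
}

// Mean state over repetitions at every step: (steps+1) x n matrix.
// Repetition r uses seed + r.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_mean(IntegerVector code, IntegerVector offsets,
                                IntegerVector lens, int n_nodes,
                                IntegerVector init, int steps, int scheme,
                                int reps, double seed,
                                IntegerVector clamp_node,
                                IntegerVector clamp_mode,
                                IntegerVector clamp_start,
                                IntegerVector clamp_end,
                                NumericVector activity) {
  Program prog = make_program(code, offsets, lens);
  Clamps cl = make_clamps(n_nodes, clamp_node, clamp_mode, clamp_start,
                          clamp_end);
  std::vector<double> act(activity.begin(), activity.end());
  std::vector<uint8_t> init8(init.begin(), init.end());
  std::vector<uint8_t> hist(static_cast<size_t>(steps + 1) * n_nodes);
  std::vector<double> acc(static_cast<size_t>(steps + 1) * n_nodes, 0.0);
  for (int r = 0; r < reps; ++r) {
    run_rep(prog, n_nodes, init8, steps, scheme, cl, act,
            static_cast<uint64_t>(seed) + static_cast<uint64_t>(r), hist,
            nullptr);
    for (size_t k = 0; k < acc.size(); ++k) acc[k] += hist[k];
  }
  NumericMatrix out(steps + 1, n_nodes);
  for (int t = 0; t <= steps; ++t)
    for (int i = 0; i < n_nodes; ++i)
      out(t, i) = acc[static_cast<size_t>(t) * n_nodes + i] / reps;
  return out;
}
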