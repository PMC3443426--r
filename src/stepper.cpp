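#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Compiled model layout (built by compile_for_stepper() on the R side):
//   n          total species count
//   target_idx 0-based species index of each internal rule target
//   rule_type  1 = postfix (RPN) program, 2 = truth-table lookup
//   ops, args  per-rule integer postfix programs
//              op 0 CONST(arg 0/1), 1 VAR(arg = species idx),
//              2 NOT, 3 AND(arg = arity), 4 OR(arg = arity)
//   regs       per-rule 0-based regulator indices (truth-table rules;
//              regulator j is bit j of the lookup index)
//   tts        per-rule raw output columns of length 2^k
//   ext_idx    0-based indices of external species, declaration order
//   stack_need maximal RPN stack depth over all rules

struct CompiledModel {
  int n;
  std::vector<int> target_idx;
  std::vector<int> rule_type;
  std::vector<std::vector<int>> ops, args, regs;
  std::vector<RawVector> tts;
  std::vector<int> ext_idx;
  int stack_need;
};

static CompiledModel unpack(const List& cm) {
  CompiledModel m;
  m.n = as<int>(cm["n"]);
  m.target_idx = as<std::vector<int>>(cm["target_idx"]);
  m.rule_type = as<std::vector<int>>(cm["rule_type"]);
  List ops = cm["ops"], args = cm["args"], regs = cm["regs"], tts = cm["tts"];
  int nr = m.target_idx.size();
  m.ops.resize(nr); m.args.resize(nr); m.regs.resize(nr); m.tts.resize(nr);
  for (int i = 0; i < nr; ++i) {
    if (m.rule_type[i] == 1) {
      m.ops[i] = as<std::vector<int>>(ops[i]);
      m.args[i] = as<std::vector<int>>(args[i]);
    } else {
      m.regs[i] = as<std::vector<int>>(regs[i]);
      m.tts[i] = as<RawVector>(tts[i]);
    }
  }
  m.ext_idx = as<std::vector<int>>(cm["ext_idx"]);
  m.stack_need = as<int>(cm["stack_need"]);
  return m;
}

static inline int eval_rule(const CompiledModel& m, int r,
                            const std::vector<int>& prev,
                            std::vector<int>& stack) {
  if (m.rule_type[r] == 2) {
    const std::vector<int>& regs = m.regs[r];
    size_t idx = 0;
    for (size_t j = 0; j < regs.size(); ++j)
      idx |= (static_cast<size_t>(prev[regs[j]]) << j);
    return m.tts[r][idx] != 0;
  }
  const std::vector<int>& ops = m.ops[r];
  const std::vector<int>& args = m.args[r];
  int sp = 0;
  for (size_t p = 0; p < ops.size(); ++p) {
    switch (ops[p]) {
    case 0: stack[sp++] = args[p]; break;
    case 1: stack[sp++] = prev[args[p]]; break;
    case 2: stack[sp - 1] = !stack[sp - 1]; break;
    case 3: {
      int k = args[p], v = 1;
      for (int j = sp - k; j < sp; ++j) v = v && stack[j];
      sp -= k; stack[sp++] = v; break;
    }
    case 4: {
      int k = args[p], v = 0;
      for (int j = sp - k; j < sp; ++j) v = v || stack[j];
      sp -= k; stack[sp++] = v; break;
    }
    default: stop("corrupt rule program");
    }
  }
  return stack[0];
}

// one synchronous update; externals either Bernoulli(p) or fixed levels
static inline void step_state(const CompiledModel& m,
                              const std::vector<int>& prev,
                              std::vector<int>& next,
                              const double* ext_p, const int* ext_fixed,
                              const std::vector<int>& mut_idx,
                              const std::vector<int>& mut_val,
                              std::vector<int>& stack) {
  for (size_t r = 0; r < m.target_idx.size(); ++r)
    next[m.target_idx[r]] = eval_rule(m, r, prev, stack);
  for (size_t j = 0; j < m.ext_idx.size(); ++j) {
    if (ext_fixed) next[m.ext_idx[j]] = ext_fixed[j];
    else next[m.ext_idx[j]] = (unif_rand() < ext_p[j]) ? 1 : 0;
  }
  for (size_t j = 0; j < mut_idx.size(); ++j)
    next[mut_idx[j]] = mut_val[j];
}

// [[Rcpp::export]]
LogicalMatrix cpp_simulate(List cm, NumericVector ext_p, IntegerVector mut_idx,
                           IntegerVector mut_val, LogicalVector init,
                           int steps) {
  CompiledModel m = unpack(cm);
  std::vector<int> prev(m.n), next(m.n), stack(std::max(m.stack_need, 1));
  std::vector<int> mi = as<std::vector<int>>(mut_idx);
  std::vector<int> mv = as<std::vector<int>>(mut_val);
  for (int i = 0; i < m.n; ++i) prev[i] = init[i] ? 1 : 0;
  LogicalMatrix out(steps + 1, m.n);
  for (int i = 0; i < m.n; ++i) out(0, i) = prev[i];
  for (int t = 1; t <= steps; ++t) {
    step_state(m, prev, next, REAL(ext_p), nullptr, mi, mv, stack);
    for (int i = 0; i < m.n; ++i) out(t, i) = next[i];
    prev.swap(next);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_steady_counts(List cm, NumericVector ext_p,
                                IntegerVector mut_idx, IntegerVector mut_val,
                                LogicalVector init, int burn_in,
                                int measure) {
  CompiledModel m = unpack(cm);
  std::vector<int> prev(m.n), next(m.n), stack(std::max(m.stack_need, 1));
  std::vector<int> mi = as<std::vector<int>>(mut_idx);
  std::vector<int> mv = as<std::vector<int>>(mut_val);
  for (int i = 0; i < m.n; ++i) prev[i] = init[i] ? 1 : 0;
  NumericVector counts(m.n);
  for (int t = 1; t <= burn_in + measure; ++t) {
    step_state(m, prev, next, REAL(ext_p), nullptr, mi, mv, stack);
    if (t > burn_in)
      for (int i = 0; i < m.n; ++i) counts[i] += next[i];
    prev.swap(next);
  }
  return counts;
}

// deterministic synchronous iteration until a state repeats
// [[Rcpp::export]]
List cpp_find_attractor(List cm, IntegerVector ext_fixed, IntegerVector mut_idx,
                        IntegerVector mut_val, LogicalVector init,
                        double cap) {
  CompiledModel m = unpack(cm);
  std::vector<int> prev(m.n), next(m.n), stack(std::max(m.stack_need, 1));
  std::vector<int> mi = as<std::vector<int>>(mut_idx);
  std::vector<int> mv = as<std::vector<int>>(mut_val);
  std::vector<int> ef = as<std::vector<int>>(ext_fixed);
  for (int i = 0; i < m.n; ++i) prev[i] = init[i] ? 1 : 0;

  std::unordered_map<std::string, int> seen;
  std::vector<std::string> history;
  std::string key(m.n, '\0');
  long long capn = static_cast<long long>(cap);
  int t = 0;
  while (true) {
    for (int i = 0; i < m.n; ++i) key[i] = static_cast<char>(prev[i]);
    auto it = seen.find(key);
    if (it != seen.end()) {
      int first = it->second;
      int len = t - first;
      LogicalMatrix cyc(len, m.n);
      for (int s = 0; s < len; ++s)
        for (int i = 0; i < m.n; ++i)
          cyc(s, i) = history[first + s][i] != 0;
      return List::create(_["transient_length"] = first,
                          _["cycle"] = cyc);
    }
    seen.emplace(key, t);
    history.push_back(key);
    if (t >= capn)
      stop("no attractor within cap of %ld iterations", capn);
    step_state(m, prev, next, nullptr, ef.data(), mi, mv, stack);
    prev.swap(next);
    ++t;
  }
}
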