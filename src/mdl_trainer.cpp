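// Coordinate-descent trainer for the two-part MDL segmentation model.
//
// Total cost (bits) = lexicon cost + alpha * corpus cost, where
//   lexicon cost = sum over morph types of the code length of the morph
//                  string under fixed letter probabilities (plus an
//                  end-of-morph marker), and
//   corpus cost  = sum over morph tokens of -log2 P(morph), with P the
//                  maximum-likelihood unigram over current token counts
//                = N*log2(N) - sum_m c_m*log2(c_m).
//
// Words arrive as byte strings; the R wrapper maps every distinct character
// to a single byte beforehand, so split points are always character
// boundaries. Training is per-word exhaustive re-analysis (all 2^(L-1)
// segmentations for short words, a memoized split DP proposal for long
// ones), word order shuffled each epoch, several seeded restarts.

#include <Rcpp.h>
#include <unordered_map>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

const double TIE_TOL = 1e-6;

inline double xlog2x(double c) { return c > 0 ? c * std::log2(c) : 0.0; }

struct State {
  std::unordered_map<std::string, double> counts;
  double N = 0.0;          // morph tokens
  double sumclogc = 0.0;   // sum c*log2 c
  double lexcost = 0.0;    // sum of string costs over types present
  const std::vector<double>* byteCost; // -log2 p per byte value
  double eomCost;

  double stringCost(const std::string& m) const {
    double s = eomCost;
    for (unsigned char ch : m) s += (*byteCost)[ch];
    return s;
  }
  void add(const std::string& m, double c) {
    auto it = counts.find(m);
    if (it == counts.end()) {
      lexcost += stringCost(m);
      counts.emplace(m, c);
      sumclogc += xlog2x(c);
    } else {
      sumclogc -= xlog2x(it->second);
      it->second += c;
      sumclogc += xlog2x(it->second);
    }
    N += c;
  }
  void remove(const std::string& m, double c) {
    auto it = counts.find(m);
    sumclogc -= xlog2x(it->second);
    it->second -= c;
    if (it->second < 1e-9) {
      lexcost -= stringCost(m);
      counts.erase(it);
    } else {
      sumclogc += xlog2x(it->second);
    }
    N -= c;
  }
  double cost(double alpha) const {
    double corpus = (N > 0) ? N * std::log2(N) - sumclogc : 0.0;
    return lexcost + alpha * corpus;
  }
};

typedef std::vector<std::string> Seg;

void addSeg(State& st, const Seg& s, double c) {
  for (const auto& m : s) st.add(m, c);
}
void removeSeg(State& st, const Seg& s, double c) {
  for (const auto& m : s) st.remove(m, c);
}

// Tie-break order: fewer morphs first, then leftmost-longest (at the first
// position where morph lengths differ, the longer morph wins).
bool tiebreakLess(const Seg& a, const Seg& b) {
  if (a.size() != b.size()) return a.size() < b.size();
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i].size() != b[i].size()) return a[i].size() > b[i].size();
  }
  return false;
}

Seg segFromMask(const std::string& w, unsigned long mask) {
  Seg out;
  size_t start = 0;
  for (size_t i = 1; i < w.size(); ++i) {
    if (mask & (1UL << (i - 1))) {
      out.push_back(w.substr(start, i - start));
      start = i;
    }
  }
  out.push_back(w.substr(start));
  return out;
}

// Split DP proposal for long words, using an additive approximation of the
// per-morph cost under the current (word-removed) state.
Seg dpProposal(const State& st, const std::string& w, double c, double alpha) {
  size_t L = w.size();
  double denom = st.N + c;
  std::vector<double> best(L + 1, 0.0);
  std::vector<int> nmorph(L + 1, 0);
  std::vector<size_t> back(L + 1, 0);
  for (size_t i = 1; i <= L; ++i) {
    best[i] = R_PosInf;
    for (size_t j = 0; j < i; ++j) {
      std::string m = w.substr(j, i - j);
      auto it = st.counts.find(m);
      double mc;
      if (it != st.counts.end()) {
        mc = alpha * (-std::log2((it->second + c) / denom));
      } else {
        mc = st.stringCost(m) + alpha * (-std::log2(c / denom));
      }
      double cand = best[j] + mc;
      bool better = cand < best[i] - TIE_TOL ||
        (cand <= best[i] + TIE_TOL && nmorph[j] + 1 < nmorph[i]);
      if (better) {
        best[i] = cand;
        nmorph[i] = nmorph[j] + 1;
        back[i] = j;
      }
    }
  }
  Seg rev;
  size_t pos = L;
  while (pos > 0) {
    size_t j = back[pos];
    rev.push_back(w.substr(j, pos - j));
    pos = j;
  }
  return Seg(rev.rbegin(), rev.rend());
}

// Exact evaluation of one candidate: temporarily add it, read the cost off.
double evalSeg(State& st, const Seg& s, double c, double alpha) {
  addSeg(st, s, c);
  double cost = st.cost(alpha);
  removeSeg(st, s, c);
  return cost;
}

bool optimizeWord(State& st, const std::string& w, double c, Seg& cur,
                  double alpha, int maxExactLen) {
  removeSeg(st, cur, c);
  std::vector<Seg> cands;
  if ((int)w.size() <= maxExactLen) {
    unsigned long nmask = 1UL << (w.size() - 1);
    cands.reserve(nmask);
    for (unsigned long mask = 0; mask < nmask; ++mask)
      cands.push_back(segFromMask(w, mask));
  } else {
    cands.push_back(Seg{w});
    cands.push_back(cur);
    cands.push_back(dpProposal(st, w, c, alpha));
  }
  double bestCost = R_PosInf;
  const Seg* best = nullptr;
  for (const auto& s : cands) {
    double cost = evalSeg(st, s, c, alpha);
    if (cost < bestCost - TIE_TOL ||
        (best != nullptr && cost <= bestCost + TIE_TOL && tiebreakLess(s, *best))) {
      bestCost = cost;
      best = &s;
    }
  }
  bool changed = !(*best == cur);
  Seg chosen = *best;
  addSeg(st, chosen, c);
  cur = chosen;
  return changed;
}

State buildState(const std::vector<Seg>& segs, const std::vector<double>& cnts,
                 const std::vector<double>& byteCost, double eomCost) {
  State st;
  st.byteCost = &byteCost;
  st.eomCost = eomCost;
  for (size_t i = 0; i < segs.size(); ++i) addSeg(st, segs[i], cnts[i]);
  return st;
}

long totalMorphs(const std::vector<Seg>& segs) {
  long n = 0;
  for (const auto& s : segs) n += s.size();
  return n;
}

} // namespace

// [[Rcpp::export]]
List mdl_train_cpp(CharacterVector words, NumericVector counts, double alpha,
                   NumericVector byte_cost, double eom_cost, int max_epochs,
                   double convergence_tol, int seed, int n_restarts,
                   int max_exact_len) {
  int nw = words.size();
  std::vector<std::string> ws(nw);
  std::vector<double> cs(nw);
  for (int i = 0; i < nw; ++i) {
    ws[i] = as<std::string>(words[i]);
    cs[i] = counts[i];
  }
  std::vector<double> bc(byte_cost.begin(), byte_cost.end());

  std::vector<Seg> bestSegs;
  double bestCost = R_PosInf;
  bool bestConverged = false;

  for (int r = 0; r < n_restarts; ++r) {
    std::vector<Seg> segs(nw);
    if (r == 0) {                       // whole-word init
      for (int i = 0; i < nw; ++i) segs[i] = Seg{ws[i]};
    } else if (r == 1) {                // fully-split init
      for (int i = 0; i < nw; ++i) {
        Seg s;
        for (char ch : ws[i]) s.push_back(std::string(1, ch));
        segs[i] = s;
      }
    } else {                            // random binary splits
      std::mt19937 rg((unsigned)(seed * 7919 + r));
      std::bernoulli_distribution coin(0.5);
      for (int i = 0; i < nw; ++i) {
        unsigned long mask = 0;
        for (size_t b = 0; b + 1 < ws[i].size(); ++b)
          if (coin(rg)) mask |= (1UL << b);
        segs[i] = segFromMask(ws[i], mask);
      }
    }

    State st = buildState(segs, cs, bc, eom_cost);
    double prev = st.cost(alpha);
    bool converged = false;
    std::vector<int> order(nw);
    for (int i = 0; i < nw; ++i) order[i] = i;
    std::mt19937 rng((unsigned)(seed + 1000003 * (r + 1)));

    for (int epoch = 0; epoch < max_epochs; ++epoch) {
      std::shuffle(order.begin(), order.end(), rng);
      bool changed = false;
      for (int idx : order)
        if (optimizeWord(st, ws[idx], cs[idx], segs[idx], alpha, max_exact_len))
          changed = true;
      // rebuild to cancel floating-point drift before the convergence test
      st = buildState(segs, cs, bc, eom_cost);
      double cur = st.cost(alpha);
      double rel = (prev - cur) / std::max(1.0, std::fabs(prev));
      prev = cur;
      if (!changed || rel < convergence_tol) { converged = true; break; }
      Rcpp::checkUserInterrupt();
    }

    double finalCost = buildState(segs, cs, bc, eom_cost).cost(alpha);
    bool better = finalCost < bestCost - TIE_TOL ||
      (finalCost <= bestCost + TIE_TOL && !bestSegs.empty() &&
       totalMorphs(segs) < totalMorphs(bestSegs));
    if (bestSegs.empty() || better) {
      bestSegs = segs;
      bestCost = finalCost;
      bestConverged = converged;
    }
  }

  State st = buildState(bestSegs, cs, bc, eom_cost);
  List segOut(nw);
  for (int i = 0; i < nw; ++i) {
    CharacterVector s(bestSegs[i].size());
    for (size_t j = 0; j < bestSegs[i].size(); ++j) s[j] = bestSegs[i][j];
    segOut[i] = s;
  }
  std::vector<std::string> lexNames;
  std::vector<double> lexCounts;
  lexNames.reserve(st.counts.size());
  for (const auto& kv : st.counts) {
    lexNames.push_back(kv.first);
    lexCounts.push_back(kv.second);
  }
  NumericVector lex(lexCounts.begin(), lexCounts.end());
  lex.names() = CharacterVector(lexNames.begin(), lexNames.end());

  return List::create(
    _["segmentations"] = segOut,
    _["lexicon"] = lex,
    _["final_cost"] = bestCost,
    _["converged"] = bestConverged,
    _["n_morph_tokens"] = st.N);
}
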