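#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Exact two-sided Fisher (Freeman-Halton) test for an r x c contingency
// table, probability-mass criterion: p = sum of probabilities of all tables
// sharing the observed margins whose multivariate hypergeometric probability
// does not exceed that of the observed table (log-space tie tolerance).
//
// Network algorithm: tables are enumerated cell by cell in column-major
// order; a node is (cell position, vector of remaining row sums).  A backward
// dynamic-programming pass records, for every reachable node, the minimum,
// maximum and total (log-sum-exp) completion weight, where the weight of a
// table is -sum(lfactorial(cell)).  A forward depth-first pass then prunes
// whole subtrees: if even the heaviest completion stays at or below the
// observed log-probability the subtree's entire mass is added in one step; if
// even the lightest completion exceeds it the subtree is skipped.

namespace {

struct NodeVals {
  double minW, maxW, massW;
};

// log(exp(a) + exp(b)) stable
inline double logAdd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct FisherDP {
  int R, C, N;
  std::vector<int> rs, cs;          // row / column margins
  std::vector<double> lfact;        // lfactorial(0..N)
  std::vector<int> csCum;           // cumulative column sums (prefix, exclusive)
  std::vector<uint64_t> radixMul;   // mixed-radix multipliers for state keys
  // one state map per stage; stage m = j*R + i for j in 0..C-2, i in 0..R-1
  std::vector< std::unordered_map<uint64_t, NodeVals> > stage;
  std::vector<int> sufRow;          // suffix sums of row margins (unused bound helper)
  double logT;                      // inclusion threshold (log scale)
  double pLog;                      // accumulated log p
  double massCheck;                 // log total mass from root (should be ~ -const)
  long long visited, visitBudget, peakFrontier;

  uint64_t key(const std::vector<int>& s) const {
    uint64_t k = 0;
    for (int i = 0; i < R; ++i) k += (uint64_t)s[i] * radixMul[i];
    return k;
  }

  // remaining count to place in column j when the state is s and we are about
  // to fill cell (i, j): derived from margin bookkeeping
  inline int colRemaining(const std::vector<int>& s, int j) const {
    int placed = 0;
    for (int i = 0; i < R; ++i) placed += s[i];
    placed = N - placed;                 // total placed so far
    return cs[j] - (placed - csCum[j]);  // what is left for column j
  }

  // completion weight of the forced last column
  inline double lastColW(const std::vector<int>& s) const {
    double w = 0;
    for (int i = 0; i < R; ++i) w -= lfact[s[i]];
    return w;
  }

  void buildStages(long long maxStates) {
    int S = (C - 1) * R;
    stage.assign(S, {});
    std::vector<int> root(rs);
    stage[0].emplace(key(root), NodeVals{0, 0, 0});
    // forward reachability, stage by stage
    std::vector<int> s(R), s2(R);
    long long total = 0;
    for (int m = 0; m < S - 1; ++m) {
      int j = m / R, i = m % R;
      std::unordered_map<uint64_t, NodeVals>& cur = stage[m];
      std::unordered_map<uint64_t, NodeVals>& nxt = stage[m + 1];
      for (auto& kv : cur) {
        uint64_t k = kv.first;
        for (int t = R - 1; t >= 0; --t) { s[t] = (int)((k / radixMul[t]) % (uint64_t)(rs[t] + 1)); }
        int rem = colRemaining(s, j);
        int below = 0;
        for (int t = i + 1; t < R; ++t) below += s[t];
        int lo = std::max(0, rem - below), hi = std::min(s[i], rem);
        for (int x = lo; x <= hi; ++x) {
          s2 = s; s2[i] -= x;
          uint64_t k2 = key(s2);
          if (nxt.emplace(k2, NodeVals{0, 0, 0}).second) {
            if (++total > maxStates)
              stop("exact mode state budget exceeded (%lld states); use method = \"montecarlo\"", total);
          }
        }
      }
    }
    // backward value pass
    for (int m = S - 1; m >= 0; --m) {
      int j = m / R, i = m % R;
      bool lastStage = (m == S - 1);
      for (auto& kv : stage[m]) {
        uint64_t k = kv.first;
        for (int t = R - 1; t >= 0; --t) s[t] = (int)((k / radixMul[t]) % (uint64_t)(rs[t] + 1));
        int rem = colRemaining(s, j);
        int below = 0;
        for (int t = i + 1; t < R; ++t) below += s[t];
        int lo = std::max(0, rem - below), hi = std::min(s[i], rem);
        double mn = R_PosInf, mx = R_NegInf, ms = R_NegInf;
        for (int x = lo; x <= hi; ++x) {
          double w = -lfact[x];
          s2 = s; s2[i] -= x;
          double cmn, cmx, cms;
          if (lastStage) {
            // child is the start of the forced last column
            double lw = lastColW(s2);
            cmn = cmx = cms = lw;
          } else {
            const NodeVals& nv = stage[m + 1].at(key(s2));
            cmn = nv.minW; cmx = nv.maxW; cms = nv.massW;
          }
          if (w + cmn < mn) mn = w + cmn;
          if (w + cmx > mx) mx = w + cmx;
          ms = logAdd(ms, w + cms);
        }
        kv.second = NodeVals{mn, mx, ms};
      }
    }
  }

  bool dfs(int m, std::vector<int>& s, double acc) {
    if (++visited > visitBudget) return false;  // fall back to merged mode
    int S = (C - 1) * R;
    const NodeVals& nv = stage[m].at(key(s));
    if (acc + nv.maxW <= logT) { pLog = logAdd(pLog, acc + nv.massW); return true; }
    if (acc + nv.minW > logT) return true;
    int j = m / R, i = m % R;
    int rem = colRemaining(s, j);
    int below = 0;
    for (int t = i + 1; t < R; ++t) below += s[t];
    int lo = std::max(0, rem - below), hi = std::min(s[i], rem);
    for (int x = lo; x <= hi; ++x) {
      double w = acc - lfact[x];
      s[i] -= x;
      if (m == S - 1) {
        double tot = w + lastColW(s);
        if (tot <= logT) pLog = logAdd(pLog, tot);
      } else {
        if (!dfs(m + 1, s, w)) { s[i] += x; return false; }
      }
      s[i] += x;
    }
    return true;
  }

  // Binned log-space distribution sweep for tables whose enumeration tree
  // is too large for path-by-path traversal.  The frontier carries the
  // joint distribution of (remaining row sums, accumulated log-weight
  // binned to `grid`) in dense per-node arrays; a bin's representative
  // weight is its canonical grid value, so rounding error is bounded by
  // stages * grid / 2 in log space (in practice about the grid itself).
  // Bins whose completions all fall at or below the threshold contribute
  // their node's total completion mass immediately; bins whose completions
  // all exceed it are dropped on the spot, so only the ambiguous band
  // (completion-weight spread around the threshold) is ever stored.
  void frontierSweep(double grid, long long groupBudget) {
    int S = (C - 1) * R;
    double safety = 0.5 * grid * S + grid;  // max accumulated rounding error
    const float NEG = -std::numeric_limits<float>::infinity();

    // forward accumulated-weight bounds per node
    std::vector< std::unordered_map<uint64_t, std::pair<double,double> > > fb(S);
    std::vector<int> s(R), s2(R);
    fb[0][key(std::vector<int>(rs))] = std::make_pair(0.0, 0.0);
    for (int m = 0; m + 1 < S; ++m) {
      int j = m / R, i = m % R;
      for (auto& kv : fb[m]) {
        uint64_t k = kv.first;
        for (int t = R - 1; t >= 0; --t) s[t] = (int)((k / radixMul[t]) % (uint64_t)(rs[t] + 1));
        int rem = colRemaining(s, j);
        int below = 0;
        for (int t = i + 1; t < R; ++t) below += s[t];
        int lo = std::max(0, rem - below), hi = std::min(s[i], rem);
        for (int x = lo; x <= hi; ++x) {
          s2 = s; s2[i] -= x;
          double a0 = kv.second.first - lfact[x];
          double a1 = kv.second.second - lfact[x];
          auto ins = fb[m + 1].emplace(key(s2), std::make_pair(a0, a1));
          if (!ins.second) {
            if (a0 < ins.first->second.first) ins.first->second.first = a0;
            if (a1 > ins.first->second.second) ins.first->second.second = a1;
          }
        }
      }
    }

    // per-node dense bin windows restricted to the ambiguous band
    struct Win { int64_t b0; int64_t len; size_t off; };
    std::vector< std::unordered_map<uint64_t, Win> > win(S);
    std::vector<size_t> stageBins(S, 0);
    for (int m = 0; m < S; ++m) {
      size_t tot = 0;
      for (auto& kv : fb[m]) {
        const NodeVals& nv = stage[m].at(kv.first);
        // keep acc only when neither bound test can resolve it:
        //   logT - safety - maxW < acc <= logT + safety - minW
        double aLo = std::max(kv.second.first, logT - safety - nv.maxW);
        double aHi = std::min(kv.second.second, logT + safety - nv.minW);
        if (aHi < aLo) continue;
        // margin for accumulated representative drift (< safety in log space)
        int64_t drift = (int64_t)(safety / grid) + 2;
        int64_t b0 = (int64_t)std::llround(-aHi / grid) - drift;
        int64_t b1 = (int64_t)std::llround(-aLo / grid) + drift;
        Win w; w.b0 = b0; w.len = b1 - b0 + 1; w.off = tot;
        tot += (size_t)w.len;
        win[m].emplace(kv.first, w);
      }
      stageBins[m] = tot;
      if ((long long)tot > groupBudget)
        stop("exact mode state budget exceeded; use method = \"montecarlo\"");
      if ((long long)tot > peakFrontier) peakFrontier = (long long)tot;
    }

    std::vector<float> curBuf, nxtBuf;
    pLog = R_NegInf;

    // log-sum-exp into a float cell
    auto cellAdd = [](float& cell, double val) {
      if (cell == -std::numeric_limits<float>::infinity()) {
        cell = (float)val;
      } else {
        double a = cell, b = val, mx = a > b ? a : b;
        cell = (float)(mx + std::log(std::exp(a - mx) + std::exp(b - mx)));
      }
    };

    // seed the root (acc = 0, bin 0); resolve immediately if outside band
    {
      uint64_t rk = key(std::vector<int>(rs));
      const NodeVals& nv = stage[0].at(rk);
      if (0.0 + safety + nv.maxW <= logT) { pLog = nv.massW; return; }
      if (0.0 - safety + nv.minW > logT) return;
      curBuf.assign(stageBins[0], NEG);
      const Win& w = win[0].at(rk);
      curBuf[w.off + (0 - w.b0)] = 0.0f;
    }

    for (int m = 0; m < S; ++m) {
      int j = m / R, i = m % R;
      bool last = (m == S - 1);
      if (!last) nxtBuf.assign(stageBins[m + 1], NEG);
      for (auto& kv : win[m]) {
        uint64_t k = kv.first;
        const Win& w = kv.second;
        for (int t = R - 1; t >= 0; --t) s[t] = (int)((k / radixMul[t]) % (uint64_t)(rs[t] + 1));
        int rem = colRemaining(s, j);
        int below = 0;
        for (int t = i + 1; t < R; ++t) below += s[t];
        int lo = std::max(0, rem - below), hi = std::min(s[i], rem);
        for (int x = lo; x <= hi; ++x) {
          s2 = s; s2[i] -= x;
          int64_t binOff = (int64_t)std::llround(lfact[x] / grid);
          if (last) {
            double lcw = lastColW(s2);
            for (int64_t b = 0; b < w.len; ++b) {
              float L = curBuf[w.off + b];
              if (L == NEG) continue;
              double acc = -grid * (double)(w.b0 + b);
              double tot = acc - lfact[x] + lcw;
              if (tot <= logT) pLog = logAdd(pLog, (double)L - lfact[x] + lcw);
            }
          } else {
            uint64_t k2 = key(s2);
            const NodeVals& nv = stage[m + 1].at(k2);
            auto wit = win[m + 1].find(k2);
            for (int64_t b = 0; b < w.len; ++b) {
              float L = curBuf[w.off + b];
              if (L == NEG) continue;
              double Lc = (double)L - lfact[x];
              int64_t bc = w.b0 + b + binOff;
              double acc = -grid * (double)bc;
              if (acc + safety + nv.maxW <= logT) {
                pLog = logAdd(pLog, Lc + nv.massW);
              } else if (acc - safety + nv.minW > logT) {
                // provably above the threshold: drop
              } else if (wit == win[m + 1].end() ||
                         bc < wit->second.b0 ||
                         bc >= wit->second.b0 + wit->second.len) {
                // safety-margin edge case: no storable window cell; resolve
                // by the midpoint bound (error confined to the margin band)
                if (acc + 0.5 * (nv.minW + nv.maxW) <= logT)
                  pLog = logAdd(pLog, Lc + nv.massW);
              } else {
                const Win& wc = wit->second;
                cellAdd(nxtBuf[wc.off + (bc - wc.b0)], Lc);
              }
            }
          }
        }
      }
      if (!last) curBuf.swap(nxtBuf);
      Rcpp::checkUserInterrupt();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".fisherExactNetwork")]]
List fisherExactNetwork(IntegerMatrix counts0, double logTieTol = 1e-7,
                        double maxStates = 2e7, double visitBudget = 2e7,
                        double mergeGrid = 5e-3, double groupBudget = 8e7) {
  // sort margins descending: p is invariant under row/column permutation and
  // large columns first lets the completion bounds resolve the bulk earlier
  IntegerMatrix counts(counts0.nrow(), counts0.ncol());
  {
    int R = counts0.nrow(), C = counts0.ncol();
    std::vector<std::pair<int,int> > rord(R), cord(C);
    for (int i = 0; i < R; ++i) {
      int t = 0; for (int j = 0; j < C; ++j) t += counts0(i, j);
      rord[i] = std::make_pair(-t, i);
    }
    for (int j = 0; j < C; ++j) {
      int t = 0; for (int i = 0; i < R; ++i) t += counts0(i, j);
      cord[j] = std::make_pair(-t, j);
    }
    std::sort(rord.begin(), rord.end());
    std::sort(cord.begin(), cord.end());
    for (int i = 0; i < R; ++i)
      for (int j = 0; j < C; ++j)
        counts(i, j) = counts0(rord[i].second, cord[j].second);
  }
  FisherDP dp;
  dp.R = counts.nrow(); dp.C = counts.ncol();
  if (dp.R < 2 || dp.C < 2) stop("table must be at least 2 x 2");
  dp.rs.assign(dp.R, 0); dp.cs.assign(dp.C, 0);
  for (int i = 0; i < dp.R; ++i)
    for (int j = 0; j < dp.C; ++j) {
      int v = counts(i, j);
      if (v == NA_INTEGER || v < 0) stop("counts must be non-negative integers");
      dp.rs[i] += v; dp.cs[j] += v;
    }
  dp.N = 0;
  for (int j = 0; j < dp.C; ++j) dp.N += dp.cs[j];
  if (dp.N == 0) stop("table total must be positive");

  dp.lfact.resize(dp.N + 1);
  dp.lfact[0] = 0.0;
  for (int n = 1; n <= dp.N; ++n) dp.lfact[n] = dp.lfact[n - 1] + std::log((double)n);
  dp.csCum.assign(dp.C, 0);
  for (int j = 1; j < dp.C; ++j) dp.csCum[j] = dp.csCum[j - 1] + dp.cs[j - 1];
  dp.radixMul.assign(dp.R, 1);
  for (int i = 1; i < dp.R; ++i)
    dp.radixMul[i] = dp.radixMul[i - 1] * (uint64_t)(dp.rs[i - 1] + 1);

  // log P(table) = const + weight(table), weight = -sum lfact(cells)
  double cnst = -dp.lfact[dp.N];
  for (int i = 0; i < dp.R; ++i) cnst += dp.lfact[dp.rs[i]];
  for (int j = 0; j < dp.C; ++j) cnst += dp.lfact[dp.cs[j]];
  double wObs = 0;
  for (int i = 0; i < dp.R; ++i)
    for (int j = 0; j < dp.C; ++j) wObs -= dp.lfact[counts(i, j)];

  dp.logT = wObs + logTieTol;  // threshold on weight scale (const cancels)
  dp.pLog = R_NegInf;
  dp.visited = 0; dp.visitBudget = (long long)visitBudget;
  dp.peakFrontier = 0;

  dp.buildStages((long long)maxStates);
  std::vector<int> root(dp.rs);
  dp.massCheck = cnst + dp.stage[0].at(dp.key(root)).massW;
  bool exactPath = dp.dfs(0, root, 0.0);
  std::string mode = "enumeration";
  if (!exactPath) {
    if (dp.radixMul[dp.R - 1] * (uint64_t)(dp.rs[dp.R - 1] + 1) >= (1ULL << 31))
      stop("table too large for exact mode; use method = \"montecarlo\"");
    dp.frontierSweep(mergeGrid, (long long)groupBudget);
    mode = "merged";
  }

  double logP = cnst + dp.pLog;
  double p = std::exp(logP);
  if (p > 1.0) p = 1.0;
  return List::create(_["p"] = p, _["logP"] = logP,
                      _["logPObs"] = cnst + wObs,
                      _["totalMassLog"] = dp.massCheck,
                      _["statesVisited"] = (double)dp.visited,
                      _["peakFrontier"] = (double)dp.peakFrontier,
                      _["mode"] = mode);
}
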