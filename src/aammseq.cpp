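#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

// base-2 Shannon entropy of a probability vector
static inline double entropy2(const double* p, int A) {
  double h = 0.0;
  for (int a = 0; a < A; ++a)
    if (p[a] > 0.0) h -= p[a] * std::log2(p[a]);
  return h;
}

// weighted Jensen-Shannon distance between clusters held in slots i and j.
// Contexts are rows of nodeP; hp/hq are cached entropies. When scaled, the
// divergence is multiplied by the total occurrence weight so rare contexts
// merge first.
static inline double pair_distance(const double* p, const double* q,
                                   double wp, double wq, double hp, double hq,
                                   int A, bool scaled, std::vector<double>& mixbuf) {
  double tot = wp + wq;
  if (tot <= 0.0) return 0.0;
  double fp = wp / tot, fq = wq / tot;
  for (int a = 0; a < A; ++a) mixbuf[a] = fp * p[a] + fq * q[a];
  double js = entropy2(mixbuf.data(), A) - fp * hp - fq * hq;
  if (js < 0.0) js = 0.0; // guard tiny negative rounding
  return scaled ? tot * js : js;
}

struct PairKey {
  int lo, hi;
  PairKey(int a, int b) : lo(a < b ? a : b), hi(a < b ? b : a) {}
  bool operator<(const PairKey& o) const {
    return lo < o.lo || (lo == o.lo && hi < o.hi);
  }
};

// true if candidate (d1,k1) beats incumbent (d2,k2); ties broken by the
// lexicographically smallest (min node id, max node id) pair
static inline bool better(double d1, const PairKey& k1, double d2, const PairKey& k2) {
  if (d1 < d2) return true;
  if (d1 > d2) return false;
  return k1 < k2;
}

// Greedy agglomeration of N contexts into a binary merge tree.
// P: N x A matrix of next-symbol distributions; w: occurrence weights.
// Returns 1-based merge records plus contexts/weights for all 2N-1 nodes.
// [[Rcpp::export(name = ".agglomerate_cpp")]]
List agglomerate_cpp(NumericMatrix P, NumericVector w, bool scaled) {
  const int N = P.nrow(), A = P.ncol();
  if (N < 1) stop("need at least one context");
  const int M = 2 * N - 1;

  std::vector<double> nodeP((size_t)M * A), nodeW(M), nodeH(M);
  for (int i = 0; i < N; ++i) {
    for (int a = 0; a < A; ++a) nodeP[(size_t)i * A + a] = P(i, a);
    nodeW[i] = w[i];
    nodeH[i] = entropy2(&nodeP[(size_t)i * A], A);
  }

  IntegerMatrix merges(std::max(N - 1, 0), 2);
  NumericVector heights(std::max(N - 1, 0));
  if (N == 1) {
    NumericMatrix outP(1, A);
    for (int a = 0; a < A; ++a) outP(0, a) = nodeP[a];
    return List::create(_["merges"] = merges, _["heights"] = heights,
                        _["node_dist"] = outP,
                        _["node_weight"] = NumericVector::create(nodeW[0]));
  }

  // slot-based active set: slot i currently holds node id nodeId[i]
  std::vector<int> nodeId(N);
  std::vector<char> active(N, 1);
  for (int i = 0; i < N; ++i) nodeId[i] = i + 1; // 1-based leaf ids

  std::vector<double> D((size_t)N * N, 0.0);
  std::vector<double> mixbuf(A);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double d = pair_distance(&nodeP[(size_t)i * A], &nodeP[(size_t)j * A],
                               nodeW[i], nodeW[j], nodeH[i], nodeH[j],
                               A, scaled, mixbuf);
      D[(size_t)i * N + j] = D[(size_t)j * N + i] = d;
    }

  // per-slot nearest neighbour cache
  std::vector<int> nns(N, -1);
  std::vector<double> nnd(N, 0.0);
  auto rescan = [&](int i) {
    int best = -1; double bd = 0.0; PairKey bk(0, 0);
    for (int j = 0; j < N; ++j) {
      if (j == i || !active[j]) continue;
      double d = D[(size_t)i * N + j];
      PairKey kk(nodeId[i], nodeId[j]);
      if (best < 0 || better(d, kk, bd, bk)) { best = j; bd = d; bk = kk; }
    }
    nns[i] = best; nnd[i] = bd;
  };
  for (int i = 0; i < N; ++i) rescan(i);

  for (int step = 0; step < N - 1; ++step) {
    // global best pair
    int bi = -1; double bd = 0.0; PairKey bk(0, 0);
    for (int i = 0; i < N; ++i) {
      if (!active[i] || nns[i] < 0) continue;
      PairKey kk(nodeId[i], nodeId[nns[i]]);
      if (bi < 0 || better(nnd[i], kk, bd, bk)) { bi = i; bd = nnd[i]; bk = kk; }
    }
    int sa = bi, sb = nns[bi];
    if (sa > sb) std::swap(sa, sb);

    int ida = nodeId[sa], idb = nodeId[sb];
    merges(step, 0) = std::min(ida, idb);
    merges(step, 1) = std::max(ida, idb);
    heights[step] = bd;

    // aggregate child contexts into the new node (count-weighted mean;
    // equal weights when both children carry zero weight)
    int newid = N + step + 1;
    double wa = nodeW[ida - 1], wb = nodeW[idb - 1];
    double tot = wa + wb;
    double fa = tot > 0.0 ? wa / tot : 0.5;
    double* pa = &nodeP[(size_t)(ida - 1) * A];
    double* pb = &nodeP[(size_t)(idb - 1) * A];
    double* pn = &nodeP[(size_t)(newid - 1) * A];
    for (int a = 0; a < A; ++a) pn[a] = fa * pa[a] + (1.0 - fa) * pb[a];
    nodeW[newid - 1] = tot;
    nodeH[newid - 1] = entropy2(pn, A);

    nodeId[sa] = newid;
    active[sb] = 0;

    for (int j = 0; j < N; ++j) {
      if (!active[j] || j == sa) continue;
      double d = pair_distance(pn, &nodeP[(size_t)(nodeId[j] - 1) * A],
                               tot, nodeW[nodeId[j] - 1],
                               nodeH[newid - 1], nodeH[nodeId[j] - 1],
                               A, scaled, mixbuf);
      D[(size_t)sa * N + j] = D[(size_t)j * N + sa] = d;
    }
    rescan(sa);
    for (int j = 0; j < N; ++j) {
      if (!active[j] || j == sa) continue;
      if (nns[j] == sa || nns[j] == sb) {
        rescan(j);
      } else {
        double d = D[(size_t)j * N + sa];
        PairKey kk(nodeId[j], nodeId[sa]);
        PairKey inc(nodeId[j], nodeId[nns[j]]);
        if (better(d, kk, nnd[j], inc)) { nns[j] = sa; nnd[j] = d; }
      }
    }
  }

  NumericMatrix outP(M, A);
  NumericVector outW(M);
  for (int i = 0; i < M; ++i) {
    for (int a = 0; a < A; ++a) outP(i, a) = nodeP[(size_t)i * A + a];
    outW[i] = nodeW[i];
  }
  return List::create(_["merges"] = merges, _["heights"] = heights,
                      _["node_dist"] = outP, _["node_weight"] = outW);
}

static inline int draw_index(const double* p, int n) {
  double u = R::unif_rand(), acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

// Sample sequences from a ground-truth abstraction-conditioned Markov chain.
// classes/block/next_kgram are 1-based; emissions is a list (per class) of
// m x A matrices; init is a distribution over the N k-grams. Uses R's RNG.
// [[Rcpp::export(name = ".sample_chain_cpp")]]
CharacterVector sample_chain_cpp(IntegerVector lengths, IntegerVector classes,
                                 List emissions, NumericVector init,
                                 IntegerVector block, IntegerMatrix next_kgram,
                                 CharacterVector kgram_strings,
                                 std::string alphabet, int k) {
  const int n = lengths.size();
  const int N = init.size();
  const int A = (int)alphabet.size();
  std::vector<NumericMatrix> em;
  for (int c = 0; c < emissions.size(); ++c)
    em.push_back(as<NumericMatrix>(emissions[c]));
  CharacterVector out(n);
  std::vector<double> row(A);
  for (int t = 0; t < n; ++t) {
    int len = lengths[t], cls = classes[t] - 1;
    int kg = draw_index(REAL(init), N);
    std::string s = as<std::string>(kgram_strings[kg]);
    s.reserve(len);
    for (int pos = k; pos < len; ++pos) {
      int b = block[kg] - 1;
      for (int a = 0; a < A; ++a) row[a] = em[cls](b, a);
      int sym = draw_index(row.data(), A);
      s.push_back(alphabet[sym]);
      kg = next_kgram(kg, sym) - 1;
    }
    out[t] = s;
  }
  return out;
}
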