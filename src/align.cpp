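// Core string kernels: bit-parallel (Myers/Hyyro block) Levenshtein distance
// and a Gotoh affine-gap global aligner with full traceback.
//
// The whole pipeline is built on unit-cost edit distance (nearest-neighbor
// graphs, read assignment) and on end-to-end pairwise alignments to a common
// target (multi-alignment construction, statistical test), so these two
// kernels are the hot path.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // anything else: matches nothing but itself never
  }
}

// Precomputed pattern bit masks for the Myers algorithm (5 symbol classes).
struct PatternMasks {
  int m;
  int words;
  std::vector<uint64_t> peq; // [5][words], flattened
  explicit PatternMasks(const std::string& a) {
    m = (int)a.size();
    words = (m + 63) / 64;
    peq.assign(5 * (size_t)words, 0ULL);
    for (int i = 0; i < m; ++i) {
      int ci = base_index(a[(size_t)i]);
      peq[(size_t)ci * words + (i >> 6)] |= (1ULL << (i & 63));
    }
  }
};

// Block bit-parallel Levenshtein distance (Hyyro 2003 formulation).
// Distance between full strings a (pattern) and b (text).
static int myers_distance(const PatternMasks& P, const std::string& b) {
  const int m = P.m;
  const int n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  const int W = P.words;
  std::vector<uint64_t> Pv((size_t)W, ~0ULL), Mv((size_t)W, 0ULL);
  int score = m;
  const uint64_t Last = 1ULL << ((m - 1) & 63);
  for (int j = 0; j < n; ++j) {
    const uint64_t* Eqs = &P.peq[(size_t)base_index(b[(size_t)j]) * W];
    int hin = 1; // row 0 of the DP increases by one per text column
    for (int w = 0; w < W; ++w) {
      uint64_t Eq = Eqs[w];
      const uint64_t Pvw = Pv[(size_t)w], Mvw = Mv[(size_t)w];
      uint64_t Xv = Eq | Mvw;
      if (hin < 0) Eq |= 1ULL;
      uint64_t Xh = (((Eq & Pvw) + Pvw) ^ Pvw) | Eq;
      uint64_t Ph = Mvw | ~(Xh | Pvw);
      uint64_t Mh = Pvw & Xh;
      const uint64_t top = (w == W - 1) ? Last : (1ULL << 63);
      int hout = 0;
      if (Ph & top) hout = 1;
      else if (Mh & top) hout = -1;
      Ph <<= 1; Mh <<= 1;
      if (hin < 0) Mh |= 1ULL;
      else if (hin > 0) Ph |= 1ULL;
      Pv[(size_t)w] = Mh | ~(Xv | Ph);
      Mv[(size_t)w] = Ph & Xv;
      hin = hout;
    }
    score += hin;
  }
  return score;
}

// [[Rcpp::export]]
IntegerVector c_edit_distance(CharacterVector x, CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  if (nx == 0 || ny == 0) return IntegerVector(0);
  R_xlen_t n = std::max(nx, ny);
  if (nx != ny && nx != 1 && ny != 1)
    stop("x and y must have equal length (or one of length 1)");
  IntegerVector out(n);
  if (nx == 1) {
    PatternMasks P(as<std::string>(x[0]));
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = myers_distance(P, as<std::string>(y[i % ny]));
  } else if (ny == 1) {
    PatternMasks P(as<std::string>(y[0]));
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = myers_distance(P, as<std::string>(x[i % nx]));
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      PatternMasks P(as<std::string>(x[i]));
      out[i] = myers_distance(P, as<std::string>(y[i]));
    }
  }
  return out;
}

// All-pairs distance matrix over a set of strings (symmetric, zero diagonal).
// [[Rcpp::export]]
IntegerMatrix c_pairwise_distances(CharacterVector strings) {
  int n = strings.size();
  IntegerMatrix D(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[(size_t)i] = as<std::string>(strings[i]);
  for (int i = 0; i < n; ++i) {
    PatternMasks P(s[(size_t)i]);
    for (int j = i + 1; j < n; ++j) {
      int d = myers_distance(P, s[(size_t)j]);
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// For each query, the minimal distance to any target and the indices (1-based)
// attaining it. Used for read-to-candidate assignment.
// [[Rcpp::export]]
List c_min_distances(CharacterVector queries, CharacterVector targets) {
  int nq = queries.size(), nt = targets.size();
  if (nt == 0) stop("no targets");
  std::vector<std::string> tg(nt);
  for (int j = 0; j < nt; ++j) tg[(size_t)j] = as<std::string>(targets[j]);
  IntegerVector mins(nq);
  List argmins(nq);
  for (int i = 0; i < nq; ++i) {
    PatternMasks P(as<std::string>(queries[i]));
    int best = INT_MAX;
    std::vector<int> idx;
    for (int j = 0; j < nt; ++j) {
      int d = myers_distance(P, tg[(size_t)j]);
      if (d < best) { best = d; idx.clear(); idx.push_back(j + 1); }
      else if (d == best) idx.push_back(j + 1);
    }
    mins[i] = best;
    argmins[i] = IntegerVector(idx.begin(), idx.end());
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["min"] = mins, _["which"] = argmins);
}

// ---------------------------------------------------------------------------
// Gotoh global alignment with affine gaps and full traceback.
// States: M (diagonal), E (gap in query row, consumes target char),
//         F (gap in target row, consumes query char).
// Scores are maximized. Traceback preference on ties: M, then E, then F,
// which is deterministic and left-normalizes gap placement for the common
// unit-cost configurations.

static const int NEG = -(1 << 29);

// [[Rcpp::export]]
List c_align_affine(CharacterVector queries, std::string target,
                    int match = 2, int mismatch = -2,
                    int gap_open = -3, int gap_extend = -1) {
  const int n = (int)target.size();
  if (n == 0) stop("empty target");
  const int nq = queries.size();
  List out(nq);
  // rolling score rows, full byte traceback
  for (int q = 0; q < nq; ++q) {
    std::string a = as<std::string>(queries[q]);
    const int m = (int)a.size();
    if (m == 0) stop("empty query");
    std::vector<int> Mp(n + 1), Ep(n + 1), Fp(n + 1);
    std::vector<int> Mc(n + 1), Ec(n + 1), Fc(n + 1);
    // trace codes per state: which predecessor state
    // tbM: 0=M,1=E,2=F ; tbE: 0=M-open,1=E-extend ; tbF: 0=M-open,1=F-extend
    std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1));
    std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1));
    std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1));
    // row 0
    Mp[0] = 0; Ep[0] = NEG; Fp[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      Mp[j] = NEG;
      Ep[j] = gap_open + gap_extend * j;
      Fp[j] = NEG;
      tbE[(size_t)j] = (j == 1) ? 0 : 1;
    }
    for (int i = 1; i <= m; ++i) {
      Mc[0] = NEG; Ec[0] = NEG;
      Fc[0] = gap_open + gap_extend * i;
      tbF[(size_t)i * (n + 1)] = (i == 1) ? 0 : 1;
      const char ai = a[(size_t)(i - 1)];
      for (int j = 1; j <= n; ++j) {
        const int s = (ai == target[(size_t)(j - 1)]) ? match : mismatch;
        // M
        int best = Mp[j - 1]; uint8_t tb = 0;
        if (Ep[j - 1] > best) { best = Ep[j - 1]; tb = 1; }
        if (Fp[j - 1] > best) { best = Fp[j - 1]; tb = 2; }
        Mc[j] = best + s;
        tbM[(size_t)i * (n + 1) + j] = tb;
        // E: gap in query (move along target)
        int eo = Mc[j - 1] + gap_open + gap_extend;
        int ee = Ec[j - 1] + gap_extend;
        if (eo >= ee) { Ec[j] = eo; tbE[(size_t)i * (n + 1) + j] = 0; }
        else          { Ec[j] = ee; tbE[(size_t)i * (n + 1) + j] = 1; }
        // F: gap in target (move along query)
        int fo = Mp[j] + gap_open + gap_extend;
        int fe = Fp[j] + gap_extend;
        if (fo >= fe) { Fc[j] = fo; tbF[(size_t)i * (n + 1) + j] = 0; }
        else          { Fc[j] = fe; tbF[(size_t)i * (n + 1) + j] = 1; }
      }
      std::swap(Mp, Mc); std::swap(Ep, Ec); std::swap(Fp, Fc);
    }
    int score = Mp[n]; int state = 0;
    if (Ep[n] > score) { score = Ep[n]; state = 1; }
    if (Fp[n] > score) { score = Fp[n]; state = 2; }
    // traceback
    std::string qr, tr;
    qr.reserve((size_t)(m + n)); tr.reserve((size_t)(m + n));
    int i = m, j = n;
    while (i > 0 || j > 0) {
      if (state == 0) {
        uint8_t tb = tbM[(size_t)i * (n + 1) + j];
        qr.push_back(a[(size_t)(i - 1)]);
        tr.push_back(target[(size_t)(j - 1)]);
        --i; --j;
        state = tb;
      } else if (state == 1) {
        uint8_t tb = tbE[(size_t)i * (n + 1) + j];
        qr.push_back('-');
        tr.push_back(target[(size_t)(j - 1)]);
        --j;
        state = (tb == 0) ? 0 : 1;
      } else {
        uint8_t tb = tbF[(size_t)i * (n + 1) + j];
        qr.push_back(a[(size_t)(i - 1)]);
        tr.push_back('-');
        --i;
        state = (tb == 0) ? 0 : 2;
      }
      if (i == 0 && j > 0 && state == 0) state = 1;
      if (j == 0 && i > 0 && state == 0) state = 2;
    }
    std::reverse(qr.begin(), qr.end());
    std::reverse(tr.begin(), tr.end());
    out[q] = List::create(_["query_row"] = qr, _["target_row"] = tr,
                          _["score"] = score);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
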