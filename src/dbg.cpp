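// de Bruijn graph core: 2-bit-packed k-mer hashing and the exact
// path-length dynamic program used for gap filling.  k is capped at 31 so
// a (k+1)-mer fits in one 64-bit word.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Path counts saturate here; traceback only needs positivity.
static const uint32_t SAT = 2147483647u;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char dec_base(int b) { return "ACGT"[b & 3]; }

struct DBG {
  int k;
  // k-mer -> abundance (vertices), (k+1)-mer -> abundance (edges)
  std::unordered_map<uint64_t, uint32_t> vert;
  std::unordered_map<uint64_t, uint32_t> edge;
};

static inline uint64_t kmask(int k) {
  return (2 * k >= 64) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

// Count k-mers and (k+1)-mers of one sequence; runs of non-ACGT split the
// sequence into unambiguous fragments.
static void count_seq(const std::string& s, int k,
                      std::unordered_map<uint64_t, uint32_t>& km,
                      std::unordered_map<uint64_t, uint32_t>& k1m) {
  const uint64_t mk = kmask(k);
  const uint64_t m1 = kmask(k + 1);
  uint64_t cur = 0;
  int run = 0;
  for (char c : s) {
    int b = enc_base(c);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)b) & m1;
    if (run < k + 1) ++run;
    if (run >= k) {
      uint32_t& v = km[cur & mk];
      if (v < SAT) ++v;
    }
    if (run >= k + 1) {
      uint32_t& e = k1m[cur];
      if (e < SAT) ++e;
    }
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Encode a k-mer string; returns false on ambiguous bases or length mismatch.
static bool enc_kmer(const std::string& s, int k, uint64_t& out) {
  if ((int)s.size() != k) return false;
  uint64_t v = 0;
  for (char c : s) {
    int b = enc_base(c);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static std::string dec_kmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = dec_base((int)(v & 3));
    v >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".dbg_build")]]
SEXP dbg_build(CharacterVector reads, int k, int min_abundance,
               bool rc_augment) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  if (min_abundance < 1) stop("min_abundance must be >= 1");
  if (reads.size() == 0) stop("no reads supplied");

  std::unordered_map<uint64_t, uint32_t> km, k1m;
  bool any_long = false;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() >= k) any_long = true;
    count_seq(s, k, km, k1m);
    if (rc_augment) count_seq(revcomp_str(s), k, km, k1m);
  }
  if (!any_long) stop("k exceeds read length: no read is at least k bases long");

  DBG* g = new DBG();
  g->k = k;
  for (auto& p : km)
    if (p.second >= (uint32_t)min_abundance) g->vert[p.first] = p.second;
  if (g->vert.empty()) {
    delete g;
    stop("empty graph: no k-mer passes the abundance threshold");
  }
  const uint64_t mk = kmask(k);
  for (auto& p : k1m) {
    if (p.second < (uint32_t)min_abundance) continue;
    uint64_t pre = p.first >> 2, suf = p.first & mk;
    if (g->vert.count(pre) && g->vert.count(suf)) g->edge[p.first] = p.second;
  }
  XPtr<DBG> ptr(g, true);
  return ptr;
}

// [[Rcpp::export(name = ".dbg_k")]]
int dbg_k(SEXP gp) { return XPtr<DBG>(gp)->k; }

// [[Rcpp::export(name = ".dbg_vcount")]]
double dbg_vcount(SEXP gp) { return (double)XPtr<DBG>(gp)->vert.size(); }

// [[Rcpp::export(name = ".dbg_ecount")]]
double dbg_ecount(SEXP gp) { return (double)XPtr<DBG>(gp)->edge.size(); }

// [[Rcpp::export(name = ".dbg_vertices")]]
CharacterVector dbg_vertices(SEXP gp) {
  XPtr<DBG> g(gp);
  std::vector<uint64_t> ks;
  ks.reserve(g->vert.size());
  for (auto& p : g->vert) ks.push_back(p.first);
  std::sort(ks.begin(), ks.end());  // 2-bit encoding sorts lexicographically
  CharacterVector out(ks.size());
  for (size_t i = 0; i < ks.size(); ++i) out[i] = dec_kmer(ks[i], g->k);
  return out;
}

// [[Rcpp::export(name = ".dbg_edges")]]
DataFrame dbg_edges(SEXP gp) {
  XPtr<DBG> g(gp);
  std::vector<uint64_t> es;
  es.reserve(g->edge.size());
  for (auto& p : g->edge) es.push_back(p.first);
  std::sort(es.begin(), es.end());
  const uint64_t mk = kmask(g->k);
  CharacterVector from(es.size()), to(es.size());
  for (size_t i = 0; i < es.size(); ++i) {
    from[i] = dec_kmer(es[i] >> 2, g->k);
    to[i] = dec_kmer(es[i] & mk, g->k);
  }
  return DataFrame::create(_["from"] = from, _["to"] = to,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".dbg_abundance")]]
IntegerVector dbg_abundance(SEXP gp, CharacterVector kmers) {
  XPtr<DBG> g(gp);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t v;
    if (!enc_kmer(as<std::string>(kmers[i]), g->k, v)) {
      out[i] = NA_INTEGER;
      continue;
    }
    auto it = g->vert.find(v);
    out[i] = (it == g->vert.end()) ? 0 : (int)it->second;
  }
  return out;
}

// [[Rcpp::export(name = ".dbg_has_vertex")]]
LogicalVector dbg_has_vertex(SEXP gp, CharacterVector kmers) {
  XPtr<DBG> g(gp);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t v;
    out[i] = enc_kmer(as<std::string>(kmers[i]), g->k, v) &&
             g->vert.count(v) > 0;
  }
  return out;
}

typedef std::vector<std::unordered_map<uint64_t, uint32_t>> Layers;

// Layered DP: layers[i] maps vertex -> number of walks of cost exactly i
// from src, counts saturating at SAT.
static void dp_layers(const DBG* g, uint64_t src, int max_cost, Layers& L) {
  const uint64_t mk = kmask(g->k);
  const uint64_t m1 = kmask(g->k + 1);
  L.clear();
  L.resize(1);
  L[0][src] = 1;
  for (int i = 1; i <= max_cost; ++i) {
    std::unordered_map<uint64_t, uint32_t> nxt;
    for (auto& p : L[i - 1]) {
      for (uint64_t b = 0; b < 4; ++b) {
        uint64_t e = ((p.first << 2) | b) & m1;
        if (!g->edge.count(e)) continue;
        uint64_t w = e & mk;
        uint32_t& c = nxt[w];
        uint64_t s = (uint64_t)c + (uint64_t)p.second;
        c = (s > SAT) ? SAT : (uint32_t)s;
      }
    }
    if (nxt.empty()) break;
    L.push_back(std::move(nxt));
  }
}

// Walk backwards from tgt at cost, taking the lexicographically smallest
// predecessor k-mer at each step; returns the spelled cost+k string.
static std::string dp_traceback(const DBG* g, const Layers& L, uint64_t tgt,
                                int cost) {
  const int k = g->k;
  std::string out(cost + k, 'N');
  uint64_t cur = tgt;
  std::string kk = dec_kmer(cur, k);
  for (int j = 0; j < k; ++j) out[cost + j] = kk[j];
  for (int i = cost; i >= 1; --i) {
    bool found = false;
    for (uint64_t b = 0; b < 4 && !found; ++b) {
      uint64_t w = (b << (2 * (k - 1))) | (cur >> 2);
      uint64_t e = ((w << 2) | (cur & 3)) & kmask(k + 1);
      auto it = L[i - 1].find(w);
      if (it != L[i - 1].end() && it->second > 0 && g->edge.count(e)) {
        out[i - 1] = dec_base((int)b);
        cur = w;
        found = true;
      }
    }
    if (!found) stop("internal error: traceback lost the path");
  }
  return out;
}

// Gap filling with flank-offset (fuzz) search.  Offsets a (left) and b
// (right) shift the source/target k-mers *into* the flanks; a path of cost c
// then spells m = c - k - a - b bases strictly between the original flank
// boundaries.  Accepts m in [max(0, est_length - slack), est_length + slack];
// returns the success minimizing (a + b, a), with the cost closest to the
// midpoint of the accepted cost interval (ties -> smaller cost).
// [[Rcpp::export(name = ".dbg_fill_gap")]]
List dbg_fill_gap(SEXP gp, std::string left_flank, std::string right_flank,
                  int est_length, int slack, int fuzz, int max_cost) {
  XPtr<DBG> g(gp);
  const int k = g->k;
  if (fuzz < 0) stop("fuzz must be >= 0");
  if (slack < 0) stop("slack must be >= 0");
  if (est_length < 0) stop("est_length must be >= 0");
  const int Ll = (int)left_flank.size(), Lr = (int)right_flank.size();
  if (Ll < k + fuzz || Lr < k + fuzz)
    stop("flanks shorter than k + fuzz");

  const int lo_len = std::max(0, est_length - slack);
  const int hi_len = est_length + slack;

  bool best_found = false;
  int best_a = 0, best_b = 0, best_cost = 0;
  double best_npaths = 0;
  std::string best_spelled;

  for (int a = 0; a <= fuzz; ++a) {
    if (best_found && a > best_a + best_b) break;  // cannot improve (a+b, a)
    uint64_t src;
    if (!enc_kmer(left_flank.substr(Ll - k - a, k), k, src)) continue;
    if (!g->vert.count(src)) continue;

    int maxc = hi_len + k + a + fuzz;
    if (max_cost > 0) maxc = std::min(maxc, max_cost);
    Layers L;
    dp_layers(g, src, maxc, L);

    for (int b = 0; b <= fuzz; ++b) {
      if (best_found &&
          (a + b > best_a + best_b || (a + b == best_a + best_b && a >= best_a)))
        continue;
      uint64_t tgt;
      if (!enc_kmer(right_flank.substr(b, k), k, tgt)) continue;
      if (!g->vert.count(tgt)) continue;

      const int lo_c = lo_len + k + a + b;
      const int hi_c = hi_len + k + a + b;
      const double mid = (lo_c + hi_c) / 2.0;
      int cstar = -1;
      double npaths = 0;
      for (int c = lo_c; c <= hi_c && c < (int)L.size(); ++c) {
        auto it = L[c].find(tgt);
        if (it == L[c].end() || it->second == 0) continue;
        npaths += (double)it->second;
        if (cstar < 0 ||
            std::abs(c - mid) < std::abs(cstar - mid) ||
            (std::abs(c - mid) == std::abs(cstar - mid) && c < cstar))
          cstar = c;
      }
      if (cstar < 0) continue;
      if (npaths > (double)SAT) npaths = (double)SAT;

      best_found = true;
      best_a = a;
      best_b = b;
      best_cost = cstar;
      best_npaths = npaths;
      best_spelled = dp_traceback(g, L, tgt, cstar);
    }
  }

  if (!best_found)
    return List::create(_["found"] = false,
                        _["insertion"] = CharacterVector::create(NA_STRING),
                        _["spelled"] = CharacterVector::create(NA_STRING),
                        _["left_offset"] = NA_INTEGER,
                        _["right_offset"] = NA_INTEGER, _["cost"] = NA_INTEGER,
                        _["n_paths"] = 0.0);

  const int m = best_cost - k - best_a - best_b;
  std::string ins = best_spelled.substr(k + best_a, (size_t)m);
  return List::create(_["found"] = true, _["insertion"] = ins,
                      _["spelled"] = best_spelled, _["left_offset"] = best_a,
                      _["right_offset"] = best_b, _["cost"] = best_cost,
                      _["n_paths"] = best_npaths);
}
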