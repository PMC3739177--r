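#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Ungapped seed-and-extend HSP discovery, blastn-like.
// Sequences arrive as integer vectors: A=0 C=1 G=2 T=3, anything >=4 is an
// ambiguity code. Ambiguities never seed and always score as mismatches.

static inline bool valid_base(int b) { return b >= 0 && b <= 3; }

struct Hsp {
  int a_start, a_end, b_start, b_end; // 0-based half-open, working strand
  int length, identities, score;
};

// X-drop extension around a seeded exact word match. Coordinates are the
// word's span; extension trims back to the maximal-scoring extent.
static Hsp extend_seed(const IntegerVector& a, const IntegerVector& b,
                       int a_pos, int b_pos, int word_size,
                       int match, int mismatch, int x_drop) {
  const int la = a.size(), lb = b.size();
  int score = word_size * match; // seed is an exact match by construction

  // rightward from the word end
  int best_right_a = a_pos + word_size, best_right_b = b_pos + word_size;
  int best_score = score;
  {
    int run = score;
    int i = a_pos + word_size, j = b_pos + word_size;
    while (i < la && j < lb) {
      bool hit = valid_base(a[i]) && valid_base(b[j]) && a[i] == b[j];
      run += hit ? match : mismatch;
      ++i; ++j;
      if (run > best_score) { best_score = run; best_right_a = i; best_right_b = j; }
      if (run <= best_score - x_drop) break;
    }
  }
  // leftward from the word start
  int best_left_a = a_pos, best_left_b = b_pos;
  {
    int run = best_score;
    int i = a_pos - 1, j = b_pos - 1;
    int best2 = best_score;
    while (i >= 0 && j >= 0) {
      bool hit = valid_base(a[i]) && valid_base(b[j]) && a[i] == b[j];
      run += hit ? match : mismatch;
      if (run > best2) { best2 = run; best_left_a = i; best_left_b = j; }
      if (run <= best2 - x_drop) break;
      --i; --j;
    }
    best_score = best2;
  }

  Hsp h;
  h.a_start = best_left_a; h.a_end = best_right_a;
  h.b_start = best_left_b; h.b_end = best_right_b;
  h.length = h.a_end - h.a_start;
  int id = 0;
  for (int k = 0; k < h.length; ++k) {
    int x = a[h.a_start + k], y = b[h.b_start + k];
    if (valid_base(x) && valid_base(y) && x == y) ++id;
  }
  h.identities = id;
  h.score = id * match + (h.length - id) * mismatch;
  return h;
}

// [[Rcpp::export(name = ".hsp_scan")]]
DataFrame hsp_scan(IntegerVector a, IntegerVector b, int word_size,
                   int min_score, int x_drop, int match, int mismatch) {
  const int la = a.size(), lb = b.size();
  std::vector<Hsp> out;
  if (la < word_size || lb < word_size) {
    return DataFrame::create(Named("a_start") = IntegerVector(0),
                             Named("a_end") = IntegerVector(0),
                             Named("b_start") = IntegerVector(0),
                             Named("b_end") = IntegerVector(0),
                             Named("length") = IntegerVector(0),
                             Named("identities") = IntegerVector(0),
                             Named("score") = IntegerVector(0));
  }

  // index A's words (2-bit packed); word_size <= 15 fits in 32 bits
  std::unordered_multimap<uint32_t, int> index;
  index.reserve(la);
  {
    uint32_t w = 0, mask = (word_size >= 16) ? 0xFFFFFFFFu
                                             : ((1u << (2 * word_size)) - 1u);
    int run = 0;
    for (int i = 0; i < la; ++i) {
      if (!valid_base(a[i])) { run = 0; continue; }
      w = ((w << 2) | (uint32_t)a[i]) & mask;
      if (++run >= word_size) index.emplace(w, i - word_size + 1);
    }
  }

  // per-diagonal furthest B end already covered by an extension
  std::unordered_map<int64_t, int> diag_bound;

  uint32_t w = 0, mask = (word_size >= 16) ? 0xFFFFFFFFu
                                           : ((1u << (2 * word_size)) - 1u);
  int run = 0;
  for (int j = 0; j < lb; ++j) {
    if (!valid_base(b[j])) { run = 0; continue; }
    w = ((w << 2) | (uint32_t)b[j]) & mask;
    if (++run < word_size) continue;
    int b_pos = j - word_size + 1;
    auto range = index.equal_range(w);
    for (auto it = range.first; it != range.second; ++it) {
      int a_pos = it->second;
      int64_t d = (int64_t)a_pos - (int64_t)b_pos;
      auto db = diag_bound.find(d);
      if (db != diag_bound.end() && b_pos < db->second) continue;
      Hsp h = extend_seed(a, b, a_pos, b_pos, word_size, match, mismatch, x_drop);
      diag_bound[d] = h.b_end;
      if (h.score >= min_score) out.push_back(h);
    }
  }

  const int n = out.size();
  IntegerVector as(n), ae(n), bs(n), be(n), len(n), id(n), sc(n);
  for (int i = 0; i < n; ++i) {
    as[i] = out[i].a_start; ae[i] = out[i].a_end;
    bs[i] = out[i].b_start; be[i] = out[i].b_end;
    len[i] = out[i].length; id[i] = out[i].identities; sc[i] = out[i].score;
  }
  return DataFrame::create(Named("a_start") = as, Named("a_end") = ae,
                           Named("b_start") = bs, Named("b_end") = be,
                           Named("length") = len, Named("identities") = id,
                           Named("score") = sc);
}
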