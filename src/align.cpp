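// Smith-Waterman local alignment (Gotoh affine gaps), score only.
// BLAST gap convention: a gap of length g costs open + g * extend.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

// q, s: 0-based residue codes; sub: NxN substitution matrix.
static int sw_score(const Rcpp::IntegerVector& q, const Rcpp::IntegerVector& s,
                    const Rcpp::IntegerMatrix& sub, int open, int ext) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  const int gapfirst = open + ext;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0;   // H[i-1][j-1]
    int Fij = NEG;   // gap in subject (vertical), per row
    int Hprev = 0;   // H[i][j-1] as we go
    H[0] = 0;
    Hprev = 0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gapfirst, E[j] - ext);      // uses H[i-1][j]
      Fij = std::max(Hprev - gapfirst, Fij - ext);       // uses H[i][j-1]
      int h = Hdiag + sub(q[i - 1], s[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, Fij);
      h = std::max(h, 0);
      Hdiag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_sw_score(Rcpp::IntegerVector q, Rcpp::IntegerVector s,
                 Rcpp::IntegerMatrix sub, int open = 11, int ext = 1) {
  return sw_score(q, s, sub, open, ext);
}

// Best subject per query.  Subjects must be supplied in the tie-break order
// (first strictly greater score wins, so earlier = preferred on ties).
// Returns a B x 2 matrix: 1-based index of best subject, raw score.
// Index 0 means no subject scored above 0.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_top_hits(Rcpp::List queries, Rcpp::List subjects,
                                 Rcpp::IntegerMatrix sub, int open = 11,
                                 int ext = 1) {
  const int B = queries.size(), M = subjects.size();
  Rcpp::IntegerMatrix out(B, 2);
  std::vector<Rcpp::IntegerVector> subj(M);
  for (int j = 0; j < M; ++j) subj[j] = subjects[j];
  for (int b = 0; b < B; ++b) {
    Rcpp::IntegerVector q = queries[b];
    int best = 0, bi = 0;
    for (int j = 0; j < M; ++j) {
      int sc = sw_score(q, subj[j], sub, open, ext);
      if (sc > best) { best = sc; bi = j + 1; }
    }
    out(b, 0) = bi;
    out(b, 1) = best;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Deterministic, platform-independent 64-bit FNV-1a hash of (salt, key),
// mapped to [0, 1).  Used for order-independent fold assignment.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_hash01(Rcpp::CharacterVector keys, int salt) {
  const uint64_t prime = 1099511628211ULL;
  Rcpp::NumericVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t h = 14695981039346656037ULL;
    uint32_t s = (uint32_t)salt;
    for (int b = 0; b < 4; ++b) {
      h ^= (s >> (8 * b)) & 0xff;
      h *= prime;
    }
    const char* k = keys[i];
    for (const char* p = k; *p; ++p) {
      h ^= (uint8_t)(*p);
      h *= prime;
    }
    // avalanche finaliser: raw FNV is too regular on serial accessions
    h ^= h >> 33; h *= 0xff51afd7ed558ccdULL;
    h ^= h >> 33; h *= 0xc4ceb9fe1a85ec53ULL;
    h ^= h >> 33;
    out[i] = (double)(h >> 11) / 9007199254740992.0;  // 53 bits -> [0,1)
  }
  return out;
}
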