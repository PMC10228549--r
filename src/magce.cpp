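#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// residue encoding against the rows of a substitution matrix
// ---------------------------------------------------------------------------

static void build_lut(const std::string &alphabet, int *lut, int &x_idx) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  x_idx = 0;
  for (size_t i = 0; i < alphabet.size(); ++i) {
    lut[(unsigned char)alphabet[i]] = (int)i;
    if (alphabet[i] == 'X') x_idx = (int)i;
  }
}

static std::vector<int> encode_seq(const std::string &s, const int *lut,
                                   int x_idx) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    v[i] = c < 0 ? x_idx : c;
  }
  return v;
}

// ---------------------------------------------------------------------------
// exact affine-gap Smith-Waterman with traceback
//
// gap of length L costs gap_open + L * gap_extend (BLAST 11/1 convention).
// Among equal-scoring cells the first in row-major order wins, i.e. the
// smallest query end coordinate, then the smallest subject end coordinate.
// ---------------------------------------------------------------------------

struct AlnResult {
  int score, qs, qe, ss, se, ident, alen;
};

static AlnResult sw_core(const std::vector<int> &q, const std::vector<int> &s,
                         const IntegerMatrix &mat, int go, int ge) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = INT_MIN / 4;
  AlnResult res{0, NA_INTEGER, NA_INTEGER, NA_INTEGER, NA_INTEGER, 0, 0};
  if (m == 0 || n == 0) return res;

  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  const size_t W = (size_t)n + 1;

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t c = (size_t)i * W + j, up = c - W, lf = c - 1, dg = up - 1;
      int e = std::max(E[lf] - ge, H[lf] - go - ge);
      int f = std::max(F[up] - ge, H[up] - go - ge);
      int h = H[dg] + mat(qi, s[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[c] = e;
      F[c] = f;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (gap in query), 2 = F
  int ident = 0, alen = 0;
  while (true) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (H[c] == 0) break;
      const size_t dg = c - W - 1;
      if (i >= 1 && j >= 1 && H[c] == H[dg] + mat(q[i - 1], s[j - 1])) {
        if (q[i - 1] == s[j - 1]) ++ident;
        ++alen;
        --i; --j;
      } else if (H[c] == E[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++alen; // consumes subject residue against a gap
      if (E[c] == E[c - 1] - ge) { --j; }
      else { --j; state = 0; }
    } else {
      ++alen; // consumes query residue against a gap
      if (F[c] == F[c - W] - ge) { --i; }
      else { --i; state = 0; }
    }
  }
  res.score = best;
  res.qs = i + 1; res.qe = bi;
  res.ss = j + 1; res.se = bj;
  res.ident = ident; res.alen = alen;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject, IntegerMatrix mat,
                  std::string alphabet, int gap_open, int gap_extend) {
  int lut[256], x_idx;
  build_lut(alphabet, lut, x_idx);
  std::vector<int> q = encode_seq(query, lut, x_idx);
  std::vector<int> s = encode_seq(subject, lut, x_idx);
  AlnResult r = sw_core(q, s, mat, gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["qstart"] = r.qs,
                      _["qend"] = r.qe, _["sstart"] = r.ss, _["send"] = r.se,
                      _["identities"] = r.ident, _["aln_length"] = r.alen);
}

// ---------------------------------------------------------------------------
// seeded six-frame search: exact-word seeding, x-drop ungapped extension,
// then exact affine DP restricted to a window around the seeded region.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_search_frames(CharacterVector queries, CharacterVector frames,
                            IntegerMatrix mat, std::string alphabet,
                            int gap_open, int gap_extend, int word_len,
                            int ungapped_min, int xdrop) {
  int lut[256], x_idx;
  build_lut(alphabet, lut, x_idx);
  const int A = (int)alphabet.size();
  const int nq = queries.size(), nf = frames.size();

  std::vector<std::vector<int>> qenc(nq);
  for (int i = 0; i < nq; ++i)
    qenc[i] = encode_seq(as<std::string>(queries[i]), lut, x_idx);

  // direct-addressed word table over all queries
  size_t tabsize = 1;
  for (int i = 0; i < word_len; ++i) tabsize *= (size_t)A;
  std::vector<std::vector<std::pair<int, int>>> table(tabsize);
  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int> &q = qenc[qi];
    if ((int)q.size() < word_len) continue;
    size_t key = 0;
    for (int p = 0; p < (int)q.size(); ++p) {
      key = (key * A + q[p]) % tabsize;
      if (p >= word_len - 1) table[key].push_back({qi, p - word_len + 1});
    }
  }

  std::vector<int> out_q, out_f, out_score, out_qs, out_qe, out_ss, out_se,
      out_id, out_al;

  for (int fi = 0; fi < nf; ++fi) {
    std::vector<int> s = encode_seq(as<std::string>(frames[fi]), lut, x_idx);
    const int n = (int)s.size();
    if (n < word_len) continue;

    // candidate intervals per query: qi -> (lo, hi)
    std::map<int, std::vector<std::pair<int, int>>> cand;
    std::unordered_map<int64_t, int> cover; // (qi, diag) -> covered end

    size_t key = 0;
    for (int sp = 0; sp < n; ++sp) {
      key = (key * A + s[sp]) % tabsize;
      if (sp < word_len - 1) continue;
      const int w0 = sp - word_len + 1; // word start in subject
      const std::vector<std::pair<int, int>> &hits = table[key];
      for (size_t h = 0; h < hits.size(); ++h) {
        const int qi = hits[h].first, qp = hits[h].second;
        const std::vector<int> &q = qenc[qi];
        const int m = (int)q.size();
        const int diag = w0 - qp;
        const int64_t ck = (int64_t)qi * 4000000000LL + diag;
        std::unordered_map<int64_t, int>::iterator it = cover.find(ck);
        if (it != cover.end() && w0 <= it->second) continue;

        // word score
        int sc = 0;
        for (int t = 0; t < word_len; ++t) sc += mat(q[qp + t], s[w0 + t]);
        // x-drop extension right
        int bestsc = sc, extR = 0;
        for (int t = word_len; qp + t < m && w0 + t < n; ++t) {
          sc += mat(q[qp + t], s[w0 + t]);
          if (sc > bestsc) { bestsc = sc; extR = t - word_len + 1; }
          if (sc < bestsc - xdrop) break;
        }
        // x-drop extension left
        int sc2 = bestsc, best2 = bestsc, extL = 0;
        for (int t = 1; qp - t >= 0 && w0 - t >= 0; ++t) {
          sc2 += mat(q[qp - t], s[w0 - t]);
          if (sc2 > best2) { best2 = sc2; extL = t; }
          if (sc2 < best2 - xdrop) break;
        }
        const int s_lo = w0 - extL, s_hi = w0 + word_len - 1 + extR;
        cover[ck] = s_hi;
        if (best2 >= ungapped_min) cand[qi].push_back({s_lo, s_hi});
      }
    }

    // merge candidate intervals and run exact DP on windows
    for (std::map<int, std::vector<std::pair<int, int>>>::iterator it =
             cand.begin();
         it != cand.end(); ++it) {
      const int qi = it->first;
      const int m = (int)qenc[qi].size();
      std::vector<std::pair<int, int>> &iv = it->second;
      std::sort(iv.begin(), iv.end());
      std::vector<std::pair<int, int>> merged;
      for (size_t k = 0; k < iv.size(); ++k) {
        if (!merged.empty() && iv[k].first <= merged.back().second + m)
          merged.back().second = std::max(merged.back().second, iv[k].second);
        else
          merged.push_back(iv[k]);
      }
      const int pad = m / 2 + 30;
      for (size_t k = 0; k < merged.size(); ++k) {
        const int wlo = std::max(0, merged[k].first - pad);
        const int whi = std::min(n - 1, merged[k].second + pad);
        std::vector<int> sub(s.begin() + wlo, s.begin() + whi + 1);
        AlnResult r = sw_core(qenc[qi], sub, mat, gap_open, gap_extend);
        if (r.score <= 0) continue;
        out_q.push_back(qi + 1);
        out_f.push_back(fi + 1);
        out_score.push_back(r.score);
        out_qs.push_back(r.qs);
        out_qe.push_back(r.qe);
        out_ss.push_back(r.ss + wlo);
        out_se.push_back(r.se + wlo);
        out_id.push_back(r.ident);
        out_al.push_back(r.alen);
      }
    }
  }

  return DataFrame::create(
      _["qidx"] = out_q, _["fidx"] = out_f, _["raw_score"] = out_score,
      _["qstart"] = out_qs, _["qend"] = out_qe, _["sstart_aa"] = out_ss,
      _["send_aa"] = out_se, _["identities"] = out_id,
      _["aln_length"] = out_al);
}

// ---------------------------------------------------------------------------
// bottom-s sketch of canonical k-mer hashes (Mash-style)
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_sketch(std::string seq, int k, int sketch_size) {
  const uint64_t mask =
      (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  std::vector<uint64_t> hashes;
  hashes.reserve(seq.size());
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b;
    switch (seq[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) hashes.push_back(splitmix64(std::min(fwd, rev)));
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  if ((int)hashes.size() > sketch_size) hashes.resize(sketch_size);
  NumericVector out(hashes.size());
  // >> 11 keeps 53 bits so the double representation stays exact
  for (size_t i = 0; i < hashes.size(); ++i)
    out[i] = (double)(hashes[i] >> 11);
  return out;
}

// ---------------------------------------------------------------------------
// PerMANOVA pseudo-F over a matrix of label permutations
// labels: one row per permutation, integer group codes 1..a
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_permanova_F(NumericMatrix d2, IntegerMatrix labels, int a) {
  const int n = d2.ncol(), np = labels.nrow();
  double sst = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) sst += d2(i, j);
  sst /= (double)n;

  NumericVector F(np);
  std::vector<double> gsum(a + 1);
  std::vector<int> gn(a + 1);
  for (int p = 0; p < np; ++p) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gn.begin(), gn.end(), 0);
    for (int i = 0; i < n; ++i) gn[labels(p, i)]++;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (labels(p, i) == labels(p, j)) gsum[labels(p, i)] += d2(i, j);
    double ssw = 0.0;
    for (int g = 1; g <= a; ++g)
      if (gn[g] > 0) ssw += gsum[g] / (double)gn[g];
    F[p] = ((sst - ssw) / (double)(a - 1)) / (ssw / (double)(n - a));
  }
  return F;
}
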