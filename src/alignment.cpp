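#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Overlap (semi-global, end-gap-free) alignment under unit scoring:
// match +1, mismatch -1, gap -1; terminal gaps are free and excluded
// from the identity denominator. The DP maximizes (score, matches)
// lexicographically; identity = matches / columns, where
// columns = matches + mismatches + internal gaps = 2*matches - score.

struct Cell { int score; int match; };

static inline bool better(int s1, int m1, int s2, int m2) {
  return s1 > s2 || (s1 == s2 && m1 > m2);
}

// Full (unbanded) overlap alignment identity.
// [[Rcpp::export]]
double overlap_identity_cpp(std::string a, std::string b) {
  const int la = (int) a.size(), lb = (int) b.size();
  if (la == 0 || lb == 0) stop("empty sequence");
  std::vector<Cell> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = {0, 0}; // free leading gaps in a
  int best_s = 0, best_m = 0;                     // empty overlap fallback
  for (int i = 1; i <= la; ++i) {
    cur[0] = {0, 0};                              // free leading gaps in b
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const bool eq = (ai == b[j - 1]);
      int s = prev[j - 1].score + (eq ? 1 : -1);
      int m = prev[j - 1].match + (eq ? 1 : 0);
      if (better(prev[j].score - 1, prev[j].match, s, m)) {
        s = prev[j].score - 1; m = prev[j].match;
      }
      if (better(cur[j - 1].score - 1, cur[j - 1].match, s, m)) {
        s = cur[j - 1].score - 1; m = cur[j - 1].match;
      }
      cur[j] = {s, m};
    }
    if (better(cur[lb].score, cur[lb].match, best_s, best_m)) {
      best_s = cur[lb].score; best_m = cur[lb].match; // free trailing gaps in a
    }
    std::swap(prev, cur);
  }
  for (int j = 0; j <= lb; ++j)                      // free trailing gaps in b
    if (better(prev[j].score, prev[j].match, best_s, best_m)) {
      best_s = prev[j].score; best_m = prev[j].match;
    }
  const int cols = 2 * best_m - best_s;
  if (cols <= 0) return 0.0;
  return (double) best_m / (double) cols;
}

// Shared banded kernel: overlap identity of one query/reference pair.
// The band is sized so that any alignment achieving identity >= t lies
// inside it; identities at/above the threshold are exact, values below it
// may be underestimated (they are only used to reject candidates).
// References that provably cannot reach the threshold are abandoned early:
// a within-band alignment at identity >= t spans >= L - w columns and
// therefore scores >= (2t - 1)(L - w); give up once even an all-match
// completion cannot reach that score.
struct BandedScratch {
  std::vector<int> prev_s, prev_m, cur_s, cur_m;
};

// 2-bit encoding of a 13-mer; -1 when a non-ACGT character occurs.
static const int KF = 13;
static long kmer_code(const char *p) {
  long code = 0;
  for (int i = 0; i < KF; ++i) {
    int b;
    switch (p[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return -1;
    }
    code = (code << 2) | b;
  }
  return code;
}

// sorted 13-mer content of one reference (empty when too short or
// containing non-ACGT characters: such references skip the filter).
static std::vector<long> kmer_index(const char *s, int len) {
  std::vector<long> out;
  if (len < KF) return out;
  out.reserve(len - KF + 1);
  for (int i = 0; i + KF <= len; ++i) {
    long c = kmer_code(s + i);
    if (c < 0) return std::vector<long>();
    out.push_back(c);
  }
  std::sort(out.begin(), out.end());
  return out;
}

static double banded_pair(const char *qc, int lq, const char *bc, int lb,
                          double min_identity, BandedScratch &ws,
                          const std::vector<long> *ref_kmers = NULL) {
  const int NEG = INT_MIN / 4;
  if (lb == 0 || lq == 0) return 0.0;
  if (lb == lq && std::memcmp(bc, qc, lq) == 0) return 1.0;
  int L = std::max(lq, lb);
  // internal gaps <= (1 - t) * cols <= (1 - t) * (lq + lb)
  int w = (int) std::ceil((1.0 - min_identity) * (lq + lb)) +
          std::abs(lq - lb) + 2;
  if (w > L) w = L;
  if (lq + lb > 4000) {
    // fall back to the exact unbanded program for unusually long inputs
    // (outside the packed-integer range below; amplicons never get here)
    return overlap_identity_cpp(std::string(qc, lq), std::string(bc, lb));
  }
  const int need =
    (int) std::ceil((2.0 * min_identity - 1.0) * (double) (L - w));
  // Pigeonhole q-gram filter: a within-band alignment at identity >= t has
  // at most maxedits edit columns, and query terminal skips are <= w, so
  // splitting the query interior [w, lq - w) into maxedits + 1 disjoint
  // segments, at least one segment is edit-free and aligned -- it must
  // occur verbatim in the reference. No segment found => below threshold.
  {
    const int maxedits =
      (int) std::floor((1.0 - min_identity) * (double) (lq + lb));
    const int nseg = maxedits + 1;
    const int start = std::min(w, lq), stop = lq - std::min(w, lq);
    const int ilen = stop - start;
    const int seg = (ilen > 0) ? ilen / nseg : 0;
    if (seg >= KF) {
      bool hit = false;
      for (int s = 0; s < nseg && !hit; ++s) {
        const char *p = qc + start + s * seg;
        if (ref_kmers && !ref_kmers->empty()) {
          // an edit-free segment's 13-mer prefix occurs verbatim in b
          long c = kmer_code(p);
          hit = (c < 0) ||
            std::binary_search(ref_kmers->begin(), ref_kmers->end(), c);
        } else {
          hit = std::search(bc, bc + lb, p, p + seg) != bc + lb;
        }
      }
      if (!hit) return 0.0;
    }
  }
  // (score, match) packed into one int: v = (score + BIAS) << SHIFT | match,
  // so lexicographic (score, match) maximization is plain integer max.
  const int SHIFT = 12, MASK = (1 << SHIFT) - 1, BIAS = 1 << (SHIFT - 1);
  const int V0 = BIAS << SHIFT;                 // score 0, match 0
  const int DIAG_EQ = (1 << SHIFT) + 1;         // +1 score, +1 match
  const int GAPV = 1 << SHIFT;                  // -1 score
  ws.prev_s.assign(lb + 1, NEG);
  ws.cur_s.assign(lb + 1, NEG);
  int *prev = ws.prev_s.data(), *cur = ws.cur_s.data();
  for (int j = 0; j <= std::min(lb, w); ++j) prev[j] = V0;
  int best = V0;
  for (int i = 1; i <= lq; ++i) {
    const int jlo = std::max(1, i - w), jhi = std::min(lb, i + w);
    if (jlo > jhi) break;
    cur[jlo - 1] = (jlo - 1 == 0 && i <= w) ? V0 : NEG;
    if (jhi < lb) cur[jhi + 1] = NEG;
    const char qi = qc[i - 1];
    int row_max = NEG;
    for (int j = jlo; j <= jhi; ++j) {
      const int d = prev[j - 1] + ((qi == bc[j - 1]) ? DIAG_EQ : -GAPV);
      const int u = prev[j] - GAPV;
      const int l = cur[j - 1] - GAPV;
      int v = d > u ? d : u;
      if (l > v) v = l;
      cur[j] = v;
      if (v > row_max) row_max = v;
    }
    if (jhi == lb && cur[lb] > best) best = cur[lb];
    if (i == lq)
      for (int j = jlo - 1; j <= jhi; ++j)
        if (j >= 0 && cur[j] > best) best = cur[j];
    // cannot reach the threshold score even with an all-match completion
    if (((row_max >> SHIFT) - BIAS) + (lq - i) < need) break;
    std::swap(prev, cur);
  }
  const int best_s = (best >> SHIFT) - BIAS, best_m = best & MASK;
  const int cols = 2 * best_m - best_s;
  return (cols <= 0) ? 0.0 : (double) best_m / (double) cols;
}

// [[Rcpp::export]]
NumericVector banded_identity_cpp(std::string q, CharacterVector refs,
                                  double min_identity) {
  const int lq = (int) q.size();
  if (lq == 0) stop("empty sequence");
  const int n = refs.size();
  NumericVector out(n);
  BandedScratch ws;
  for (int r = 0; r < n; ++r)
    out[r] = banded_pair(q.c_str(), lq, CHAR(STRING_ELT(refs, r)),
                         (int) LENGTH(STRING_ELT(refs, r)),
                         min_identity, ws);
  return out;
}

// Best reference per query under the shared tie rules: highest identity,
// then larger `sizes`, then earlier reference; 0 when nothing reaches
// min_identity. Mirrors the R-side .best_hit() selection.
// [[Rcpp::export]]
IntegerVector best_hit_batch(CharacterVector queries, CharacterVector refs,
                             NumericVector sizes, double min_identity) {
  const int nq = queries.size(), nr = refs.size();
  IntegerVector out(nq);
  BandedScratch ws;
  const double eps = 1e-12;
  std::vector< std::vector<long> > idx(nr);
  for (int r = 0; r < nr; ++r)
    idx[r] = kmer_index(CHAR(STRING_ELT(refs, r)),
                        (int) LENGTH(STRING_ELT(refs, r)));
  for (int i = 0; i < nq; ++i) {
    const char *qc = CHAR(STRING_ELT(queries, i));
    const int lq = (int) LENGTH(STRING_ELT(queries, i));
    int best = 0;
    double best_id = -1.0, best_size = -1.0;
    for (int r = 0; r < nr; ++r) {
      double id = banded_pair(qc, lq, CHAR(STRING_ELT(refs, r)),
                              (int) LENGTH(STRING_ELT(refs, r)),
                              min_identity, ws, &idx[r]);
      if (id < min_identity - eps) continue;
      if (id > best_id + eps ||
          (id > best_id - eps && sizes[r] > best_size)) {
        best = r + 1; best_id = id; best_size = sizes[r];
      }
    }
    out[i] = best;
  }
  return out;
}

// Greedy centroid clustering over uniques already sorted by decreasing
// size: join the best centroid at/above the threshold (ties to the larger
// founding size, then the earlier centroid); otherwise found a new
// centroid when size >= minsize. Returns per-unique centroid assignment
// (0 = discarded from centroid formation).
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, IntegerVector sizes,
                                 double threshold, int minsize) {
  const int n = seqs.size();
  IntegerVector out(n);
  std::vector<int> cent_idx;   // indices into seqs
  std::vector< std::vector<long> > cent_kmers;
  BandedScratch ws;
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    const char *qc = CHAR(STRING_ELT(seqs, i));
    const int lq = (int) LENGTH(STRING_ELT(seqs, i));
    int best = 0;
    double best_id = -1.0;
    int best_size = -1;
    for (size_t k = 0; k < cent_idx.size(); ++k) {
      const int r = cent_idx[k];
      double id = banded_pair(qc, lq, CHAR(STRING_ELT(seqs, r)),
                              (int) LENGTH(STRING_ELT(seqs, r)),
                              threshold, ws, &cent_kmers[k]);
      if (id < threshold - eps) continue;
      if (id > best_id + eps ||
          (id > best_id - eps && sizes[r] > best_size)) {
        best = (int) k + 1; best_id = id; best_size = sizes[r];
      }
    }
    if (best == 0 && sizes[i] >= minsize) {
      cent_idx.push_back(i);
      cent_kmers.push_back(kmer_index(qc, lq));
      best = (int) cent_idx.size();
    }
    out[i] = best;
  }
  return out;
}
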