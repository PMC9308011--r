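#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// Affine-gap global (Needleman-Wunsch/Gotoh) alignment of a vs b, optionally
// banded around the main diagonal. A one-base gap costs gap_open + gap_ext;
// each further base gap_ext. band <= 0 means full dynamic programming.
// Traceback tie order: diagonal > gap-in-b (vertical) > gap-in-a (horizontal).
struct AlnResult {
  std::string aa, ab;
  int score, matches, columns, mismatches;
};

static AlnResult align_core(const std::string& a, const std::string& b,
                            int match, int mismatch, int gap_open, int gap_ext,
                            int band, bool want_strings) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (band <= 0) band = std::max(la, lb);
  const int bl = band + std::max(0, la - lb);
  const int br = band + std::max(0, lb - la);
  const int W = bl + br + 1;          // k = j - i + bl in [0, W)
  const int go = gap_open, ge = gap_ext;

  std::vector<int> M((size_t)(la + 1) * W, NEG);
  std::vector<int> X((size_t)(la + 1) * W, NEG);  // gap in b (a consumed)
  std::vector<int> Y((size_t)(la + 1) * W, NEG);  // gap in a (b consumed)
  std::vector<unsigned char> tb((size_t)(la + 1) * W, 0); // 2 bits per matrix

  auto idx = [&](int i, int k) { return (size_t)i * W + k; };

  M[idx(0, bl)] = 0;
  for (int j = 1; j <= lb; ++j) {
    int k = j + bl;
    if (k >= W) break;
    Y[idx(0, k)] = -(go + ge * j);
    tb[idx(0, k)] |= (2 << 4); // Y came from Y
  }
  for (int i = 1; i <= la; ++i) {
    int k = bl - i;
    if (k < 0) break;
    X[idx(i, k)] = -(go + ge * i);
    tb[idx(i, k)] |= (1 << 2); // X came from X
  }

  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - bl), jhi = std::min(lb, i + br);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + bl;
      size_t c = idx(i, k);
      // M: diagonal from (i-1, j-1) -> same k; tie order M > X > Y
      {
        size_t d = idx(i - 1, k);
        int best = M[d], from = 0;
        if (X[d] > best) { best = X[d]; from = 1; }
        if (Y[d] > best) { best = Y[d]; from = 2; }
        if (best > NEG / 2) {
          int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          M[c] = best + s;
          tb[c] |= (unsigned char)from;
        }
      }
      // X: vertical from (i-1, j) -> k+1
      if (k + 1 < W) {
        size_t u = idx(i - 1, k + 1);
        int cm = M[u] - go - ge, cx = X[u] - ge, cy = Y[u] - go - ge;
        int best = cm, from = 0;
        if (cx > best) { best = cx; from = 1; }
        if (cy > best) { best = cy; from = 2; }
        if (best > NEG / 2) { X[c] = best; tb[c] |= (unsigned char)(from << 2); }
      }
      // Y: horizontal from (i, j-1) -> k-1
      if (k - 1 >= 0) {
        size_t l = idx(i, k - 1);
        int cm = M[l] - go - ge, cx = X[l] - go - ge, cy = Y[l] - ge;
        int best = cm, from = 0;
        if (cx > best) { best = cx; from = 1; }
        if (cy > best) { best = cy; from = 2; }
        if (best > NEG / 2) { Y[c] = best; tb[c] |= (unsigned char)(from << 4); }
      }
    }
  }

  int kend = lb - la + bl;
  size_t e = idx(la, kend);
  int state = 0, score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  if (score <= NEG / 2)
    stop("alignment band too narrow for these sequences");

  AlnResult r; r.score = score; r.matches = 0; r.columns = 0; r.mismatches = 0;
  std::string ra, rb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int k = j - i + bl;
    unsigned char t = tb[idx(i, k)];
    r.columns++;
    if (state == 0) {
      char ca = a[i - 1], cb = b[j - 1];
      if (want_strings) { ra.push_back(ca); rb.push_back(cb); }
      if (ca == cb) r.matches++; else r.mismatches++;
      state = t & 3;
      --i; --j;
    } else if (state == 1) {
      if (want_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      state = (t >> 2) & 3;
      --i;
    } else {
      if (want_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      state = (t >> 4) & 3;
      --j;
    }
  }
  if (want_strings) {
    r.aa.assign(ra.rbegin(), ra.rend());
    r.ab.assign(rb.rbegin(), rb.rend());
  }
  return r;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, int match, int mismatch,
                    int gap_open, int gap_ext, int band, bool strings) {
  if (a.empty() || b.empty()) stop("cannot align an empty sequence");
  AlnResult r = align_core(a, b, match, mismatch, gap_open, gap_ext, band, strings);
  List out = List::create(
    _["score"] = r.score, _["matches"] = r.matches,
    _["columns"] = r.columns, _["mismatches"] = r.mismatches);
  if (strings) { out["aligned_a"] = r.aa; out["aligned_b"] = r.ab; }
  return out;
}

// Align many patterns to one subject; returns parallel vectors (and aligned
// strings when requested). Used for consensus pileups and allele assignment.
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector patterns, std::string subject, int match,
                     int mismatch, int gap_open, int gap_ext, int band,
                     bool strings) {
  int n = patterns.size();
  IntegerVector score(n), matches(n), columns(n), mismatches(n);
  CharacterVector aa(n), ab(n);
  for (int i = 0; i < n; ++i) {
    std::string p = as<std::string>(patterns[i]);
    if (p.empty()) stop("cannot align an empty sequence");
    int b2 = band;
    if (b2 > 0) b2 += std::abs((int)p.size() - (int)subject.size());
    AlnResult r = align_core(p, subject, match, mismatch, gap_open, gap_ext,
                             b2, strings);
    score[i] = r.score; matches[i] = r.matches;
    columns[i] = r.columns; mismatches[i] = r.mismatches;
    if (strings) { aa[i] = r.aa; ab[i] = r.ab; }
  }
  List out = List::create(
    _["score"] = score, _["matches"] = matches,
    _["columns"] = columns, _["mismatches"] = mismatches);
  if (strings) { out["aligned_pattern"] = aa; out["aligned_subject"] = ab; }
  return out;
}

// Semi-global (pattern fully aligned, subject infix free) unit-cost edit
// distance; returns best distance with leftmost-ending match coordinates.
static void find_infix(const std::string& s, const std::string& p,
                       int& dist, int& start, int& end) {
  int m = (int)p.size(), n = (int)s.size();
  std::vector<int> prev(n + 1), cur(n + 1), pstart(n + 1), cstart(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; pstart[j] = j; }
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; cstart[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int diag = prev[j - 1] + (p[i - 1] == s[j - 1] ? 0 : 1);
      int up = prev[j] + 1, left = cur[j - 1] + 1;
      int best = diag, st = pstart[j - 1];
      if (up < best) { best = up; st = pstart[j]; }
      if (left < best) { best = left; st = cstart[j - 1]; }
      cur[j] = best; cstart[j] = st;
    }
    std::swap(prev, cur); std::swap(pstart, cstart);
  }
  dist = INT_MAX; start = 0; end = 0;
  for (int j = 0; j <= n; ++j) {
    if (prev[j] < dist) { dist = prev[j]; end = j; start = pstart[j]; }
  }
}

// [[Rcpp::export]]
List cpp_find_infix(std::string subject, std::string pattern) {
  if (subject.empty() || pattern.empty()) stop("empty sequence");
  int d, s, e;
  find_infix(subject, pattern, d, s, e);
  return List::create(_["dist"] = d, _["start"] = s + 1, _["end"] = e);
}

// Orient reads against amplicon primer pairs. For each read, both
// orientations are scanned: the forward primer must lie in the first
// `window` bases and the reverse-complemented reverse primer in the last
// `window` bases, each within its edit budget. The candidate with the
// smallest total edit count wins; a tie across distinct amplicons rejects
// the read as ambiguous. Returns one row per read:
// amp, strand (1 fwd / 2 rc), fwd_end, rev_start (oriented coords),
// edits, status (0 ok, 1 no_primer, 2 ambiguous).
// [[Rcpp::export]]
IntegerMatrix cpp_orient_reads(CharacterVector reads, CharacterVector reads_rc,
                               CharacterVector fwd_primers,
                               CharacterVector revrc_primers,
                               IntegerVector fwd_budget,
                               IntegerVector rev_budget, int window) {
  int n = reads.size(), na = fwd_primers.size();
  std::vector<std::string> fp(na), rp(na);
  for (int a = 0; a < na; ++a) {
    fp[a] = as<std::string>(fwd_primers[a]);
    rp[a] = as<std::string>(revrc_primers[a]);
  }
  IntegerMatrix out(n, 6);
  colnames(out) = CharacterVector::create("amp", "strand", "fwd_end",
                                          "rev_start", "edits", "status");
  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rc = as<std::string>(reads_rc[r]);
    int L = (int)fwd.size();
    int best_edits = INT_MAX, best_amp = -1, best_strand = 0;
    int best_fe = 0, best_rs = 0;
    bool tie_other_amp = false;
    if (L > 0) {
      int W = std::min(window, L);
      std::string headF = fwd.substr(0, W), tailF = fwd.substr(L - W);
      std::string headR = rc.substr(0, W), tailR = rc.substr(L - W);
      for (int strand = 1; strand <= 2; ++strand) {
        const std::string& head = (strand == 1) ? headF : headR;
        const std::string& tail = (strand == 1) ? tailF : tailR;
        for (int a = 0; a < na; ++a) {
          int d1, s1, e1;
          find_infix(head, fp[a], d1, s1, e1);
          if (d1 > fwd_budget[a]) continue;
          int d2, s2, e2;
          find_infix(tail, rp[a], d2, s2, e2);
          if (d2 > rev_budget[a]) continue;
          int tot = d1 + d2;
          int rev_start = L - W + s2 + 1; // 1-based start of rc(rev primer)
          if (tot < best_edits) {
            best_edits = tot; best_amp = a; best_strand = strand;
            best_fe = e1; best_rs = rev_start; tie_other_amp = false;
          } else if (tot == best_edits && a != best_amp) {
            tie_other_amp = true;
          }
        }
      }
    }
    if (best_amp < 0) {
      out(r, 5) = 1; // no_primer
    } else if (tie_other_amp) {
      out(r, 5) = 2; // ambiguous_amplicon
    } else {
      out(r, 0) = best_amp + 1;
      out(r, 1) = best_strand;
      out(r, 2) = best_fe;
      out(r, 3) = best_rs;
      out(r, 4) = best_edits;
      out(r, 5) = 0;
    }
  }
  return out;
}

// Levenshtein distance with early abandon above `limit`; returns limit + 1
// when the true distance exceeds it.
static int lev_bounded(const std::string& a, const std::string& b, int limit) {
  int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > limit) return limit + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - limit), jhi = std::min(lb, i + limit);
    cur[0] = i;
    if (jlo > 1) cur[jlo - 1] = limit + 1;
    int rowmin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = (j <= i + limit - 1) ? prev[j] + 1 : limit + 1;
      int left = (j - 1 >= jlo - 1) ? cur[j - 1] + 1 : limit + 1;
      int best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (jhi < lb) cur[jhi + 1] = limit + 1;
    if (rowmin > limit) return limit + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], limit + 1);
}

// [[Rcpp::export]]
int cpp_lev_bounded(std::string a, std::string b, int limit) {
  return lev_bounded(a, b, limit);
}

// Greedy directional UMI clustering. `umis` must already be sorted by count
// descending then lexicographic. A UMI joins an existing group when its
// Levenshtein distance to the group centroid is <= max_ed and its count is
// <= ceiling(centroid_count / ratio); candidate groups are ranked by
// distance, then centroid count, then creation order. Returns the 1-based
// group id per UMI; the centroid of group g is the first UMI assigned to it.
// [[Rcpp::export]]
IntegerVector cpp_group_umis(CharacterVector umis, IntegerVector counts,
                             int max_ed, double ratio) {
  int n = umis.size();
  IntegerVector gid(n);
  std::vector<std::string> cent;
  std::vector<int> cent_count, cent_first;
  for (int i = 0; i < n; ++i) {
    std::string u = as<std::string>(umis[i]);
    int best = -1, best_d = max_ed + 1, best_c = -1;
    for (size_t g = 0; g < cent.size(); ++g) {
      double cap = std::ceil((double)cent_count[g] / ratio);
      if ((double)counts[i] > cap) continue;
      int d = lev_bounded(u, cent[g], max_ed);
      if (d > max_ed) continue;
      if (d < best_d || (d == best_d && cent_count[g] > best_c)) {
        best = (int)g; best_d = d; best_c = cent_count[g];
      }
    }
    if (best < 0) {
      cent.push_back(u);
      cent_count.push_back(counts[i]);
      cent_first.push_back(i);
      gid[i] = (int)cent.size();
    } else {
      gid[i] = best + 1;
    }
  }
  return gid;
}

// Apply nanopore-like read errors: per-base substitution (to one of the
// three other bases), then left-to-right deletion/insertion, each position
// independent. Draws from R's RNG so results are reproducible via set.seed.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double sub, double ins,
                                double del) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    buf.clear();
    buf.reserve(s.size() + 16);
    for (size_t i = 0; i < s.size(); ++i) {
      char c = s[i];
      if (sub > 0 && unif_rand() < sub) {
        int bi = 0;
        switch (c) { case 'A': bi = 0; break; case 'C': bi = 1; break;
                     case 'G': bi = 2; break; default: bi = 3; }
        int k = (int)(unif_rand() * 3.0); if (k > 2) k = 2;
        c = BASES[(bi + 1 + k) % 4];
      }
      if (!(del > 0 && unif_rand() < del)) buf.push_back(c);
      if (ins > 0 && unif_rand() < ins) {
        int k = (int)(unif_rand() * 4.0); if (k > 3) k = 3;
        buf.push_back(BASES[k]);
      }
    }
    out[r] = buf;
  }
  return out;
}
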