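#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
std::string rc_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (char &c : out) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    case 'a': c = 't'; break;
    case 'c': c = 'g'; break;
    case 'g': c = 'c'; break;
    case 't': c = 'a'; break;
    default:  c = 'N'; break;
    }
  }
  return out;
}

struct OvlResult {
  int score, p_start, p_end, s_start, s_end;
};

// Ends-free ("overlap") pairwise alignment with linear gap costs.
// Both the pattern prefix/suffix and the subject prefix/suffix may dangle
// free of charge. When band_offset != NA the DP is restricted to the
// diagonal band j in [i + band_offset - band_width, i + band_offset +
// band_width]. Returns the optimal score with 1-based coordinates of the
// aligned blocks in both sequences.
static OvlResult overlap_align(const std::string &p, const std::string &s,
                               int match, int mismatch, int gap,
                               bool banded, int band_offset, int band_width) {
  const int m = (int)p.size(), n = (int)s.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<int> pbi(n + 1), pbj(n + 1), cbi(n + 1), cbj(n + 1);

  int best = NEG, bei = 0, bej = 0, bbi = 0, bbj = 0;

  // row 0: free subject prefix
  for (int j = 0; j <= n; ++j) { prev[j] = 0; pbi[j] = 0; pbj[j] = j; }
  // cell (0, n) is an admissible end (empty alignment)
  best = 0; bei = 0; bej = n; bbi = 0; bbj = n;

  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (banded) {
      jlo = std::max(1, i + band_offset - band_width);
      jhi = std::min(n, i + band_offset + band_width);
      if (jlo > n || jhi < 1) break;
      if (jlo > 1) { cur[jlo - 1] = NEG; }
    }
    if (jlo == 1) { cur[0] = 0; cbi[0] = i; cbj[0] = 0; }  // free pattern prefix
    for (int j = jlo; j <= jhi; ++j) {
      int diag = prev[j - 1] + (p[i - 1] == s[j - 1] ? match : mismatch);
      int up   = prev[j] + gap;   // gap in subject
      int left = cur[j - 1] + gap; // gap in pattern
      int sc = diag; int from = 0;
      if (up > sc) { sc = up; from = 1; }
      if (left > sc) { sc = left; from = 2; }
      cur[j] = sc;
      if (from == 0) { cbi[j] = pbi[j - 1]; cbj[j] = pbj[j - 1]; }
      else if (from == 1) { cbi[j] = pbi[j]; cbj[j] = pbj[j]; }
      else { cbi[j] = cbi[j - 1]; cbj[j] = cbj[j - 1]; }
      bool at_end = (i == m) || (j == n);
      if (at_end && sc > best) {
        best = sc; bei = i; bej = j; bbi = cbi[j]; bbj = cbj[j];
      }
    }
    if (banded && jhi < n) cur[jhi + 1] = NEG;  // sentinel for next row
    std::swap(prev, cur); std::swap(pbi, cbi); std::swap(pbj, cbj);
  }
  OvlResult r;
  r.score = best; r.p_start = bbi + 1; r.p_end = bei;
  r.s_start = bbj + 1; r.s_end = bej;
  return r;
}

// [[Rcpp::export]]
List align_overlap_cpp(std::string pattern, std::string subject,
                       int match, int mismatch, int gap,
                       int band_offset, int band_width, bool banded) {
  OvlResult r = overlap_align(pattern, subject, match, mismatch, gap,
                              banded, band_offset, band_width);
  return List::create(_["score"] = r.score,
                      _["p_start"] = r.p_start, _["p_end"] = r.p_end,
                      _["s_start"] = r.s_start, _["s_end"] = r.s_end);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2;
  case 'T': return 3; default: return -1;
  }
}

// k-mer -> first position index of a sequence (2-bit encoding, k <= 31)
static std::unordered_map<uint64_t, int> kmer_index(const std::string &s,
                                                    int k) {
  std::unordered_map<uint64_t, int> idx;
  const int n = (int)s.size();
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx.emplace(key, i - k + 1);
  }
  return idx;
}

// Locate the band diagonal for a read against a conformation: probe
// non-overlapping k-mer windows across the read in the conformation's
// k-mer index and take the modal offset. A read that shares no k-mer at
// all with a conformation cannot plausibly derive from it and is skipped
// by the caller.
static bool find_seed(const std::string &read,
                      const std::unordered_map<uint64_t, int> &idx,
                      int k, int &offset) {
  int L = (int)read.size();
  if (L < k) return false;
  std::unordered_map<int, int> votes;
  int best_off = 0, best_n = 0;
  for (int p0 = 0; p0 + k <= L; p0 += k) {
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base_code(read[p0 + j]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    int off = it->second - p0;
    int n = ++votes[off];
    if (n > best_n) { best_n = n; best_off = off; }
  }
  if (best_n == 0) return false;
  offset = best_off;
  return true;
}

// [[Rcpp::export]]
DataFrame classify_reads_cpp(CharacterVector reads, CharacterVector confs,
                             IntegerVector rep_start, IntegerVector rep_end,
                             int min_anchor, int min_margin,
                             int match, int mismatch, int gap,
                             int band_width, int seed_k) {
  const int nr = reads.size();
  std::vector<std::string> cs(4);
  std::vector<std::unordered_map<uint64_t, int> > idx(4);
  for (int c = 0; c < 4; ++c) {
    cs[c] = as<std::string>(confs[c]);
    if (band_width > 0) idx[c] = kmer_index(cs[c], seed_k);
  }
  int replen = rep_end[0] - rep_start[0] + 1;

  CharacterVector best_out(nr), strand_out(nr), reason_out(nr);
  IntegerVector sb_out(nr), ss_out(nr), al_out(nr), ar_out(nr);
  LogicalVector usable_out(nr);
  static const char *labels[4] = {"c1", "c2", "c3", "c4"};

  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int L = (int)rd.size();
    if (L < replen + 2 * min_anchor) {
      best_out[r] = NA_STRING; strand_out[r] = NA_STRING;
      sb_out[r] = NA_INTEGER; ss_out[r] = NA_INTEGER;
      al_out[r] = NA_INTEGER; ar_out[r] = NA_INTEGER;
      usable_out[r] = false; reason_out[r] = "too_short";
      continue;
    }
    std::string rc = rc_cpp(rd);
    int sc[4]; OvlResult best_res[4]; char strand_best[4];
    for (int c = 0; c < 4; ++c) {
      sc[c] = NEG;
      for (int st = 0; st < 2; ++st) {
        const std::string &q = st == 0 ? rd : rc;
        OvlResult res;
        int off = 0;
        if (band_width > 0) {
          // no shared seed k-mer: the read cannot derive from this
          // conformation on this strand; skip the alignment
          if (!find_seed(q, idx[c], seed_k, off)) continue;
          res = overlap_align(q, cs[c], match, mismatch, gap,
                              true, off, band_width);
        } else {
          res = overlap_align(q, cs[c], match, mismatch, gap, false, 0, 0);
        }
        if (res.score > sc[c]) {
          sc[c] = res.score; best_res[c] = res;
          strand_best[c] = st == 0 ? '+' : '-';
        }
      }
    }
    {
      bool any = false;
      for (int c = 0; c < 4; ++c) if (sc[c] > NEG) any = true;
      if (!any) {
        best_out[r] = NA_STRING; strand_out[r] = NA_STRING;
        sb_out[r] = NA_INTEGER; ss_out[r] = NA_INTEGER;
        al_out[r] = NA_INTEGER; ar_out[r] = NA_INTEGER;
        usable_out[r] = false; reason_out[r] = "no_seed";
        continue;
      }
    }
    int cbest = 0;
    for (int c = 1; c < 4; ++c) if (sc[c] > sc[cbest]) cbest = c;
    int second = NEG;
    for (int c = 0; c < 4; ++c) if (c != cbest && sc[c] > second) second = sc[c];
    const OvlResult &br = best_res[cbest];
    int aleft = rep_start[cbest] - br.s_start;
    int aright = br.s_end - rep_end[cbest];
    bool covers = (aleft >= min_anchor) && (aright >= min_anchor);
    sb_out[r] = sc[cbest]; ss_out[r] = second;
    al_out[r] = std::max(aleft, 0); ar_out[r] = std::max(aright, 0);
    strand_out[r] = std::string(1, strand_best[cbest]);
    if (!covers) {
      usable_out[r] = false; reason_out[r] = "no_span";
      best_out[r] = NA_STRING;
    } else if (sc[cbest] - second < min_margin || sc[cbest] == second) {
      usable_out[r] = true; reason_out[r] = NA_STRING;
      best_out[r] = "ambiguous";
    } else {
      usable_out[r] = true; reason_out[r] = NA_STRING;
      best_out[r] = labels[cbest];
    }
  }
  return DataFrame::create(
      _["best"] = best_out, _["strand"] = strand_out,
      _["score_best"] = sb_out, _["score_second"] = ss_out,
      _["anchor_left"] = al_out, _["anchor_right"] = ar_out,
      _["usable"] = usable_out, _["reason"] = reason_out,
      _["stringsAsFactors"] = false);
}
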