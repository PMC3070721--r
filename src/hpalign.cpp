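#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <array>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Column costs for the homopolymer-insensitive global alignment:
//  - substitution column: 1 if the bases differ, else 0;
//  - indel column: 0 iff the inserted/deleted base equals the most recently
//    consumed base of the OPPOSITE sequence (the indel merely changes the
//    length of a homopolymer run shared by both sequences at that point);
//  - an indel before any opposite base has been consumed always costs 1.

static void check_acgt(const std::string& s, const char* what) {
  for (char c : s) {
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("non-ACGT character '%c' in %s", c, what);
  }
}

// Full dynamic program; returns the distance, optionally filling a traceback.
static int hp_dp(const std::string& a, const std::string& b,
                 std::vector<signed char>* tb) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  if (tb) tb->assign((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) {
    prev[j] = j;
    if (tb) (*tb)[j] = 2;            // came from left (insert b_j)
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    if (tb) (*tb)[(size_t)i * (m + 1)] = 1;   // from above (delete a_i)
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      int up   = prev[j] + (a[i - 1] == b[j - 1] ? 0 : 1);   // delete a_i; last consumed b is b_j
      int left = cur[j - 1] + (b[j - 1] == a[i - 1] ? 0 : 1); // insert b_j; last consumed a is a_i
      int best = diag; signed char dir = 0;
      if (up < best)   { best = up;   dir = 1; }
      if (left < best) { best = left; dir = 2; }
      cur[j] = best;
      if (tb) (*tb)[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".hp_distance_cpp")]]
List hp_distance_cpp(std::string a, std::string b, bool alignment = false) {
  check_acgt(a, "first sequence");
  check_acgt(b, "second sequence");
  if (!alignment) {
    int d = hp_dp(a, b, nullptr);
    return List::create(_["distance"] = d);
  }
  std::vector<signed char> tb;
  int d = hp_dp(a, b, &tb);
  const int m = (int)b.size();
  std::string ga, gb;
  int i = (int)a.size(), j = m;
  while (i > 0 || j > 0) {
    signed char dir = tb[(size_t)i * (m + 1) + j];
    if (dir == 0) { ga += a[--i]; gb += b[--j]; }
    else if (dir == 1) { ga += a[--i]; gb += '-'; }
    else { ga += '-'; gb += b[--j]; }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["distance"] = d,
                      _["alignment"] = CharacterVector::create(ga, gb));
}

// Row-minimum early abandoning; returns min(distance, k + 1). Exact whenever
// the true distance is <= k because column costs are non-negative.
static int hp_bounded(const std::string& a, const std::string& b, int k) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  if (n == 0) return std::min(m, k + 1);
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      int up   = prev[j] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int left = cur[j - 1] + (b[j - 1] == a[i - 1] ? 0 : 1);
      int best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[m], k + 1);
}

// [[Rcpp::export(name = ".hp_bounded_cpp")]]
int hp_bounded_cpp(std::string a, std::string b, int k) {
  check_acgt(a, "first sequence");
  check_acgt(b, "second sequence");
  if (k < 0) stop("k must be >= 0");
  return hp_bounded(a, b, k);
}

// Exhaustive-alignment oracle: plain depth-first enumeration of every global
// alignment path, no memoisation. Used only in tests; exponential.
static int oracle_rec(const std::string& a, const std::string& b, int i, int j) {
  const int n = (int)a.size(), m = (int)b.size();
  if (i == n && j == m) return 0;
  int best = INT_MAX;
  if (i < n && j < m) {
    int c = (a[i] != b[j] ? 1 : 0) + oracle_rec(a, b, i + 1, j + 1);
    if (c < best) best = c;
  }
  if (i < n) {  // delete a[i]; last consumed base of b is b[j-1]
    int c = ((j > 0 && a[i] == b[j - 1]) ? 0 : 1) + oracle_rec(a, b, i + 1, j);
    if (c < best) best = c;
  }
  if (j < m) {  // insert b[j]; last consumed base of a is a[i-1]
    int c = ((i > 0 && b[j] == a[i - 1]) ? 0 : 1) + oracle_rec(a, b, i, j + 1);
    if (c < best) best = c;
  }
  return best;
}

// [[Rcpp::export(name = ".hp_oracle_cpp")]]
int hp_oracle_cpp(std::string a, std::string b, int max_len = 12) {
  check_acgt(a, "first sequence");
  check_acgt(b, "second sequence");
  if ((int)a.size() > max_len || (int)b.size() > max_len)
    stop("oracle refuses sequences longer than %d", max_len);
  return oracle_rec(a, b, 0, 0);
}

// Abundance-greedy clustering over sequences already sorted by decreasing
// abundance. Returns the 1-based OTU index (seed-creation order) per tag.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, int k) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    check_acgt(s[i], "tag sequence");
  }
  std::vector<int> assign(n, 0);
  int n_otu = 0;
  for (int i = 0; i < n; ++i) {
    if (assign[i]) continue;
    assign[i] = ++n_otu;
    for (int j = i + 1; j < n; ++j) {
      if (assign[j]) continue;
      if (hp_bounded(s[i], s[j], k) <= k) assign[j] = n_otu;
    }
    Rcpp::checkUserInterrupt();
  }
  return wrap(assign);
}

// Unit-cost global (Needleman-Wunsch) alignment; reports match columns and
// total columns so callers can form an identity fraction.
// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> D((size_t)(n + 1) * (m + 1));
  std::vector<signed char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { D[j] = j; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * (m + 1)] = i; tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int diag = D[(size_t)(i - 1) * (m + 1) + j - 1] + (a[i - 1] != b[j - 1]);
      int up   = D[(size_t)(i - 1) * (m + 1) + j] + 1;
      int left = D[(size_t)i * (m + 1) + j - 1] + 1;
      int best = diag; signed char dir = 0;
      if (up < best)   { best = up;   dir = 1; }
      if (left < best) { best = left; dir = 2; }
      D[(size_t)i * (m + 1) + j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
  }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    signed char dir = tb[(size_t)i * (m + 1) + j];
    ++cols;
    if (dir == 0) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (dir == 1) --i;
    else --j;
  }
  if (cols == 0) cols = 1;
  return List::create(_["matches"] = matches, _["columns"] = cols,
                      _["distance"] = D[(size_t)n * (m + 1) + m]);
}

// ---- Seeded local search -------------------------------------------------

struct SwResult { int score, identities, gaps, q_start, q_end; };

// Affine-gap Smith-Waterman (Gotoh), BLAST-like scoring. A gap of length L
// costs gap_open + gap_ext * L. Reports identities (match columns) and gap
// columns of the best local alignment, 0-based half-open query coordinates.
static SwResult sw_align(const std::string& q, const std::string& r,
                         int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)q.size(), m = (int)r.size();
  const int NEG = -1000000000;
  const size_t W = (size_t)m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // tbH: -1 stop, 0 diagonal, 1 enter E, 2 enter F
  // tbE/tbF: 1 if the gap opened here (came from H), 0 if it extends
  std::vector<signed char> tbH((n + 1) * W, -1), tbE((n + 1) * W, 1),
      tbF((n + 1) * W, 1);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, up = c - W, left = c - 1, diag = up - 1;
      int e_open = H[up] - gap_open - gap_ext, e_ext = E[up] - gap_ext;
      E[c] = std::max(e_open, e_ext);
      tbE[c] = (e_open >= e_ext) ? 1 : 0;
      int f_open = H[left] - gap_open - gap_ext, f_ext = F[left] - gap_ext;
      F[c] = std::max(f_open, f_ext);
      tbF[c] = (f_open >= f_ext) ? 1 : 0;
      int sc = H[diag] + (q[i - 1] == r[j - 1] ? match : mismatch);
      int h = 0; signed char dir = -1;
      if (sc > h) { h = sc; dir = 0; }
      if (E[c] > h) { h = E[c]; dir = 1; }
      if (F[c] > h) { h = F[c]; dir = 2; }
      H[c] = h; tbH[c] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SwResult res{best, 0, 0, 0, 0};
  if (best == 0) return res;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  res.q_end = bi;
  for (;;) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      signed char dir = tbH[c];
      if (dir == -1) break;
      if (dir == 0) {
        if (q[i - 1] == r[j - 1]) ++res.identities;
        --i; --j;
      } else {
        state = dir;
      }
    } else if (state == 1) {  // query base against gap in reference
      ++res.gaps;
      state = tbE[c] ? 0 : 1;
      --i;
    } else {                  // reference base against gap in query
      ++res.gaps;
      state = tbF[c] ? 0 : 2;
      --j;
    }
    if (i == 0 || j == 0) break;
  }
  res.q_start = i;
  return res;
}

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Seeded search of many queries against a reference set. A reference is a
// candidate for a query when at least `min_shared_words` query positions carry
// a word (length `word_size`) present in the reference; candidates are scored
// by local alignment. Returns parallel vectors of (query, ref) hit records.
// [[Rcpp::export(name = ".search_many_cpp")]]
List search_many_cpp(CharacterVector queries, CharacterVector refs,
                     int word_size = 7, int min_shared_words = 4,
                     int match = 5, int mismatch = -4,
                     int gap_open = 8, int gap_ext = 6) {
  const int nq = queries.size(), nr = refs.size();
  if (nr == 0) stop("reference set is empty");
  if (word_size < 1 || word_size > 12) stop("word_size out of range");
  const uint32_t nwords = 1u << (2 * word_size);
  std::vector<std::string> R(nr);
  for (int j = 0; j < nr; ++j) R[j] = as<std::string>(refs[j]);

  // word -> sorted unique ref ids
  std::vector<std::vector<int>> index(nwords);
  for (int j = 0; j < nr; ++j) {
    const std::string& s = R[j];
    uint32_t w = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & (nwords - 1);
      if (++run >= word_size) {
        std::vector<int>& v = index[w];
        if (v.empty() || v.back() != j) v.push_back(j);
      }
    }
  }

  std::vector<int> out_q, out_r, out_score, out_id, out_gap, out_qs, out_qe;
  std::vector<int> count(nr), stamp(nr, -1);
  for (int qi = 0; qi < nq; ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    uint32_t w = 0; int run = 0;
    for (size_t p = 0; p < q.size(); ++p) {
      int c = base_code(q[p]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & (nwords - 1);
      if (++run >= word_size) {
        for (int rj : index[w]) {
          if (stamp[rj] != qi) { stamp[rj] = qi; count[rj] = 0; }
          ++count[rj];
        }
      }
    }
    for (int rj = 0; rj < nr; ++rj) {
      if (stamp[rj] != qi || count[rj] < min_shared_words) continue;
      SwResult sw = sw_align(q, R[rj], match, mismatch, gap_open, gap_ext);
      if (sw.score <= 0) continue;
      out_q.push_back(qi + 1); out_r.push_back(rj + 1);
      out_score.push_back(sw.score); out_id.push_back(sw.identities);
      out_gap.push_back(sw.gaps);
      out_qs.push_back(sw.q_start); out_qe.push_back(sw.q_end);
    }
    if (qi % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["query"] = wrap(out_q), _["ref"] = wrap(out_r),
                      _["score"] = wrap(out_score),
                      _["identities"] = wrap(out_id),
                      _["gaps"] = wrap(out_gap),
                      _["q_start"] = wrap(out_qs), _["q_end"] = wrap(out_qe));
}
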