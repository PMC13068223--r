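#include <Rcpp.h>
#include <array>
#include <cstring>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Unit-cost edit alignment primitives used across the package:
//  - cpp_anchor_scan: all non-overlapping approximate occurrences of a short
//    query (the anchor) in a long target, semi-global, with traceback.
//  - cpp_semiglobal: best single occurrence of a full query inside a target
//    (query global, target local), with full edit script.
//  - cpp_global: end-to-end alignment of two near-identical sequences.
//  - cpp_min_rotation: Booth's algorithm for canonical circular form.
// Edit scripts use ops 'M' match, 'X' mismatch, 'I' query-only base,
// 'D' target-only base.

static const int BIG = std::numeric_limits<int>::max() / 4;

// ---------------------------------------------------------------------------
// Anchor scan: full DP with move matrix (query is short, ~200 bp).
// Returns an integer matrix with columns start, end (1-based, inclusive) and
// dist, sorted by start.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_scan(std::string query, std::string target,
                              int max_dist) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n < 1 || m < 1) return IntegerMatrix(0, 3);

  // moves: 0 diag, 1 up (query-only), 2 left (target-only)
  std::vector<unsigned char> mv((size_t)(n + 1) * (m + 1));
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0;  // free target prefix
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    mv[(size_t)i * (m + 1)] = 1;
    const char qc = query[i - 1];
    const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
    (void)prow;
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (qc != target[j - 1]);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      int best = d; unsigned char b = 0;
      if (u < best) { best = u; b = 1; }
      if (l < best) { best = l; b = 2; }
      cur[j] = best;
      mv[row + j] = b;
    }
    std::swap(prev, cur);
  }
  // prev now holds row n: dist of query aligned ending at column j
  std::vector<int> ends(prev.begin(), prev.end());
  std::vector<bool> masked(m + 1, false);
  std::vector<std::array<int, 3>> hits;
  for (;;) {
    int bestj = -1, bestd = max_dist + 1;
    for (int j = 1; j <= m; ++j)
      if (!masked[j] && ends[j] < bestd) { bestd = ends[j]; bestj = j; }
    if (bestj < 0) break;
    // traceback from (n, bestj) to row 0 to find the start column
    int i = n, j = bestj;
    while (i > 0) {
      unsigned char b = mv[(size_t)i * (m + 1) + j];
      if (b == 0) { --i; --j; }
      else if (b == 1) { --i; }
      else { --j; }
    }
    int s = j;  // occurrence covers target positions s+1 .. bestj (1-based)
    hits.push_back({s + 1, bestj, bestd});
    int lo = std::max(1, s + 1), hi = std::min(m, bestj + n - 1);
    for (int k = lo; k <= hi; ++k) masked[k] = true;
  }
  std::sort(hits.begin(), hits.end(),
            [](const std::array<int, 3>& a, const std::array<int, 3>& b) {
              return a[0] < b[0];
            });
  IntegerMatrix out((int)hits.size(), 3);
  for (int r = 0; r < (int)hits.size(); ++r) {
    out(r, 0) = hits[r][0]; out(r, 1) = hits[r][1]; out(r, 2) = hits[r][2];
  }
  colnames(out) = CharacterVector::create("start", "end", "dist");
  return out;
}

// ---------------------------------------------------------------------------
// Banded global alignment of query vs target window with a free target
// prefix (start column free in row 0). End fixed at (n, L). Returns dist,
// start column (0-based) and reversed ops, or dist = -1 if the band was too
// narrow to reach the end.
static int banded_freeprefix(const std::string& q, const std::string& t,
                             int h, bool free_prefix,
                             int* start_col, std::string* ops_rev) {
  const int n = (int)q.size(), L = (int)t.size();
  const int off = L - n;  // band center at row i: i + off
  const int W = 2 * h + 1;
  std::vector<int> prev(W, BIG), cur(W, BIG);
  std::vector<unsigned char> mv((size_t)(n + 1) * W, 3);

  // row 0: cols max(0, off-h) .. min(L, off+h)
  int lo0 = std::max(0, off - h), hi0 = std::min(L, off + h);
  for (int j = lo0; j <= hi0; ++j)
    prev[j - (off - h)] = free_prefix ? 0 : j;
  for (int i = 1; i <= n; ++i) {
    const int c = i + off;
    const int lo = std::max(0, c - h), hi = std::min(L, c + h);
    const int base = c - h;          // col of slot 0 in this row
    const int pbase = base - 1;      // col of slot 0 in previous row
    std::fill(cur.begin(), cur.end(), BIG);
    const char qc = q[i - 1];
    const size_t row = (size_t)i * W;
    for (int j = lo; j <= hi; ++j) {
      const int s = j - base;
      int best = BIG; unsigned char b = 3;
      if (j >= 1) {
        int ps = j - 1 - pbase;  // diag: prev row col j-1
        if (ps >= 0 && ps < W && prev[ps] < BIG) {
          int d = prev[ps] + (qc != t[j - 1]);
          if (d < best) { best = d; b = 0; }
        }
      }
      {
        int ps = j - pbase;      // up: prev row col j
        if (ps >= 0 && ps < W && prev[ps] < BIG) {
          int u = prev[ps] + 1;
          if (u < best) { best = u; b = 1; }
        }
      }
      if (j >= 1 && s >= 1 && cur[s - 1] < BIG) {
        int l = cur[s - 1] + 1;  // left
        if (l < best) { best = l; b = 2; }
      }
      cur[s] = best;
      mv[row + s] = b;
    }
    std::swap(prev, cur);
  }
  const int endc = n + off;  // = L
  int slot = L - (endc - h);
  if (slot < 0 || slot >= W || prev[slot] >= BIG) return -1;
  int dist = prev[slot];
  if (ops_rev) {
    ops_rev->clear();
    int i = n, j = L;
    while (i > 0) {
      int c = i + off, s = j - (c - h);
      unsigned char b = mv[(size_t)i * W + s];
      if (b == 0) { ops_rev->push_back(q[i - 1] == t[j - 1] ? 'M' : 'X'); --i; --j; }
      else if (b == 1) { ops_rev->push_back('I'); --i; }
      else if (b == 2) { ops_rev->push_back('D'); --j; }
      else return -1;
    }
    if (!free_prefix) { while (j > 0) { ops_rev->push_back('D'); --j; } }
    if (start_col) *start_col = j;
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Semi-global alignment: full query against a local stretch of target.
// Returns list(dist, t_start, t_end, ops); t_start/t_end 1-based inclusive.
// [[Rcpp::export]]
List cpp_semiglobal(std::string query, std::string target, bool with_ops = true) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n < 1 || m < 1) stop("empty sequence in alignment");
  // pass 1: rolling rows over the full target to find the best end column
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char qc = query[i - 1];
    int* pv = prev.data(); int* cv = cur.data();
    for (int j = 1; j <= m; ++j) {
      int d = pv[j - 1] + (qc != target[j - 1]);
      int u = pv[j] + 1;
      if (u < d) d = u;
      int l = cv[j - 1] + 1;
      if (l < d) d = l;
      cv[j] = d;
    }
    std::swap(prev, cur);
  }
  int e = 1, dist = prev[1];
  for (int j = 2; j <= m; ++j) if (prev[j] < dist) { dist = prev[j]; e = j; }
  if (!with_ops)
    return List::create(_["dist"] = dist, _["t_start"] = NA_INTEGER,
                        _["t_end"] = e, _["ops"] = R_NilValue);
  // pass 2: banded traceback on the window ending at e
  int s_min = std::max(0, e - n - dist - 2);
  std::string window = target.substr(s_min, e - s_min);
  int h = std::max(8, 2 * dist + 8);
  const int Lw = (int)window.size();
  for (;;) {
    int start_col = 0; std::string ops_rev;
    int d2 = banded_freeprefix(query, window, h, true, &start_col, &ops_rev);
    if (d2 >= 0 && d2 <= dist) {
      std::reverse(ops_rev.begin(), ops_rev.end());
      return List::create(_["dist"] = d2,
                          _["t_start"] = s_min + start_col + 1,
                          _["t_end"] = e,
                          _["ops"] = ops_rev);
    }
    if (h >= Lw + n) stop("semi-global traceback failed");  // unreachable
    h *= 2;
  }
}

// ---------------------------------------------------------------------------
// Global alignment with automatic band widening.
// [[Rcpp::export]]
List cpp_global(std::string query, std::string target) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n < 1 || m < 1) stop("empty sequence in alignment");
  int h = std::max(16, std::abs(n - m) + 8);
  for (;;) {
    std::string ops_rev;
    int d = banded_freeprefix(query, target, h, false, nullptr, &ops_rev);
    // optimal iff the band provably contains any path of cost d
    if (d >= 0 && (d + std::abs(n - m) < h || h >= n + m)) {
      std::reverse(ops_rev.begin(), ops_rev.end());
      return List::create(_["dist"] = d, _["ops"] = ops_rev);
    }
    if (h >= n + m) stop("global alignment failed");  // unreachable
    h *= 2;
  }
}

// ---------------------------------------------------------------------------
// Booth's algorithm: 1-based start index of the lexicographically minimal
// rotation of s.
// [[Rcpp::export]]
int cpp_min_rotation(std::string s) {
  const int n = (int)s.size();
  if (n == 0) stop("empty string");
  std::string ss = s + s;
  std::vector<int> f(2 * n, -1);
  int k = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = ss[j];
    int i = f[j - k - 1];
    while (i != -1 && sj != ss[k + i + 1]) {
      if (sj < ss[k + i + 1]) k = j - i - 1;
      i = f[i];
    }
    if (sj != ss[k + i + 1]) {
      if (sj < ss[k]) k = j;
      f[j - k] = -1;
    } else {
      f[j - k] = i + 1;
    }
  }
  return k + 1;
}
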