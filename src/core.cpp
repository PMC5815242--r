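// Suffix-array machinery for the concatenated profile string, plus the
// block-filter candidate enumeration and LCE-based capped Hamming
// verification. All positions and row indices here are 0-based; the R
// wrappers translate rows to 1-based.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// ---- suffix array (prefix doubling, O(n log^2 n)) --------------------------

// [[Rcpp::export]]
IntegerVector cpp_build_sa(IntegerVector s) {
  const int n = s.size();
  std::vector<int> sa(n), rank(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank[i] = s[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank[a] != rank[b]) return rank[a] < rank[b];
      int ra = a + len < n ? rank[a + len] : -1;
      int rb = b + len < n ? rank[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank = tmp;
    if (rank[sa[n - 1]] == n - 1 || len >= n) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// ---- LCP array (Kasai) -----------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_build_lcp(IntegerVector s, IntegerVector sa) {
  const int n = s.size();
  std::vector<int> isa(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) isa[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (isa[i] > 0) {
      int j = sa[isa[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[isa[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return IntegerVector(lcp.begin(), lcp.end());
}

// ---- sparse-table RMQ over the LCP array -----------------------------------
// Table entries hold *indices* of range minima so ties resolve to a position.

// [[Rcpp::export]]
IntegerMatrix cpp_build_rmq(IntegerVector lcp) {
  const int n = lcp.size();
  int levels = 1;
  while ((1 << levels) <= n) ++levels;
  IntegerMatrix sp(n, levels);
  for (int i = 0; i < n; ++i) sp(i, 0) = i;
  for (int j = 1; j < levels; ++j) {
    const int span = 1 << j;
    for (int i = 0; i + span <= n; ++i) {
      int a = sp(i, j - 1), b = sp(i + (span >> 1), j - 1);
      sp(i, j) = (lcp[a] <= lcp[b]) ? a : b;
    }
  }
  return sp;
}

static inline int rmq_query(const IntegerVector& lcp, const IntegerMatrix& sp,
                            int i, int j) {
  // index of minimum of lcp[i..j], inclusive, i <= j
  int k = 0;
  while ((1 << (k + 1)) <= j - i + 1) ++k;
  int a = sp(i, k), b = sp(j - (1 << k) + 1, k);
  return (lcp[a] <= lcp[b]) ? a : b;
}

// [[Rcpp::export]]
int cpp_rmq(IntegerVector lcp, IntegerMatrix sp, int i, int j) {
  return rmq_query(lcp, sp, i, j);
}

static inline int lce_at(const IntegerVector& lcp, const IntegerMatrix& sp,
                         const IntegerVector& isa, int n, int i, int j) {
  if (i == j) return n - i;
  int ri = isa[i], rj = isa[j];
  if (ri > rj) std::swap(ri, rj);
  return lcp[rmq_query(lcp, sp, ri + 1, rj)];
}

// [[Rcpp::export]]
int cpp_lce(IntegerVector lcp, IntegerMatrix sp, IntegerVector isa,
            int n, int i, int j) {
  return lce_at(lcp, sp, isa, n, i, j);
}

// ---- capped Hamming distance by LCE jumps (kangaroo) -----------------------
// Returns min(cap, H(row pi, row pj)); each LCE is clipped at the profile end
// so that matches never leak across the separator-free concatenation.

static inline int hd_capped(const IntegerVector& lcp, const IntegerMatrix& sp,
                            const IntegerVector& isa, int n, int m,
                            int pi, int pj, int cap) {
  int q = 0, mism = 0;
  const int a = pi * m, b = pj * m;
  while (q < m) {
    int e = lce_at(lcp, sp, isa, n, a + q, b + q);
    if (e > m - q) e = m - q;
    q += e;
    if (q >= m) break;
    if (++mism >= cap) return cap;
    ++q;
  }
  return mism;
}

// [[Rcpp::export]]
int cpp_hd_capped(IntegerVector lcp, IntegerMatrix sp, IntegerVector isa,
                  int n, int m, int pi, int pj, int cap) {
  return hd_capped(lcp, sp, isa, n, m, pi, pj, cap);
}

// ---- candidate enumeration: LCP-cluster scan -------------------------------
// One left-to-right scan of the LCP array; maximal runs with adjacent
// lcp >= L share a length-L prefix, and aligned members are grouped by
// block ordinal before pair emission.

static inline int aligned_block(int pos, int m, int L) {
  int l = pos % m;
  if (l % L == 0 && l + L <= m) return l / L;
  return -1;
}

// [[Rcpp::export]]
int cpp_aligned(int pos, int m, int L) { return aligned_block(pos, m, L); }

// [[Rcpp::export]]
IntegerMatrix cpp_candidates_lcp(IntegerVector sa, IntegerVector lcp,
                                 int m, int d, int L) {
  const int n = sa.size();
  std::vector<int> oi, oj, ot;
  std::vector<std::pair<int, int>> members;  // (block ordinal, profile row)
  auto flush = [&](int start, int end) {
    members.clear();
    for (int q = start; q <= end; ++q) {
      int t = aligned_block(sa[q], m, L);
      if (t >= 0) members.push_back({t, sa[q] / m});
    }
    std::sort(members.begin(), members.end());
    size_t a = 0;
    while (a < members.size()) {
      size_t b = a;
      while (b < members.size() && members[b].first == members[a].first) ++b;
      for (size_t u = a; u < b; ++u)
        for (size_t v = u + 1; v < b; ++v) {
          int r1 = members[u].second, r2 = members[v].second;
          if (r1 == r2) continue;
          oi.push_back(std::min(r1, r2));
          oj.push_back(std::max(r1, r2));
          ot.push_back(members[a].first);
        }
      a = b;
    }
  };
  int runStart = -1;
  for (int p = 1; p < n; ++p) {
    if (lcp[p] >= L) {
      if (runStart < 0) runStart = p - 1;
    } else if (runStart >= 0) {
      flush(runStart, p - 1);
      runStart = -1;
    }
  }
  if (runStart >= 0) flush(runStart, n - 1);
  IntegerMatrix out(oi.size(), 3);
  for (size_t r = 0; r < oi.size(); ++r) {
    out(r, 0) = oi[r]; out(r, 1) = oj[r]; out(r, 2) = ot[r];
  }
  return out;
}

// ---- candidate enumeration: SA binary search per block ---------------------

// compare suffix starting at pos against pattern pat[from..from+L-1];
// a suffix shorter than L that matches as far as it goes sorts before.
static inline int cmp_suffix_pattern(const IntegerVector& s, int n, int pos,
                                     const int* pat, int L) {
  for (int q = 0; q < L; ++q) {
    if (pos + q >= n) return -1;
    if (s[pos + q] != pat[q]) return s[pos + q] < pat[q] ? -1 : 1;
  }
  return 0;
}

static inline void sa_range(const IntegerVector& s, const IntegerVector& sa,
                            int n, const int* pat, int L, int& lo, int& hi) {
  int a = 0, b = n;  // lo: first idx with suffix >= pattern-prefix
  while (a < b) {
    int mid = (a + b) / 2;
    if (cmp_suffix_pattern(s, n, sa[mid], pat, L) < 0) a = mid + 1; else b = mid;
  }
  lo = a;
  b = n;
  while (a < b) {
    int mid = (a + b) / 2;
    if (cmp_suffix_pattern(s, n, sa[mid], pat, L) <= 0) a = mid + 1; else b = mid;
  }
  hi = a;
}

// [[Rcpp::export]]
IntegerMatrix cpp_candidates_binary(IntegerVector s, IntegerVector sa,
                                    int m, int d, int L) {
  const int n = s.size();
  std::vector<int> oi, oj, ot;
  std::vector<int> pat(L);
  for (int r = 0; r < d; ++r) {
    for (int t = 0; (t + 1) * L <= m; ++t) {
      const int start = r * m + t * L;
      for (int q = 0; q < L; ++q) pat[q] = s[start + q];
      int lo, hi;
      sa_range(s, sa, n, pat.data(), L, lo, hi);
      for (int q = lo; q < hi; ++q) {
        int pos = sa[q];
        if (pos % m != t * L) continue;  // must be aligned at the same block
        int r2 = pos / m;
        if (r2 == r) continue;
        oi.push_back(std::min(r, r2));
        oj.push_back(std::max(r, r2));
        ot.push_back(t);
      }
    }
  }
  IntegerMatrix out(oi.size(), 3);
  for (size_t r = 0; r < oi.size(); ++r) {
    out(r, 0) = oi[r]; out(r, 1) = oj[r]; out(r, 2) = ot[r];
  }
  return out;
}

// ---- dedup + verification --------------------------------------------------

// [[Rcpp::export]]
List cpp_verify_candidates(IntegerVector cand_i, IntegerVector cand_j,
                           IntegerVector lcp, IntegerMatrix sp,
                           IntegerVector isa, int n, int m, int d, int k) {
  std::vector<int64_t> keys(cand_i.size());
  for (int r = 0; r < cand_i.size(); ++r)
    keys[r] = (int64_t)cand_i[r] * d + cand_j[r];
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  std::vector<int> oi, oj, oh;
  for (int64_t key : keys) {
    int i = (int)(key / d), j = (int)(key % d);
    int h = hd_capped(lcp, sp, isa, n, m, i, j, k + 1);
    if (h <= k) { oi.push_back(i); oj.push_back(j); oh.push_back(h); }
  }
  return List::create(_["i"] = IntegerVector(oi.begin(), oi.end()),
                      _["j"] = IntegerVector(oj.begin(), oj.end()),
                      _["h"] = IntegerVector(oh.begin(), oh.end()),
                      _["n_verified"] = (int)keys.size());
}

// ---- naive all-pairs oracle ------------------------------------------------

// [[Rcpp::export]]
List cpp_naive_pairs(IntegerMatrix prof, int k) {
  const int d = prof.nrow(), m = prof.ncol();
  std::vector<int> oi, oj, oh;
  for (int i = 0; i < d; ++i)
    for (int j = i + 1; j < d; ++j) {
      int h = 0;
      for (int q = 0; q < m; ++q) {
        if (prof(i, q) != prof(j, q) && ++h > k) break;
      }
      if (h <= k) { oi.push_back(i); oj.push_back(j); oh.push_back(h); }
    }
  return List::create(_["i"] = IntegerVector(oi.begin(), oi.end()),
                      _["j"] = IntegerVector(oj.begin(), oj.end()),
                      _["h"] = IntegerVector(oh.begin(), oh.end()));
}

// ---- query: per-block SA search for an external profile --------------------

// [[Rcpp::export]]
List cpp_query(IntegerVector s, IntegerVector sa, IntegerMatrix prof,
               IntegerVector u, int k, int L) {
  const int n = s.size(), m = prof.ncol();
  std::vector<char> seen(prof.nrow(), 0);
  std::vector<int> rows;
  std::vector<int> pat(L);
  int n_candidates = 0;
  for (int t = 0; (t + 1) * L <= m; ++t) {
    for (int q = 0; q < L; ++q) pat[q] = u[t * L + q];
    int lo, hi;
    sa_range(s, sa, n, pat.data(), L, lo, hi);
    for (int q = lo; q < hi; ++q) {
      int pos = sa[q];
      if (pos % m != t * L) continue;
      ++n_candidates;
      int r = pos / m;
      if (!seen[r]) { seen[r] = 1; rows.push_back(r); }
    }
  }
  // verify by direct letter comparison against u
  std::vector<int> orow, oh;
  for (int r : rows) {
    int h = 0;
    for (int q = 0; q < m; ++q) {
      if (prof(r, q) != u[q] && ++h > k) break;
    }
    if (h <= k) { orow.push_back(r); oh.push_back(h); }
  }
  return List::create(_["row"] = IntegerVector(orow.begin(), orow.end()),
                      _["h"] = IntegerVector(oh.begin(), oh.end()),
                      _["n_candidates"] = n_candidates,
                      _["n_verified"] = (int)rows.size());
}
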