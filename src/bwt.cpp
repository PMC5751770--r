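#include <Rcpp.h>
#include "bwt.h"

#include <algorithm>
#include <stdexcept>

namespace fqarc {

// Suffix array by prefix doubling with two-pass counting sort (Manber-Myers),
// O(n log n); t must end in a unique minimal sentinel.
static void suffix_array(const std::vector<int>& t, std::vector<int>& sa) {
  const int n = static_cast<int>(t.size());
  sa.resize(n);
  std::vector<int> rnk(n), tmp(n), key2(n), sa2(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = t[i]; }
  for (int k = 1;; k <<= 1) {
    int maxr = 0;
    for (int i = 0; i < n; ++i) maxr = std::max(maxr, rnk[i]);
    maxr += 2;
    for (int i = 0; i < n; ++i) key2[i] = (i + k < n) ? rnk[i + k] + 1 : 0;
    std::vector<int> c(maxr, 0);
    for (int i = 0; i < n; ++i) ++c[key2[i]];
    for (int i = 1; i < maxr; ++i) c[i] += c[i - 1];
    for (int i = n - 1; i >= 0; --i) sa2[--c[key2[i]]] = i;
    c.assign(maxr, 0);
    for (int i = 0; i < n; ++i) ++c[rnk[i] + 1];
    for (int i = 1; i < maxr; ++i) c[i] += c[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--c[rnk[sa2[i]] + 1]] = sa2[i];
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      bool same = rnk[a] == rnk[b] && key2[a] == key2[b];
      tmp[b] = tmp[a] + (same ? 0 : 1);
    }
    rnk.swap(tmp);
    if (rnk[sa[n - 1]] == n - 1) break;
  }
}

void bwt_forward_raw(const uint8_t* s, size_t n,
                     std::vector<uint8_t>& out, size_t& primary) {
  if (n == 0) throw std::runtime_error("bwt: empty block");
  std::vector<int> t(n + 1);
  for (size_t i = 0; i < n; ++i) t[i] = static_cast<int>(s[i]) + 1;
  t[n] = 0;
  std::vector<int> sa;
  suffix_array(t, sa);
  out.clear();
  out.reserve(n);
  primary = 0;
  for (size_t i = 0; i <= n; ++i) {
    if (sa[i] == 0) {
      primary = i;   // row whose rotation ends in the sentinel
    } else {
      out.push_back(static_cast<uint8_t>(t[sa[i] - 1] - 1));
    }
  }
}

void bwt_inverse_raw(const uint8_t* b, size_t n, size_t primary,
                     std::vector<uint8_t>& out) {
  if (primary > n) throw std::runtime_error("bwt: primary index out of range");
  const size_t N = n + 1;
  // last column with the sentinel (symbol 0) re-inserted at `primary`
  std::vector<int> L(N);
  for (size_t i = 0, j = 0; i < N; ++i) {
    L[i] = (i == primary) ? 0 : static_cast<int>(b[j++]) + 1;
  }
  std::vector<size_t> count(258, 0);
  for (size_t i = 0; i < N; ++i) ++count[L[i] + 1];
  for (int c = 1; c < 258; ++c) count[c] += count[c - 1];
  std::vector<size_t> lf(N);
  std::vector<size_t> seen(257, 0);
  for (size_t i = 0; i < N; ++i) {
    lf[i] = count[L[i]] + seen[L[i]];
    ++seen[L[i]];
  }
  out.assign(n, 0);
  size_t row = 0;   // row 0 is the sentinel-only rotation
  for (size_t k = n; k-- > 0;) {
    if (L[row] == 0) throw std::runtime_error("bwt: corrupt block");
    out[k] = static_cast<uint8_t>(L[row] - 1);
    row = lf[row];
  }
}

} // namespace fqarc

// [[Rcpp::export]]
Rcpp::List cpp_bwt_forward(Rcpp::RawVector block) {
  std::vector<uint8_t> out;
  size_t primary = 0;
  fqarc::bwt_forward_raw(RAW(block), static_cast<size_t>(block.size()), out, primary);
  Rcpp::RawVector perm(out.size());
  std::copy(out.begin(), out.end(), RAW(perm));
  return Rcpp::List::create(Rcpp::Named("permuted") = perm,
                            Rcpp::Named("primary_index") = static_cast<double>(primary));
}

// [[Rcpp::export]]
Rcpp::RawVector cpp_bwt_inverse(Rcpp::RawVector permuted, double primary_index) {
  if (primary_index < 0) Rcpp::stop("bwt: primary index out of range");
  std::vector<uint8_t> out;
  fqarc::bwt_inverse_raw(RAW(permuted), static_cast<size_t>(permuted.size()),
                         static_cast<size_t>(primary_index), out);
  Rcpp::RawVector res(out.size());
  std::copy(out.begin(), out.end(), RAW(res));
  return res;
}
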