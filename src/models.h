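#ifndef FQARC_MODELS_H
#define FQARC_MODELS_H

#include <cstdint>
#include <vector>
#include <algorithm>
#include <stdexcept>

#include "arith.h"

namespace fqarc {

// Coder-facing probability grid: 14-bit totals leave headroom below the
// coder's 16-bit frequency ceiling; every symbol keeps at least 1 count so
// any byte stays decodable.
constexpr int      GRID_BITS   = 14;
constexpr uint32_t GRID        = 1u << GRID_BITS;
constexpr uint32_t RESCALE_CAP = 256;   // context total at which counts halve

// Symbols are 0..A-1; contexts additionally use the out-of-band boundary id A
// (start-of-read padding). ctx[0] is the immediately preceding symbol.
struct Model {
  virtual ~Model() {}
  virtual void dist(const int* ctx, int maxk, double* out) = 0;
  virtual void update(const int* ctx, int maxk, int sym) = 0;
};

struct Order0Model : Model {
  int A;
  std::vector<uint32_t> cnt;
  uint32_t tot = 0;
  explicit Order0Model(int A_) : A(A_), cnt(A_, 0) {}
  void dist(const int*, int, double* out) override {
    double denom = static_cast<double>(tot) + A;
    for (int i = 0; i < A; ++i) out[i] = (cnt[i] + 1.0) / denom;
  }
  void update(const int*, int, int s) override {
    ++cnt[s]; ++tot;
    if (tot >= RESCALE_CAP) {
      tot = 0;
      for (auto& c : cnt) { c >>= 1; tot += c; }
    }
  }
};

// Dense order-k table; used for small k where (A+1)^k contexts fit in memory.
struct DirectOrderK : Model {
  int A, k;
  size_t nctx;
  std::vector<uint16_t> cnt;
  std::vector<uint32_t> tot;
  DirectOrderK(int A_, int k_) : A(A_), k(k_) {
    nctx = 1;
    for (int i = 0; i < k; ++i) nctx *= static_cast<size_t>(A + 1);
    cnt.assign(nctx * static_cast<size_t>(A), 0);
    tot.assign(nctx, 0);
  }
  size_t idx(const int* ctx) const {
    size_t v = 0;
    for (int i = 0; i < k; ++i) v = v * (A + 1) + ctx[i];
    return v;
  }
  void dist(const int* ctx, int, double* out) override {
    size_t c = idx(ctx);
    const uint16_t* row = cnt.data() + c * A;
    double denom = static_cast<double>(tot[c]) + A;
    for (int i = 0; i < A; ++i) out[i] = (row[i] + 1.0) / denom;
  }
  void update(const int* ctx, int, int s) override {
    size_t c = idx(ctx);
    uint16_t* row = cnt.data() + c * A;
    ++row[s]; ++tot[c];
    if (tot[c] >= RESCALE_CAP) {
      uint32_t t = 0;
      for (int i = 0; i < A; ++i) { row[i] >>= 1; t += row[i]; }
      tot[c] = t;
    }
  }
};

// High orders (4, 6) live in a fixed-size hashed table with verification
// tags; a colliding context simply sees an empty (uniform) row, so the mixer
// falls back on the lower orders until the bucket is re-claimed on update.
struct HashedOrderK : Model {
  int A, k, bits;
  size_t mask;
  std::vector<uint32_t> tag;
  std::vector<uint16_t> cnt;
  std::vector<uint32_t> tot;
  HashedOrderK(int A_, int k_, int bits_) : A(A_), k(k_), bits(bits_) {
    size_t nb = static_cast<size_t>(1) << bits;
    mask = nb - 1;
    tag.assign(nb, 0);
    cnt.assign(nb * static_cast<size_t>(A), 0);
    tot.assign(nb, 0);
  }
  size_t bucket(const int* ctx, uint32_t& tg) const {
    uint64_t h = 1469598103934665603ull;  // FNV-1a over the context window
    for (int i = 0; i < k; ++i) {
      h ^= static_cast<uint64_t>(ctx[i]) + 1;
      h *= 1099511628211ull;
    }
    tg = static_cast<uint32_t>(h >> 40) | 1u;
    return static_cast<size_t>(h & mask);
  }
  void dist(const int* ctx, int, double* out) override {
    uint32_t tg;
    size_t b = bucket(ctx, tg);
    if (tag[b] != tg || tot[b] == 0) {
      double u = 1.0 / A;
      for (int i = 0; i < A; ++i) out[i] = u;
      return;
    }
    const uint16_t* row = cnt.data() + b * A;
    double denom = static_cast<double>(tot[b]) + A;
    for (int i = 0; i < A; ++i) out[i] = (row[i] + 1.0) / denom;
  }
  void update(const int* ctx, int, int s) override {
    uint32_t tg;
    size_t b = bucket(ctx, tg);
    uint16_t* row = cnt.data() + b * A;
    if (tag[b] != tg) {
      tag[b] = tg;
      std::fill(row, row + A, 0);
      tot[b] = 0;
    }
    ++row[s]; ++tot[b];
    if (tot[b] >= RESCALE_CAP) {
      uint32_t t = 0;
      for (int i = 0; i < A; ++i) { row[i] >>= 1; t += row[i]; }
      tot[b] = t;
    }
  }
};

// Matching model: if the most recent `minm` symbols occurred earlier in the
// block, propose the symbol that followed that occurrence with mass 1-delta.
struct MatchModel : Model {
  int A, minm;
  double delta;
  std::vector<int> hist;
  std::vector<int64_t> last;   // context hash -> position following it
  size_t mask;
  int pred = -1;
  MatchModel(int A_, int minm_, double delta_, int bits = 20)
      : A(A_), minm(minm_), delta(delta_) {
    size_t nb = static_cast<size_t>(1) << bits;
    mask = nb - 1;
    last.assign(nb, -1);
  }
  void dist(const int*, int, double* out) override {
    if (pred < 0 || A == 1) {
      double u = 1.0 / A;
      for (int i = 0; i < A; ++i) out[i] = u;
      return;
    }
    double rest = delta / (A - 1);
    for (int i = 0; i < A; ++i) out[i] = rest;
    out[pred] = 1.0 - delta;
  }
  void update(const int*, int, int s) override {
    hist.push_back(s);
    int64_t n = static_cast<int64_t>(hist.size());
    pred = -1;
    if (n < minm) return;
    uint64_t h = 1469598103934665603ull;
    for (int i = 0; i < minm; ++i) {
      h ^= static_cast<uint64_t>(hist[n - minm + i]) + 1;
      h *= 1099511628211ull;
    }
    size_t b = static_cast<size_t>(h & mask);
    int64_t p = last[b];
    if (p >= minm && p < n) {
      bool ok = true;   // verify against hash collisions
      for (int i = 0; i < minm && ok; ++i)
        ok = hist[p - minm + i] == hist[n - minm + i];
      if (ok) pred = hist[p];
    }
    last[b] = n;
  }
};

// Adaptive convex mixing of the sub-models' predictions, quantised onto the
// coder grid. Encoder and decoder drive this identically symbol by symbol.
struct MixCoder {
  int A = 0, maxk = 0, nl_sym = -1;
  bool reset_reads = false;
  std::vector<Model*> models;
  std::vector<double> w;
  std::vector<int> ctx;
  std::vector<std::vector<double>> dms;
  std::vector<double> mixed;
  std::vector<uint32_t> freq, cum;

  void init(int A_, std::vector<Model*> ms, int maxk_, int nl, bool reset) {
    A = A_; models = ms; maxk = maxk_; nl_sym = nl; reset_reads = reset;
    size_t M = models.size();
    w.assign(M, 1.0 / M);
    ctx.assign(std::max(maxk, 1), A);     // boundary padding
    dms.assign(M, std::vector<double>(A));
    mixed.assign(A, 0.0);
    freq.assign(A, 0);
    cum.assign(A + 1, 0);
  }

  void compute() {
    size_t M = models.size();
    for (size_t m = 0; m < M; ++m) models[m]->dist(ctx.data(), maxk, dms[m].data());
    for (int i = 0; i < A; ++i) mixed[i] = 0.0;
    for (size_t m = 0; m < M; ++m) {
      double wm = w[m];
      const double* d = dms[m].data();
      for (int i = 0; i < A; ++i) mixed[i] += wm * d[i];
    }
    uint32_t budget = GRID - static_cast<uint32_t>(A);
    int64_t s = 0;
    for (int i = 0; i < A; ++i) {
      uint32_t f = static_cast<uint32_t>(mixed[i] * budget) + 1;
      freq[i] = f;
      s += f;
    }
    int64_t resid = static_cast<int64_t>(GRID) - s;
    int am = 0;
    for (int i = 1; i < A; ++i) if (freq[i] > freq[am]) am = i;
    if (resid >= 0) {
      freq[am] += static_cast<uint32_t>(resid);
    } else {
      // floating-point edge: trim the largest entry (keeps every entry >= 1)
      freq[am] -= static_cast<uint32_t>(std::min<int64_t>(-resid, freq[am] - 1));
    }
    cum[0] = 0;
    for (int i = 0; i < A; ++i) cum[i + 1] = cum[i] + freq[i];
  }

  void advance(int s) {
    size_t M = models.size();
    double wsum = 0.0;
    for (size_t m = 0; m < M; ++m) {
      w[m] *= std::max(dms[m][s], 1e-12);
      wsum += w[m];
    }
    for (size_t m = 0; m < M; ++m) w[m] /= wsum;
    double s2 = 0.0;
    for (size_t m = 0; m < M; ++m) {
      if (w[m] < 0.01) w[m] = 0.01;   // weight floor keeps every model alive
      s2 += w[m];
    }
    for (size_t m = 0; m < M; ++m) w[m] /= s2;
    for (size_t m = 0; m < M; ++m) models[m]->update(ctx.data(), maxk, s);
    for (int i = maxk - 1; i > 0; --i) ctx[i] = ctx[i - 1];
    if (maxk > 0) ctx[0] = s;
    if (reset_reads && s == nl_sym) std::fill(ctx.begin(), ctx.end(), A);
  }
};

inline std::vector<uint8_t> mix_encode(const std::vector<int>& syms, MixCoder& mc) {
  ArithEncoder enc;
  for (int s : syms) {
    mc.compute();
    enc.encode(mc.cum[s], mc.cum[s + 1], GRID);
    mc.advance(s);
  }
  return enc.finish();
}

inline std::vector<int> mix_decode(const uint8_t* p, size_t n, size_t count, MixCoder& mc) {
  ArithDecoder dec(p, n);
  std::vector<int> out(count);
  for (size_t i = 0; i < count; ++i) {
    mc.compute();
    uint32_t t = dec.decode_target(GRID);
    int s = static_cast<int>(std::upper_bound(mc.cum.begin(), mc.cum.end(), t) -
                             mc.cum.begin()) - 1;
    if (s < 0 || s >= mc.A) throw std::runtime_error("decoder: symbol out of range");
    dec.decode_update(mc.cum[s], mc.cum[s + 1], GRID);
    out[i] = s;
    mc.advance(s);
  }
  return out;
}

} // namespace fqarc

#endif
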