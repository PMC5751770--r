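#include <Rcpp.h>
#include "arith.h"
#include "models.h"
#include "bwt.h"

#include <memory>

using namespace fqarc;

namespace {

// ---- alphabet helpers -----------------------------------------------------

struct Alphabet {
  int A = 0;
  int map[256];
  std::vector<uint8_t> syms;
  void build(const uint8_t* p, size_t n) {
    bool seen[256] = {false};
    for (size_t i = 0; i < n; ++i) seen[p[i]] = true;
    std::fill(map, map + 256, -1);
    for (int b = 0; b < 256; ++b) {
      if (seen[b]) { map[b] = A++; syms.push_back(static_cast<uint8_t>(b)); }
    }
  }
  void from_syms(const std::vector<uint8_t>& s) {
    syms = s;
    A = static_cast<int>(s.size());
    std::fill(map, map + 256, -1);
    for (int i = 0; i < A; ++i) map[syms[i]] = i;
  }
};

void put_alphabet(std::vector<uint8_t>& out, const Alphabet& al) {
  put_varint(out, static_cast<uint64_t>(al.A));
  out.insert(out.end(), al.syms.begin(), al.syms.end());
}

Alphabet get_alphabet(const uint8_t* p, size_t n, size_t& pos) {
  uint64_t A = get_varint(p, n, pos);
  if (A > 256 || pos + A > n) throw std::runtime_error("codec: corrupt alphabet");
  Alphabet al;
  al.from_syms(std::vector<uint8_t>(p + pos, p + pos + A));
  pos += A;
  return al;
}

std::vector<int> map_syms(const uint8_t* p, size_t n, const Alphabet& al) {
  std::vector<int> s(n);
  for (size_t i = 0; i < n; ++i) {
    int m = al.map[p[i]];
    if (m < 0) throw std::runtime_error("codec: byte outside declared alphabet");
    s[i] = m;
  }
  return s;
}

// Model stacks per stream type. Orders follow the per-stream designs:
// bases 0+1 over the BWT output, qualities 1/2/4/6 + matching model,
// general fallback 0+1 without transform.
struct Stack {
  std::vector<std::unique_ptr<Model>> own;
  std::vector<Model*> ptrs() {
    std::vector<Model*> p;
    for (auto& m : own) p.push_back(m.get());
    return p;
  }
};

Stack make_low_order(int A) {
  Stack st;
  st.own.emplace_back(new Order0Model(A));
  st.own.emplace_back(new DirectOrderK(A, 1));
  return st;
}

Stack make_quality(int A, int hash_bits) {
  Stack st;
  st.own.emplace_back(new DirectOrderK(A, 1));
  st.own.emplace_back(new DirectOrderK(A, 2));
  st.own.emplace_back(new HashedOrderK(A, 4, hash_bits));
  st.own.emplace_back(new HashedOrderK(A, 6, hash_bits));
  st.own.emplace_back(new MatchModel(A, 6, 0.1));
  return st;
}

Stack make_order0(int A) {
  Stack st;
  st.own.emplace_back(new Order0Model(A));
  return st;
}

enum StackKind { LOW_ORDER, QUALITY, ORDER0 };

Stack make_stack(StackKind kind, int A, int hash_bits) {
  switch (kind) {
    case QUALITY: return make_quality(A, hash_bits);
    case ORDER0:  return make_order0(A);
    default:      return make_low_order(A);
  }
}

int stack_maxk(StackKind kind) { return kind == QUALITY ? 6 : (kind == ORDER0 ? 0 : 1); }

Rcpp::RawVector to_raw(const std::vector<uint8_t>& v) {
  Rcpp::RawVector r(v.size());
  std::copy(v.begin(), v.end(), RAW(r));
  return r;
}

// Shared body: [varint n][alphabet][coded payload]; QUALITY resets order-k
// contexts at read boundaries ('\n').
Rcpp::RawVector compress_plain(Rcpp::RawVector data, StackKind kind, int hash_bits) {
  size_t n = static_cast<size_t>(data.size());
  std::vector<uint8_t> out;
  put_varint(out, n);
  if (n == 0) return to_raw(out);
  Alphabet al;
  al.build(RAW(data), n);
  put_alphabet(out, al);
  std::vector<int> syms = map_syms(RAW(data), n, al);
  Stack st = make_stack(kind, al.A, hash_bits);
  MixCoder mc;
  mc.init(al.A, st.ptrs(), stack_maxk(kind), al.map['\n'], kind == QUALITY);
  std::vector<uint8_t> body = mix_encode(syms, mc);
  out.insert(out.end(), body.begin(), body.end());
  return to_raw(out);
}

Rcpp::RawVector decompress_plain(Rcpp::RawVector payload, StackKind kind, int hash_bits) {
  const uint8_t* p = RAW(payload);
  size_t n = static_cast<size_t>(payload.size());
  size_t pos = 0;
  uint64_t len = get_varint(p, n, pos);
  if (len == 0) return Rcpp::RawVector(0);
  Alphabet al = get_alphabet(p, n, pos);
  Stack st = make_stack(kind, al.A, hash_bits);
  MixCoder mc;
  mc.init(al.A, st.ptrs(), stack_maxk(kind), al.map['\n'], kind == QUALITY);
  std::vector<int> syms = mix_decode(p + pos, n - pos, static_cast<size_t>(len), mc);
  Rcpp::RawVector out(len);
  for (size_t i = 0; i < len; ++i) out[i] = al.syms[syms[i]];
  return out;
}

constexpr size_t BWT_SEG = static_cast<size_t>(1) << 22;  // 4 MiB segments

} // namespace

// ---- base-sequence codec: BWT + mixed order-0/1 ---------------------------

// [[Rcpp::export]]
Rcpp::RawVector cpp_compress_bases(Rcpp::RawVector data) {
  size_t n = static_cast<size_t>(data.size());
  std::vector<uint8_t> out;
  put_varint(out, n);
  if (n == 0) return to_raw(out);
  const uint8_t* p = RAW(data);
  size_t nseg = (n + BWT_SEG - 1) / BWT_SEG;
  put_varint(out, nseg);
  std::vector<uint8_t> transformed;
  transformed.reserve(n);
  for (size_t s = 0; s < nseg; ++s) {
    size_t off = s * BWT_SEG;
    size_t len = std::min(BWT_SEG, n - off);
    std::vector<uint8_t> perm;
    size_t primary = 0;
    bwt_forward_raw(p + off, len, perm, primary);
    put_varint(out, len);
    put_varint(out, primary);
    transformed.insert(transformed.end(), perm.begin(), perm.end());
  }
  Alphabet al;
  al.build(transformed.data(), transformed.size());
  put_alphabet(out, al);
  std::vector<int> syms = map_syms(transformed.data(), transformed.size(), al);
  Stack st = make_low_order(al.A);
  MixCoder mc;
  mc.init(al.A, st.ptrs(), 1, -1, false);
  std::vector<uint8_t> body = mix_encode(syms, mc);
  out.insert(out.end(), body.begin(), body.end());
  return to_raw(out);
}

// [[Rcpp::export]]
Rcpp::RawVector cpp_decompress_bases(Rcpp::RawVector payload) {
  const uint8_t* p = RAW(payload);
  size_t n = static_cast<size_t>(payload.size());
  size_t pos = 0;
  uint64_t total = get_varint(p, n, pos);
  if (total == 0) return Rcpp::RawVector(0);
  uint64_t nseg = get_varint(p, n, pos);
  std::vector<std::pair<uint64_t, uint64_t>> segs;
  uint64_t sum = 0;
  for (uint64_t s = 0; s < nseg; ++s) {
    uint64_t len = get_varint(p, n, pos);
    uint64_t primary = get_varint(p, n, pos);
    segs.emplace_back(len, primary);
    sum += len;
  }
  if (sum != total) throw std::runtime_error("bases codec: corrupt segment table");
  Alphabet al = get_alphabet(p, n, pos);
  Stack st = make_low_order(al.A);
  MixCoder mc;
  mc.init(al.A, st.ptrs(), 1, -1, false);
  std::vector<int> syms = mix_decode(p + pos, n - pos, static_cast<size_t>(total), mc);
  std::vector<uint8_t> transformed(total);
  for (uint64_t i = 0; i < total; ++i) transformed[i] = al.syms[syms[i]];
  Rcpp::RawVector out(total);
  size_t off = 0;
  for (auto& sg : segs) {
    std::vector<uint8_t> seg;
    bwt_inverse_raw(transformed.data() + off, static_cast<size_t>(sg.first),
                    static_cast<size_t>(sg.second), seg);
    std::copy(seg.begin(), seg.end(), RAW(out) + off);
    off += static_cast<size_t>(sg.first);
  }
  return out;
}

// ---- quality codec: orders 1/2/4/6 + matching model, no transform ---------

// [[Rcpp::export]]
Rcpp::RawVector cpp_compress_quality(Rcpp::RawVector data, int hash_bits = 18) {
  return compress_plain(data, QUALITY, hash_bits);
}

// [[Rcpp::export]]
Rcpp::RawVector cpp_decompress_quality(Rcpp::RawVector payload, int hash_bits = 18) {
  return decompress_plain(payload, QUALITY, hash_bits);
}

// ---- general low-order codec (metadata residuals, aux, non-FASTQ) ---------

// [[Rcpp::export]]
Rcpp::RawVector cpp_compress_general(Rcpp::RawVector data) {
  return compress_plain(data, LOW_ORDER, 18);
}

// [[Rcpp::export]]
Rcpp::RawVector cpp_decompress_general(Rcpp::RawVector payload) {
  return decompress_plain(payload, LOW_ORDER, 18);
}

// ---- order-0-only baseline (benchmark comparisons) ------------------------

// [[Rcpp::export]]
Rcpp::RawVector cpp_compress_order0(Rcpp::RawVector data) {
  return compress_plain(data, ORDER0, 18);
}

// [[Rcpp::export]]
Rcpp::RawVector cpp_decompress_order0(Rcpp::RawVector payload) {
  return decompress_plain(payload, ORDER0, 18);
}

// ---- raw coder entry points ------------------------------------------------

static void check_freqs(Rcpp::IntegerVector freqs, std::vector<uint32_t>& cum) {
  uint64_t tot = 0;
  cum.assign(freqs.size() + 1, 0);
  for (int i = 0; i < freqs.size(); ++i) {
    if (freqs[i] < 1) Rcpp::stop("coder: every coded symbol needs count >= 1");
    tot += static_cast<uint64_t>(freqs[i]);
    cum[i + 1] = static_cast<uint32_t>(tot);
  }
  if (tot > AC_MAX_TOTAL) Rcpp::stop("coder: frequency total exceeds 2^16");
}

// Static model: one fixed integer frequency table for the whole stream.
// [[Rcpp::export]]
Rcpp::RawVector cpp_ac_encode_static(Rcpp::IntegerVector syms, Rcpp::IntegerVector freqs) {
  std::vector<uint32_t> cum;
  check_freqs(freqs, cum);
  uint32_t total = cum.back();
  ArithEncoder enc;
  for (int i = 0; i < syms.size(); ++i) {
    int s = syms[i];
    if (s < 0 || s >= freqs.size()) Rcpp::stop("coder: symbol outside alphabet");
    enc.encode(cum[s], cum[s + 1], total);
  }
  return to_raw(enc.finish());
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_ac_decode_static(Rcpp::RawVector payload,
                                         Rcpp::IntegerVector freqs, double count) {
  std::vector<uint32_t> cum;
  check_freqs(freqs, cum);
  uint32_t total = cum.back();
  size_t cnt = static_cast<size_t>(count);
  ArithDecoder dec(RAW(payload), static_cast<size_t>(payload.size()));
  Rcpp::IntegerVector out(cnt);
  for (size_t i = 0; i < cnt; ++i) {
    uint32_t t = dec.decode_target(total);
    int s = static_cast<int>(std::upper_bound(cum.begin(), cum.end(), t) - cum.begin()) - 1;
    dec.decode_update(cum[s], cum[s + 1], total);
    out[i] = s;
  }
  return out;
}

// Adaptive order-0 with add-one counts used directly as the frequency table.
// [[Rcpp::export]]
Rcpp::RawVector cpp_ac_encode_order0(Rcpp::IntegerVector syms, int alphabet_size) {
  Order0Model m(alphabet_size);
  std::vector<uint32_t> cum(alphabet_size + 1);
  ArithEncoder enc;
  for (int i = 0; i < syms.size(); ++i) {
    int s = syms[i];
    if (s < 0 || s >= alphabet_size) Rcpp::stop("coder: symbol outside alphabet");
    cum[0] = 0;
    for (int j = 0; j < alphabet_size; ++j) cum[j + 1] = cum[j] + m.cnt[j] + 1;
    enc.encode(cum[s], cum[s + 1], cum[alphabet_size]);
    m.update(nullptr, 0, s);
  }
  return to_raw(enc.finish());
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_ac_decode_order0(Rcpp::RawVector payload, int alphabet_size,
                                         double count) {
  Order0Model m(alphabet_size);
  std::vector<uint32_t> cum(alphabet_size + 1);
  size_t cnt = static_cast<size_t>(count);
  ArithDecoder dec(RAW(payload), static_cast<size_t>(payload.size()));
  Rcpp::IntegerVector out(cnt);
  for (size_t i = 0; i < cnt; ++i) {
    cum[0] = 0;
    for (int j = 0; j < alphabet_size; ++j) cum[j + 1] = cum[j] + m.cnt[j] + 1;
    uint32_t t = dec.decode_target(cum[alphabet_size]);
    int s = static_cast<int>(std::upper_bound(cum.begin(), cum.end(), t) - cum.begin()) - 1;
    dec.decode_update(cum[s], cum[s + 1], cum[alphabet_size]);
    out[i] = s;
    m.update(nullptr, 0, s);
  }
  return out;
}

// Callback-driven coder: `driver` maps the already-coded prefix (1-based
// symbol ids) to an integer frequency table. Intended for small inputs and
// cross-checks; the production codecs keep the model on the C++ side.
// [[Rcpp::export]]
Rcpp::RawVector cpp_ac_encode_driver(Rcpp::IntegerVector syms, Rcpp::Function driver) {
  ArithEncoder enc;
  std::vector<int> hist;
  for (int i = 0; i < syms.size(); ++i) {
    Rcpp::IntegerVector h(hist.begin(), hist.end());
    Rcpp::IntegerVector freqs = driver(h);
    std::vector<uint32_t> cum;
    check_freqs(freqs, cum);
    int s = syms[i];
    if (s < 0 || s >= freqs.size()) Rcpp::stop("coder: symbol outside driver table");
    enc.encode(cum[s], cum[s + 1], cum.back());
    hist.push_back(s + 1);
  }
  return to_raw(enc.finish());
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_ac_decode_driver(Rcpp::RawVector payload, Rcpp::Function driver,
                                         double count) {
  size_t cnt = static_cast<size_t>(count);
  ArithDecoder dec(RAW(payload), static_cast<size_t>(payload.size()));
  std::vector<int> hist;
  Rcpp::IntegerVector out(cnt);
  for (size_t i = 0; i < cnt; ++i) {
    Rcpp::IntegerVector h(hist.begin(), hist.end());
    Rcpp::IntegerVector freqs = driver(h);
    std::vector<uint32_t> cum;
    check_freqs(freqs, cum);
    uint32_t t = dec.decode_target(cum.back());
    int s = static_cast<int>(std::upper_bound(cum.begin(), cum.end(), t) - cum.begin()) - 1;
    dec.decode_update(cum[s], cum[s + 1], cum.back());
    out[i] = s;
    hist.push_back(s + 1);
  }
  return out;
}
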