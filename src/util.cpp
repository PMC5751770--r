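#include <Rcpp.h>
#include <cstdint>
#include <vector>

// ---- CRC-32 (IEEE polynomial, reflected) ----------------------------------

static uint32_t crc_table[256];
static bool crc_init = false;

static void init_crc() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[i] = c;
  }
  crc_init = true;
}

// [[Rcpp::export]]
double cpp_crc32(Rcpp::RawVector data) {
  if (!crc_init) init_crc();
  uint32_t c = 0xFFFFFFFFu;
  const uint8_t* p = RAW(data);
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = crc_table[(c ^ p[i]) & 0xFF] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// ---- deterministic Markov text generator ----------------------------------

// xorshift64* PRNG; self-contained so fixture output is identical across
// platforms and R versions.
static inline uint64_t xs_next(uint64_t& s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ull;
}

static inline double xs_unif(uint64_t& s) {
  return (xs_next(s) >> 11) * (1.0 / 9007199254740992.0);
}

// Order-k Markov chain over `alphabet` with transition sharpness alpha:
// P(next | ctx) = alpha/A + (1-alpha) * [next == preferred(ctx)].
// For order 1 the preferred successor is the previous symbol itself (alpha
// near 0 yields long runs); for higher orders it is a hash of the context.
// [[Rcpp::export]]
Rcpp::RawVector cpp_markov_bytes(double n, int order, double alpha,
                                 Rcpp::RawVector alphabet, double seed) {
  const int A = static_cast<int>(alphabet.size());
  if (A < 1) Rcpp::stop("alphabet must be non-empty");
  const size_t len = static_cast<size_t>(n);
  uint64_t st = static_cast<uint64_t>(seed) * 6364136223846793005ull + 1442695040888963407ull;
  for (int i = 0; i < 8; ++i) xs_next(st);
  std::vector<int> ctx(order > 0 ? order : 1, 0);
  Rcpp::RawVector out(len);
  for (size_t i = 0; i < len; ++i) {
    int pref;
    if (order <= 0) {
      pref = 0;
    } else if (order == 1) {
      pref = ctx[0];
    } else {
      uint64_t h = 1469598103934665603ull;
      for (int j = 0; j < order; ++j) {
        h ^= static_cast<uint64_t>(ctx[j]) + 1;
        h *= 1099511628211ull;
      }
      pref = static_cast<int>(h % static_cast<uint64_t>(A));
    }
    double u = xs_unif(st);
    int sym;
    if (u < alpha) {
      sym = static_cast<int>(xs_unif(st) * A);
      if (sym >= A) sym = A - 1;
    } else {
      sym = pref;
    }
    out[i] = alphabet[sym];
    for (int j = (order > 0 ? order : 1) - 1; j > 0; --j) ctx[j] = ctx[j - 1];
    ctx[0] = sym;
  }
  return out;
}
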