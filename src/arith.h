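#ifndef FQARC_ARITH_H
#define FQARC_ARITH_H

#include <cstdint>
#include <vector>
#include <stdexcept>

namespace fqarc {

// Binary arithmetic coder: 32-bit low/high registers, carry handling via
// pending-bit counting, 16-bit maximum frequency-table total so that
// range/total never underflows after renormalisation.
constexpr uint32_t AC_TOP    = 0xFFFFFFFFu;
constexpr uint32_t AC_HALF   = 0x80000000u;
constexpr uint32_t AC_QTR    = 0x40000000u;
constexpr uint32_t AC_3QTR   = 0xC0000000u;
constexpr uint32_t AC_MAX_TOTAL = 1u << 16;

class BitWriter {
public:
  std::vector<uint8_t> bytes;
  void put(int b) {
    cur_ = static_cast<uint8_t>((cur_ << 1) | (b & 1));
    if (++nb_ == 8) { bytes.push_back(cur_); cur_ = 0; nb_ = 0; }
  }
  void pad() { while (nb_ != 0) put(0); }
private:
  uint8_t cur_ = 0;
  int nb_ = 0;
};

class ArithEncoder {
public:
  void encode(uint32_t cumlo, uint32_t cumhi, uint32_t total) {
    if (total == 0 || total > AC_MAX_TOTAL || cumhi <= cumlo || cumhi > total)
      throw std::runtime_error("arithmetic coder: invalid frequency interval");
    uint64_t range = static_cast<uint64_t>(high_) - low_ + 1;
    high_ = low_ + static_cast<uint32_t>(range * cumhi / total) - 1;
    low_  = low_ + static_cast<uint32_t>(range * cumlo / total);
    for (;;) {
      if (high_ < AC_HALF) {
        emit(0);
      } else if (low_ >= AC_HALF) {
        emit(1); low_ -= AC_HALF; high_ -= AC_HALF;
      } else if (low_ >= AC_QTR && high_ < AC_3QTR) {
        ++pending_; low_ -= AC_QTR; high_ -= AC_QTR;
      } else {
        break;
      }
      low_ <<= 1;
      high_ = (high_ << 1) | 1;
    }
  }

  // Disambiguate the final interval, pad to a byte, then a 2-byte tail guard
  // so the decoder's 32-bit preload never starves on short payloads.
  std::vector<uint8_t> finish() {
    ++pending_;
    if (low_ < AC_QTR) emit(0); else emit(1);
    out_.pad();
    out_.bytes.push_back(0);
    out_.bytes.push_back(0);
    return out_.bytes;
  }

private:
  void emit(int b) {
    out_.put(b);
    while (pending_ > 0) { out_.put(!b); --pending_; }
  }
  uint32_t low_ = 0, high_ = AC_TOP;
  uint64_t pending_ = 0;
  BitWriter out_;
};

class ArithDecoder {
public:
  ArithDecoder(const uint8_t* buf, size_t n) : buf_(buf), n_(n) {
    for (int i = 0; i < 32; ++i) code_ = (code_ << 1) | get_bit();
  }
  uint32_t decode_target(uint32_t total) {
    uint64_t range = static_cast<uint64_t>(high_) - low_ + 1;
    return static_cast<uint32_t>(
        ((static_cast<uint64_t>(code_ - low_) + 1) * total - 1) / range);
  }
  void decode_update(uint32_t cumlo, uint32_t cumhi, uint32_t total) {
    uint64_t range = static_cast<uint64_t>(high_) - low_ + 1;
    high_ = low_ + static_cast<uint32_t>(range * cumhi / total) - 1;
    low_  = low_ + static_cast<uint32_t>(range * cumlo / total);
    for (;;) {
      if (high_ < AC_HALF) {
        // nothing
      } else if (low_ >= AC_HALF) {
        low_ -= AC_HALF; high_ -= AC_HALF; code_ -= AC_HALF;
      } else if (low_ >= AC_QTR && high_ < AC_3QTR) {
        low_ -= AC_QTR; high_ -= AC_QTR; code_ -= AC_QTR;
      } else {
        break;
      }
      low_ <<= 1;
      high_ = (high_ << 1) | 1;
      code_ = (code_ << 1) | get_bit();
    }
  }

private:
  int get_bit() {
    if (pos_ >= n_) {
      // the encoder flush guarantees at most ~32 bits of slack; anything more
      // means the payload was cut short
      if (++overrun_ > 32) throw std::runtime_error("arithmetic coder: payload exhausted");
      return 0;
    }
    int b = (buf_[pos_] >> (7 - bit_)) & 1;
    if (++bit_ == 8) { bit_ = 0; ++pos_; }
    return b;
  }
  const uint8_t* buf_;
  size_t n_, pos_ = 0, overrun_ = 0;
  int bit_ = 0;
  uint32_t low_ = 0, high_ = AC_TOP, code_ = 0;
};

inline void put_varint(std::vector<uint8_t>& v, uint64_t x) {
  for (;;) {
    uint8_t b = static_cast<uint8_t>(x & 0x7F);
    x >>= 7;
    if (x != 0) { v.push_back(b | 0x80); } else { v.push_back(b); break; }
  }
}

inline uint64_t get_varint(const uint8_t* p, size_t n, size_t& pos) {
  uint64_t x = 0;
  int shift = 0;
  for (;;) {
    if (pos >= n) throw std::runtime_error("varint: truncated");
    uint8_t b = p[pos++];
    x |= static_cast<uint64_t>(b & 0x7F) << shift;
    if ((b & 0x80) == 0) break;
    shift += 7;
    if (shift > 63) throw std::runtime_error("varint: overflow");
  }
  return x;
}

} // namespace fqarc

#endif
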