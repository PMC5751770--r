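#ifndef FQARC_BWT_H
#define FQARC_BWT_H

#include <cstdint>
#include <cstddef>
#include <vector>

namespace fqarc {

// Burrows-Wheeler transform of a non-empty block with an implicit sentinel
// (smaller than every byte) appended; the sentinel is stripped from the
// output and its row recorded as `primary`.
void bwt_forward_raw(const uint8_t* s, size_t n,
                     std::vector<uint8_t>& out, size_t& primary);
void bwt_inverse_raw(const uint8_t* b, size_t n, size_t primary,
                     std::vector<uint8_t>& out);

} // namespace fqarc

#endif
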