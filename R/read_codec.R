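# Base-sequence codec. A block of read lines is joined into one byte stream
# (newline-terminated, so variable-length reads need no separate length
# stream), Burrows-Wheeler transformed, and coded with an adaptive mix of an
# order-0 and an order-1 model over the block's declared byte alphabet.
# Arbitrary bytes (N, IUPAC codes) are handled by the byte alphabet itself;
# there is no 2-bit packing special case to escape from.

#' Compress a block of base-sequence lines
#'
#' @param base_lines Character vector of read sequences (one per record).
#' @param params Codec parameters, see [codec_params()].
#' @param first_record 0-based index of the first record in the block.
#' @return An `fq_block` with `stream_type = "bases"`.
#' @export
compress_reads_block <- function(base_lines, params = codec_params(),
                                 first_record = 0L) {
  bytes <- join_lines(base_lines)
  payload <- cpp_compress_bases(bytes)
  new_block("bases", 1L, payload, bytes, first_record, length(base_lines))
}

#' Decompress a base-sequence block
#'
#' @param block An `fq_block` produced by [compress_reads_block()].
#' @return The original character vector of read sequences.
#' @export
decompress_reads_block <- function(block) {
  if (block$stream_type != "bases") {
    fq_structure_error("decompress_reads_block: not a bases block")
  }
  bytes <- decode_payload(block, cpp_decompress_bases)
  split_joined(bytes, block$n_records)
}

#' Order-0-only baseline compressor
#'
#' Codes a byte stream with a single adaptive order-0 model and no
#' transform. Used as the comparison baseline when measuring what the BWT
#' and the higher-order models buy.
#'
#' @param bytes Raw vector (or character scalar).
#' @return Raw compressed payload; invert with [baseline_order0_decompress()].
#' @export
baseline_order0_compress <- function(bytes) {
  if (is.character(bytes)) bytes <- charToRaw(bytes)
  cpp_compress_order0(bytes)
}

#' @rdname baseline_order0_compress
#' @param payload Raw payload from [baseline_order0_compress()].
#' @export
baseline_order0_decompress <- function(payload) {
  cpp_decompress_order0(payload)
}
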