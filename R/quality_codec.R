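# Quality-score codec. No transform is applied: quality strings go straight
# into an expanding prediction mix of order-1, order-2, order-4 and order-6
# context models plus a matching model (minimum match 6, proposing the
# symbol that followed the last occurrence of the current context with mass
# 0.9). Order-k contexts reset at read boundaries; high orders live in
# fixed-size hashed tables.

#' Compress a block of quality-score lines
#'
#' @param quality_lines Character vector of quality strings (printable
#'   ASCII, one per record).
#' @param params Codec parameters, see [codec_params()].
#' @param first_record 0-based index of the first record in the block.
#' @return An `fq_block` with `stream_type = "quality"`.
#' @export
compress_quality_block <- function(quality_lines, params = codec_params(),
                                   first_record = 0L) {
  bytes <- join_lines(quality_lines)
  payload <- cpp_compress_quality(bytes, params$hash_bits)
  blk <- new_block("quality", 2L, payload, bytes, first_record,
                   length(quality_lines))
  blk$hash_bits <- params$hash_bits
  blk
}

#' Decompress a quality-score block
#'
#' @param block An `fq_block` produced by [compress_quality_block()].
#' @return The original character vector of quality strings.
#' @export
decompress_quality_block <- function(block) {
  if (block$stream_type != "quality") {
    fq_structure_error("decompress_quality_block: not a quality block")
  }
  hb <- if (is.null(block$hash_bits)) 18L else block$hash_bits
  bytes <- decode_payload(block, function(p) cpp_decompress_quality(p, hb))
  split_joined(bytes, block$n_records)
}
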