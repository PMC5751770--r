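# Auxiliary side stream: per-record "the '+' line is bare" flags plus a rare
# exception list of literal payloads. Almost every real file uses a bare
# '+', so this stream is a few bytes per block while keeping line 3
# byte-exact.

compress_aux_block <- function(plus_payloads, first_record = 0L) {
  raw_bytes <- join_lines(plus_payloads)
  n <- length(plus_payloads)
  exc <- which(plus_payloads != "")
  body <- c(varint_encode(n), varint_encode(length(exc)))
  if (length(exc) > 0L) {
    body <- c(body,
              pack_chunk(varint_encode(exc - 1L)),
              pack_chunk(join_values(plus_payloads[exc])))
  }
  payload <- cpp_compress_general(body)
  new_block("aux", 4L, payload, raw_bytes, first_record, n)
}

decompress_aux_block <- function(block) {
  if (block$stream_type != "aux") {
    fq_structure_error("decompress_aux_block: not an aux block")
  }
  body <- tryCatch(cpp_decompress_general(block$payload),
                   error = function(e) fq_corruption_error(conditionMessage(e)))
  cur <- new_cursor(body)
  n <- cursor_varint(cur)
  nexc <- cursor_varint(cur)
  out <- rep("", n)
  if (nexc > 0L) {
    idx <- varint_decode(cursor_chunk(cur), nexc)
    vals <- split_values(cursor_chunk(cur), nexc)
    out[idx + 1L] <- vals
  }
  check_block_bytes(block, join_lines(out))
  out
}
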