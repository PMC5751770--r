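# Compressed-block plumbing shared by the stream codecs: canonical byte
# framing of a list of lines ('\n'-terminated), CRC-32 checksums, and the
# CompressedBlock structure the container stores.

# canonical sub-stream bytes: every line followed by '\n'
join_lines <- function(lines) {
  if (length(lines) == 0L) return(raw(0))
  charToRaw(paste0(paste0(lines, "\n"), collapse = ""))
}

split_joined <- function(bytes, expected_n = NULL) {
  if (length(bytes) == 0L) {
    lines <- character(0)
  } else {
    txt <- rawToChar(bytes)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  }
  if (!is.null(expected_n) && length(lines) != expected_n) {
    fq_corruption_error(sprintf("expected %d line(s), reconstructed %d",
                                expected_n, length(lines)))
  }
  lines
}

#' Codec parameters
#'
#' @param hash_bits Log2 number of buckets of the hashed high-order context
#'   tables used by the quality codec.
#' @return A list of class `fq_codec_params`.
#' @export
codec_params <- function(hash_bits = 18L) {
  structure(list(hash_bits = as.integer(hash_bits)), class = "fq_codec_params")
}

new_block <- function(stream_type, scheme_tag, payload, raw_bytes,
                      first_record = 0L, n_records = 0L) {
  structure(list(
    stream_type = stream_type,
    scheme_tag = as.integer(scheme_tag),
    first_record = as.integer(first_record),
    n_records = as.integer(n_records),
    raw_size = length(raw_bytes),
    payload = payload,
    checksum = cpp_crc32(raw_bytes)
  ), class = "fq_block")
}

#' @export
print.fq_block <- function(x, ...) {
  cat(sprintf("<fq_block %s: records [%d,%d), %d -> %d bytes>\n",
              x$stream_type, x$first_record, x$first_record + x$n_records,
              x$raw_size, length(x$payload)))
  invisible(x)
}

# decode payload -> raw bytes, verifying size and checksum
check_block_bytes <- function(block, bytes) {
  if (length(bytes) != block$raw_size ||
      cpp_crc32(bytes) != block$checksum) {
    fq_corruption_error(sprintf("checksum mismatch in %s block [%d,%d)",
                                block$stream_type, block$first_record,
                                block$first_record + block$n_records))
  }
  bytes
}

decode_payload <- function(block, decompress) {
  bytes <- tryCatch(decompress(block$payload),
                    error = function(e) {
                      fq_corruption_error(sprintf(
                        "corrupt %s block [%d,%d): %s",
                        block$stream_type, block$first_record,
                        block$first_record + block$n_records,
                        conditionMessage(e)))
                    })
  check_block_bytes(block, bytes)
}
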