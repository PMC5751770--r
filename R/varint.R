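# Self-delimiting integer codes (LEB128-style: 7 payload bits per byte, the
# high bit marks continuation) plus the little cursor/chunk framing the
# metadata block format is built from.

#' Self-delimiting variable-length integer codes
#'
#' Encodes non-negative integers as 1-9 byte codes with 7 payload bits per
#' byte and a continuation bit, so concatenated codes parse back without any
#' separator. Values up to 2^53 are supported (stored in doubles).
#'
#' @param x Numeric vector of non-negative integers.
#' @return `varint_encode()`: raw vector of concatenated codes.
#' @export
#' @examples
#' varint_encode(c(86, 238, 1))
#' varint_decode(varint_encode(c(86, 238, 1)))
varint_encode <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(raw(0))
  if (any(is.na(x) | x < 0 | x != floor(x))) {
    fq_structure_error("varint_encode: non-negative integers required")
  }
  groups <- list()
  act <- rep(TRUE, n)
  rem <- x
  while (any(act)) {
    b <- rem[act] %% 128
    rem2 <- rem[act] %/% 128
    more <- rem2 > 0
    v <- rep(NA_real_, n)
    v[act] <- b + 128 * more
    groups[[length(groups) + 1L]] <- v
    rem[act] <- rem2
    act[act] <- more
  }
  m <- do.call(rbind, groups)   # column-major extraction keeps value order
  as.raw(m[!is.na(m)])
}

#' @rdname varint_encode
#' @param bytes Raw vector of concatenated codes.
#' @param n Expected number of values (checked when given).
#' @return `varint_decode()`: numeric vector of decoded values.
#' @export
varint_decode <- function(bytes, n = NULL) {
  if (length(bytes) == 0L) {
    if (!is.null(n) && n != 0L) fq_corruption_error("varint stream truncated")
    return(numeric(0))
  }
  v <- as.integer(bytes)
  if (v[length(v)] >= 128L) fq_corruption_error("varint stream truncated")
  ends <- which(v < 128L)
  sizes <- diff(c(0L, ends))
  if (any(sizes > 9L)) fq_corruption_error("varint code overflow")
  grp <- rep(seq_along(ends), sizes)
  pos <- sequence(sizes)
  vals <- as.numeric(rowsum((v %% 128L) * 128^(pos - 1), grp))
  if (!is.null(n) && length(vals) != n) {
    fq_corruption_error("varint stream has wrong number of values")
  }
  vals
}

zigzag_encode <- function(d) ifelse(d >= 0, 2 * d, -2 * d - 1)
zigzag_decode <- function(z) ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)

# chunk framing: varint length + payload
pack_chunk <- function(bytes) c(varint_encode(length(bytes)), bytes)

new_cursor <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

cursor_varint <- function(cur) {
  x <- 0
  mult <- 1
  repeat {
    if (cur$pos > length(cur$bytes)) fq_corruption_error("truncated varint")
    b <- as.integer(cur$bytes[[cur$pos]])
    cur$pos <- cur$pos + 1L
    x <- x + (b %% 128L) * mult
    if (b < 128L) break
    mult <- mult * 128
  }
  x
}

cursor_bytes <- function(cur, n) {
  if (n == 0) return(raw(0))
  if (cur$pos + n - 1 > length(cur$bytes)) fq_corruption_error("truncated chunk")
  out <- cur$bytes[cur$pos:(cur$pos + n - 1)]
  cur$pos <- cur$pos + as.integer(n)
  out
}

cursor_chunk <- function(cur) cursor_bytes(cur, cursor_varint(cur))
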