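# Hybrid identifier codec. Identifier lines are split at punctuation into
# fields; records sharing a delimiter signature form a template group, and
# each field column of a group is classified and coded with the scheme that
# fits it: incremental (delta) coding for counters (digit-wise, matching
# worked form '3458644' -> 3,1,1,3,-2,-2,0, or value-wise when the deltas
# form a small set), run-length-limited coding for constant columns,
# self-delimiting varints for free-running numbers, and a plain text
# fallback. The assembled column streams are then entropy-coded with the
# low-order byte codec.

META_DELIM_RE <- "[[:punct:] ]"

#' Tokenise an identifier line at punctuation
#'
#' Splits a metadata line into fields separated by single punctuation or
#' space characters. Interleaving fields and delimiters reconstructs the
#' line exactly: a line with `k` delimiters has `k + 1` (possibly empty)
#' fields.
#'
#' @param line A length-1 character string.
#' @return A list of class `fq_tokens` with `fields` and `delimiters`.
#' @export
#' @examples
#' tokenize_identifier("ERR194147.1.HSQ1004:134/1")
tokenize_identifier <- function(line) {
  m <- gregexpr(META_DELIM_RE, line, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    out <- list(fields = line, delimiters = character(0))
  } else {
    pos <- as.integer(m)
    delims <- substring(line, pos, pos)
    starts <- c(1L, pos + 1L)
    ends <- c(pos - 1L, nchar(line))
    out <- list(fields = substring(line, starts, ends), delimiters = delims)
  }
  class(out) <- "fq_tokens"
  out
}

#' Reassemble a tokenised identifier
#'
#' Exact inverse of [tokenize_identifier()].
#'
#' @param t An `fq_tokens` list.
#' @return The original line.
#' @export
detokenize_identifier <- function(t) {
  if (length(t$fields) != length(t$delimiters) + 1L) {
    fq_structure_error("field/delimiter count mismatch")
  }
  if (length(t$delimiters) == 0L) return(t$fields)
  paste0(t$fields[1L],
         paste0(t$delimiters, t$fields[-1L], collapse = ""))
}

#' Classify a field column
#'
#' Chooses the coding scheme for one field across a block of records:
#' `"incremental"` for digit strings whose (value-wise or digit-wise) delta
#' stream has a small alphabet, `"runlength"` for columns dominated by runs
#' of identical values, `"varint_numeric"` for free-running digit strings of
#' varying precision, and `"general"` otherwise.
#'
#' @param column Character vector of one field's values across records.
#' @return One of `"incremental"`, `"runlength"`, `"varint_numeric"`,
#'   `"general"`.
#' @export
classify_field <- function(column) {
  n <- length(column)
  if (n == 0L) fq_structure_error("classify_field: empty column")
  if (all(grepl("^[0-9]+$", column))) {
    num_ok <- all(nchar(column) <= 15L) && all(grepl("^(0|[1-9][0-9]*)$", column))
    if (num_ok) {
      if (n == 1L) return("incremental")
      d <- diff(as.numeric(column))
      if (length(unique(d)) <= 8L) return("incremental")
    }
    if (length(unique(nchar(column))) == 1L) return("incremental")
    if (num_ok) return("varint_numeric")
    return("general")
  }
  runs <- rle(column)
  if (length(runs$lengths) <= max(1, ceiling(n / 4))) return("runlength")
  "general"
}

#' Digit-wise incremental (delta) coding
#'
#' The first output is the first digit; every later output is the
#' difference between consecutive digits, e.g. `"3458644"` encodes to
#' `3, 1, 1, 3, -2, -2, 0`.
#'
#' @param s A non-empty digit string.
#' @return Integer vector of the first digit followed by digit deltas.
#' @export
delta_encode_digits <- function(s) {
  if (length(s) != 1L || !grepl("^[0-9]+$", s)) {
    fq_structure_error("delta_encode_digits: non-empty digit string required")
  }
  d <- as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  c(d[1L], diff(d))
}

#' @rdname delta_encode_digits
#' @param deltas Integer vector produced by `delta_encode_digits()`.
#' @export
delta_decode_digits <- function(deltas) {
  paste(cumsum(as.integer(deltas)), collapse = "")
}

#' Run-length-limited coding
#'
#' Encodes runs of identical values as (value, run-length) pairs with runs
#' capped at `cap`; longer runs are split. A single multi-character string
#' is treated as its character sequence and decoded back to one string.
#'
#' @param values Character vector (or one string).
#' @param cap Maximum run length per pair.
#' @return A data frame with columns `value` and `run`.
#' @export
#' @examples
#' rle_encode("AAAABBB")
rle_encode <- function(values, cap = 255L) {
  collapsed <- FALSE
  if (length(values) == 1L && nchar(values) != 1L) {
    values <- strsplit(values, "", fixed = TRUE)[[1L]]
    collapsed <- TRUE
  }
  if (length(values) == 0L) {
    out <- data.frame(value = character(0), run = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- rle_pairs(values, cap)
  }
  attr(out, "collapsed") <- collapsed
  out
}

#' @rdname rle_encode
#' @param pairs Data frame from `rle_encode()`.
#' @export
rle_decode <- function(pairs) {
  out <- rep(pairs$value, pairs$run)
  if (isTRUE(attr(pairs, "collapsed"))) out <- paste(out, collapse = "")
  out
}

# ---- column scheme encoders (byte-level) ----------------------------------

# run-length pairs over whole values (no character splitting), runs capped
rle_pairs <- function(values, cap = 255L) {
  r <- rle(values)
  splits <- Map(function(v, l) {
    k <- l %/% cap
    runs <- c(rep(cap, k), l - k * cap)
    runs <- runs[runs > 0L]
    data.frame(value = rep(v, length(runs)), run = as.integer(runs),
               stringsAsFactors = FALSE)
  }, r$values, r$lengths)
  out <- do.call(rbind, splits)
  rownames(out) <- NULL
  out
}

join_values <- function(values) {
  if (length(values) == 0L) raw(0) else charToRaw(paste0(paste0(values, "\n"), collapse = ""))
}

split_values <- function(bytes, n) {
  split_joined(bytes, n)
}

value_numeric_ok <- function(values) {
  all(nchar(values) <= 15L) && all(grepl("^(0|[1-9][0-9]*)$", values))
}

TAG_INC_VALUE <- 1L
TAG_INC_DIGIT <- 2L
TAG_RLE <- 3L
TAG_VARINT <- 4L
TAG_GENERAL <- 5L

encode_column <- function(values) {
  cls <- classify_field(values)
  if (cls == "incremental" && value_numeric_ok(values)) {
    v <- as.numeric(values)
    body <- c(pack_chunk(charToRaw(values[1L])),
              pack_chunk(varint_encode(zigzag_encode(diff(v)))))
    return(list(tag = TAG_INC_VALUE, body = body))
  }
  if (cls == "incremental") {
    digs <- lapply(values, function(s) {
      e <- delta_encode_digits(s)
      c(e[1L], e[-1L] + 9L)            # deltas in -9..9 -> bytes 0..18
    })
    body <- c(pack_chunk(varint_encode(nchar(values))),
              pack_chunk(as.raw(unlist(digs))))
    return(list(tag = TAG_INC_DIGIT, body = body))
  }
  if (cls == "runlength") {
    pairs <- rle_pairs(values)
    body <- c(varint_encode(nrow(pairs)),
              pack_chunk(join_values(pairs$value)),
              pack_chunk(varint_encode(pairs$run)))
    return(list(tag = TAG_RLE, body = body))
  }
  if (cls == "varint_numeric") {
    body <- pack_chunk(varint_encode(as.numeric(values)))
    return(list(tag = TAG_VARINT, body = body))
  }
  list(tag = TAG_GENERAL, body = pack_chunk(join_values(values)))
}

decode_column <- function(tag, cur, n_records) {
  if (tag == TAG_INC_VALUE) {
    first <- rawToChar(cursor_chunk(cur))
    deltas <- zigzag_decode(varint_decode(cursor_chunk(cur), n_records - 1L))
    v <- cumsum(c(as.numeric(first), deltas))
    return(sprintf("%.0f", v))
  }
  if (tag == TAG_INC_DIGIT) {
    lens <- varint_decode(cursor_chunk(cur), n_records)
    digits <- as.integer(cursor_chunk(cur))
    if (length(digits) != sum(lens)) fq_corruption_error("digit stream length mismatch")
    off <- cumsum(c(0, lens[-length(lens)]))
    vapply(seq_len(n_records), function(i) {
      d <- digits[(off[i] + 1):(off[i] + lens[i])]
      delta_decode_digits(c(d[1L], d[-1L] - 9L))
    }, character(1))
  } else if (tag == TAG_RLE) {
    npairs <- cursor_varint(cur)
    vals <- split_values(cursor_chunk(cur), npairs)
    runs <- varint_decode(cursor_chunk(cur), npairs)
    out <- rep(vals, runs)
    if (length(out) != n_records) fq_corruption_error("run-length total mismatch")
    out
  } else if (tag == TAG_VARINT) {
    sprintf("%.0f", varint_decode(cursor_chunk(cur), n_records))
  } else if (tag == TAG_GENERAL) {
    split_values(cursor_chunk(cur), n_records)
  } else {
    fq_corruption_error(sprintf("unknown metadata scheme tag %d", tag))
  }
}

# ---- block codec ----------------------------------------------------------

#' Compress a block of identifier lines
#'
#' Records are grouped by delimiter signature (so a template change inside a
#' block is handled by coding each group independently); each group's field
#' columns are coded with the scheme [classify_field()] selects, and the
#' assembled streams are entropy-coded with the low-order byte codec.
#'
#' @param lines Character vector of identifier lines (without the leading
#'   `@`).
#' @param params Codec parameters, see [codec_params()].
#' @param first_record 0-based index of the first record in the block.
#' @return An `fq_block` with `stream_type = "metadata"`.
#' @export
compress_metadata_block <- function(lines, params = codec_params(),
                                    first_record = 0L) {
  raw_bytes <- join_lines(lines)
  n <- length(lines)
  body <- varint_encode(n)
  if (n > 0L) {
    toks <- lapply(lines, tokenize_identifier)
    sigs <- vapply(toks, function(t) paste(t$delimiters, collapse = ""), character(1))
    usig <- unique(sigs)
    gid <- match(sigs, usig) - 1L
    body <- c(body, varint_encode(length(usig)),
              pack_chunk(varint_encode(gid)))
    for (g in seq_along(usig)) {
      idx <- which(gid == g - 1L)
      delims <- toks[[idx[1L]]]$delimiters
      fields <- do.call(rbind, lapply(toks[idx], function(t) t$fields))
      body <- c(body, pack_chunk(charToRaw(paste(delims, collapse = ""))),
                varint_encode(length(idx)))
      for (j in seq_len(ncol(fields))) {
        col <- encode_column(fields[, j])
        body <- c(body, as.raw(col$tag), col$body)
      }
    }
  }
  payload <- cpp_compress_general(body)
  new_block("metadata", 3L, payload, raw_bytes, first_record, n)
}

#' Decompress an identifier block
#'
#' @param block An `fq_block` produced by [compress_metadata_block()].
#' @return The original character vector of identifier lines.
#' @export
decompress_metadata_block <- function(block) {
  if (block$stream_type != "metadata") {
    fq_structure_error("decompress_metadata_block: not a metadata block")
  }
  body <- tryCatch(cpp_decompress_general(block$payload),
                   error = function(e) fq_corruption_error(conditionMessage(e)))
  cur <- new_cursor(body)
  n <- cursor_varint(cur)
  if (n == 0L) {
    lines <- character(0)
  } else {
    ngroups <- cursor_varint(cur)
    gid <- varint_decode(cursor_chunk(cur), n)
    group_lines <- vector("list", ngroups)
    for (g in seq_len(ngroups)) {
      delims <- rawToChar(cursor_chunk(cur))
      delims <- if (nchar(delims) == 0L) character(0) else
        strsplit(delims, "", fixed = TRUE)[[1L]]
      n_rec <- cursor_varint(cur)
      ncols <- length(delims) + 1L
      cols <- vector("list", ncols)
      for (j in seq_len(ncols)) {
        tag <- as.integer(cursor_bytes(cur, 1L))
        cols[[j]] <- decode_column(tag, cur, n_rec)
      }
      if (ncols == 1L) {
        group_lines[[g]] <- cols[[1L]]
      } else {
        parts <- cols[[1L]]
        for (j in 2L:ncols) parts <- paste0(parts, delims[j - 1L], cols[[j]])
        group_lines[[g]] <- parts
      }
    }
    lines <- character(n)
    taken <- integer(ngroups)
    for (g in seq_len(ngroups)) {
      sel <- which(gid == g - 1L)
      lines[sel] <- group_lines[[g]]
    }
  }
  check_block_bytes(block, join_lines(lines))
  lines
}
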