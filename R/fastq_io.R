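# FASTQ parsing/serialisation and sub-stream split/merge.
#
# Byte exactness is the contract here: parse -> serialize reproduces the
# input including the line-3 payload after '+', the newline dialect (LF or
# CRLF, recorded once per file) and the presence of a final newline.

#' Parse FASTQ text into records
#'
#' Parses 4-line FASTQ records into a data frame with one row per record and
#' columns `identifier` (without the leading `@`), `bases`, `plus_payload`
#' (text after `+` on line 3, usually empty) and `quality`. The newline
#' dialect (`crlf`) and whether the input ended with a newline
#' (`final_newline`) are recorded as attributes so that [serialize_fastq()]
#' can reproduce the input byte for byte.
#'
#' @param x A raw vector, or a length-1 character string of FASTQ text.
#' @return A data frame of class `fastq_records`.
#' @export
#' @examples
#' txt <- "@r1\nACGT\n+\nIIII\n"
#' rec <- parse_fastq(txt)
#' rec$bases
parse_fastq <- function(x) {
  if (is.raw(x)) {
    txt <- rawToChar(x)
  } else if (is.character(x) && length(x) == 1L) {
    txt <- x
  } else {
    fq_parse_error("parse_fastq expects a raw vector or a single string")
  }
  if (nchar(txt, type = "bytes") == 0L) {
    return(new_fastq_records(character(0), character(0), character(0),
                             character(0), final_newline = TRUE, crlf = FALSE))
  }
  final_newline <- endsWith(txt, "\n")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  crlf <- any(endsWith(lines, "\r"))
  if (crlf) {
    has_cr <- endsWith(lines, "\r")
    n <- length(lines)
    expect_cr <- if (final_newline) rep(TRUE, n) else c(rep(TRUE, n - 1L), FALSE)
    if (!identical(has_cr, expect_cr)) {
      fq_parse_error("mixed newline dialects in FASTQ input",
                     line = which(has_cr != expect_cr)[1L])
    }
    lines[has_cr] <- substr(lines[has_cr], 1L, nchar(lines[has_cr]) - 1L)
  }
  rec <- records_from_lines(lines, line_offset = 0L)
  attr(rec, "final_newline") <- final_newline
  attr(rec, "crlf") <- crlf
  rec
}

# Validate a block of FASTQ lines (already stripped of EOLs) and build the
# record frame; `line_offset` makes error line numbers file-absolute when
# parsing a chunk mid-file.
records_from_lines <- function(lines, line_offset = 0L) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    bad <- (n %/% 4L) * 4L + 1L
    fq_parse_error(
      sprintf("truncated FASTQ record: line count not a multiple of 4 (at line %d)",
              line_offset + bad),
      line = line_offset + bad
    )
  }
  if (n == 0L) {
    return(new_fastq_records(character(0), character(0), character(0),
                             character(0), final_newline = TRUE, crlf = FALSE))
  }
  ids <- lines[seq.int(1L, n, 4L)]
  bases <- lines[seq.int(2L, n, 4L)]
  plus <- lines[seq.int(3L, n, 4L)]
  qual <- lines[seq.int(4L, n, 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad) > 0L) {
    ln <- line_offset + (bad[1L] - 1L) * 4L + 1L
    fq_parse_error(sprintf("record header missing '@' at line %d", ln), line = ln)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    ln <- line_offset + (bad[1L] - 1L) * 4L + 3L
    fq_parse_error(sprintf("separator line missing '+' at line %d", ln), line = ln)
  }
  bad <- which(nchar(bases, type = "bytes") != nchar(qual, type = "bytes"))
  if (length(bad) > 0L) {
    ln <- line_offset + (bad[1L] - 1L) * 4L + 4L
    fq_parse_error(
      sprintf("base and quality lengths differ for record ending at line %d", ln),
      line = ln
    )
  }
  new_fastq_records(substring(ids, 2L), bases, substring(plus, 2L), qual,
                   final_newline = TRUE, crlf = FALSE)
}

new_fastq_records <- function(identifier, bases, plus_payload, quality,
                              final_newline = TRUE, crlf = FALSE) {
  rec <- data.frame(
    identifier = identifier,
    bases = bases,
    plus_payload = plus_payload,
    quality = quality,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("fastq_records", "data.frame")
  attr(rec, "final_newline") <- final_newline
  attr(rec, "crlf") <- crlf
  rec
}

#' Serialise FASTQ records to bytes
#'
#' Exact inverse of [parse_fastq()] at the byte level.
#'
#' @param records A `fastq_records` data frame.
#' @param final_newline Emit a newline after the last record? Defaults to the
#'   value recorded on `records`.
#' @param crlf Use CRLF line endings? Defaults to the value recorded on
#'   `records`.
#' @return A raw vector of FASTQ text.
#' @export
serialize_fastq <- function(records,
                            final_newline = attr(records, "final_newline"),
                            crlf = attr(records, "crlf")) {
  if (is.null(final_newline)) final_newline <- TRUE
  if (is.null(crlf)) crlf <- FALSE
  n <- nrow(records)
  if (n == 0L) return(raw(0))
  eol <- if (crlf) "\r\n" else "\n"
  m <- rbind(paste0("@", records$identifier),
             records$bases,
             paste0("+", records$plus_payload),
             records$quality)
  txt <- paste(as.vector(m), collapse = eol)
  if (final_newline) txt <- paste0(txt, eol)
  charToRaw(txt)
}

#' Read a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A `fastq_records` data frame (see [parse_fastq()]).
#' @export
read_fastq <- function(path) {
  parse_fastq(readBin(path, "raw", n = file.size(path)))
}

#' Write FASTQ records to a file
#'
#' @param records A `fastq_records` data frame.
#' @param path Output path.
#' @inheritParams serialize_fastq
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path,
                        final_newline = attr(records, "final_newline"),
                        crlf = attr(records, "crlf")) {
  writeBin(serialize_fastq(records, final_newline, crlf), path)
  invisible(path)
}

#' Split records into the three sub-streams
#'
#' Pre-processing step of the compressor: a record stream becomes a metadata
#' sub-stream, a base-sequence sub-stream and a quality-score sub-stream,
#' with positional correspondence preserved. The `+`-line payloads, which are
#' not modelled by any of the three codecs, are carried in an auxiliary side
#' stream so reconstruction stays lossless.
#'
#' @param records A `fastq_records` data frame.
#' @return A list of class `fq_substreams` with elements `metadata_lines`,
#'   `base_lines`, `quality_lines`, `plus_payloads`, `record_count` and
#'   `final_newline`.
#' @export
split_streams <- function(records) {
  out <- list(
    metadata_lines = records$identifier,
    base_lines = records$bases,
    quality_lines = records$quality,
    plus_payloads = records$plus_payload,
    record_count = nrow(records),
    final_newline = isTRUE(attr(records, "final_newline"))
  )
  class(out) <- "fq_substreams"
  out
}

#' Merge sub-streams back into records
#'
#' Inverse of [split_streams()].
#'
#' @param s An `fq_substreams` list.
#' @return A `fastq_records` data frame.
#' @export
merge_streams <- function(s) {
  lens <- c(length(s$metadata_lines), length(s$base_lines),
            length(s$quality_lines), length(s$plus_payloads))
  if (length(unique(lens)) != 1L || lens[1L] != s$record_count) {
    fq_structure_error("sub-stream lengths disagree with record_count")
  }
  new_fastq_records(s$metadata_lines, s$base_lines, s$plus_payloads,
                   s$quality_lines, final_newline = s$final_newline,
                   crlf = FALSE)
}

#' @export
print.fastq_records <- function(x, ...) {
  cat(sprintf("<fastq_records: %d record(s)%s%s>\n", nrow(x),
              if (isTRUE(attr(x, "crlf"))) ", CRLF" else "",
              if (isTRUE(attr(x, "final_newline"))) "" else ", no final newline"))
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 5L))
  invisible(x)
}
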