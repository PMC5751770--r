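# The nested archive: a root container holds one block container per record
# range; each block container holds one instance block per sub-stream
# (metadata, bases, quality, aux). The index maps line/record ranges to
# block entries so a slice of the file can be fetched and decoded without
# touching the rest of the archive.
#
# Physical layout (single-file sink): magic "FQAR" + format byte, the block
# payloads in append order, the JSON index, and a fixed 12-byte trailer
# (4-byte little-endian index length + "FQIX") so a reader can find the
# index from the end of the file. Directory and in-memory sinks address
# objects by name instead and need no trailer.

ARCHIVE_MAGIC <- charToRaw("FQAR")
TRAILER_MAGIC <- charToRaw("FQIX")

#' Create an archive writer
#'
#' The writer streams each appended block to the sink immediately (so
#' transmission overlaps compression of later blocks) and accumulates the
#' index, which [finalize_archive()] serialises as the archive trailer.
#'
#' @param sink An `fq_sink` from [sink_file()], [sink_dir()] or
#'   [sink_memory()].
#' @param dialect List with `crlf` and `final_newline` of the source file.
#' @param records_per_block Block capacity used by the compressor.
#' @param params Codec parameters, see [codec_params()].
#' @param retries put() attempts per object before a sink error surfaces.
#' @return An environment of class `fq_archive_writer`.
#' @export
archive_writer <- function(sink, dialect = list(crlf = FALSE, final_newline = TRUE),
                           records_per_block = 100000L,
                           params = codec_params(), retries = 3L,
                           mode = "fastq") {
  w <- new.env(parent = emptyenv())
  w$sink <- sink
  w$mode <- mode
  w$dialect <- dialect
  w$records_per_block <- as.integer(records_per_block)
  w$params <- params
  w$retries <- as.integer(retries)
  w$entries <- list()
  w$finalized <- FALSE
  sink_put_retry(sink, "header", c(ARCHIVE_MAGIC, as.raw(1L)), w$retries)
  class(w) <- "fq_archive_writer"
  w
}

#' Append a compressed block to an archive
#'
#' @param writer An `fq_archive_writer`.
#' @param block An `fq_block` from one of the stream codecs.
#' @return The entry id (0-based), invisibly.
#' @export
append_block <- function(writer, block) {
  if (writer$finalized) fq_structure_error("archive already finalized")
  id <- length(writer$entries)
  name <- sprintf("blk-%06d-%s", id, block$stream_type)
  sink_put_retry(writer$sink, name, block$payload, writer$retries)
  writer$entries[[id + 1L]] <- list(
    name = name,
    stream = block$stream_type,
    scheme = block$scheme_tag,
    first_record = block$first_record,
    n_records = block$n_records,
    offset = as.numeric(writer$sink$object_offset(name)),
    length = length(block$payload),
    raw_size = block$raw_size,
    crc = block$checksum
  )
  invisible(id)
}

#' Finalise an archive
#'
#' Serialises the index (as JSON) through the sink and, for file sinks,
#' appends the fixed trailer that lets a reader locate the index.
#'
#' @param writer An `fq_archive_writer`.
#' @return The archive index, an object of class `fq_archive_index`.
#' @export
finalize_archive <- function(writer) {
  if (writer$finalized) fq_structure_error("archive already finalized")
  ent <- writer$entries
  firsts <- vapply(ent, `[[`, integer(1), "first_record")
  total_records <- if (length(ent) == 0L) 0L else
    max(vapply(ent, function(e) e$first_record + e$n_records, integer(1)))
  ukeys <- unique(firsts[order(firsts)])
  blocks <- lapply(ukeys, function(fr) {
    sel <- ent[firsts == fr]
    list(first_record = fr,
         n_records = sel[[1L]]$n_records,
         entries = sel)
  })
  index <- list(
    format_version = 1L,
    mode = writer$mode,
    crlf = isTRUE(writer$dialect$crlf),
    final_newline = isTRUE(writer$dialect$final_newline),
    records_per_block = writer$records_per_block,
    hash_bits = writer$params$hash_bits,
    total_records = total_records,
    total_lines = 4L * total_records,
    block_count = length(blocks),
    blocks = blocks
  )
  idx_raw <- charToRaw(as.character(jsonlite::toJSON(index, auto_unbox = TRUE,
                                                     digits = NA, na = "null")))
  sink_put_retry(writer$sink, "index.json", idx_raw, writer$retries)
  if (identical(writer$sink$kind, "file")) {
    trailer <- c(writeBin(length(idx_raw), raw(), size = 4L, endian = "little"),
                 TRAILER_MAGIC)
    sink_put_retry(writer$sink, "trailer", trailer, writer$retries)
  }
  writer$sink$finalize()
  writer$finalized <- TRUE
  structure(index, class = "fq_archive_index")
}

parse_index_json <- function(idx_raw) {
  index <- jsonlite::fromJSON(rawToChar(idx_raw), simplifyVector = FALSE)
  structure(index, class = "fq_archive_index")
}

#' Open an archive for reading
#'
#' @param x Path to an archive file or directory, or the `fq_sink` the
#'   archive was written to.
#' @return A handle of class `fq_archive` with the parsed index; block
#'   payload fetches are counted on the handle (see [extract_range()]).
#' @export
archive_open <- function(x) {
  if (inherits(x, "fq_sink")) {
    index <- parse_index_json(x$get("index.json"))
    fetch_payload <- function(entry) x$get(entry$name)
  } else if (is.character(x) && dir.exists(x)) {
    root <- x
    index <- parse_index_json(read_object_file(root, "index.json"))
    fetch_payload <- function(entry) read_object_file(root, entry$name)
  } else if (is.character(x) && file.exists(x)) {
    sz <- file.size(x)
    if (sz < 15) fq_corruption_error("archive too short")
    con <- file(x, "rb")
    on.exit(close(con))
    seek(con, sz - 8)
    idx_len <- readBin(con, "integer", size = 4L, endian = "little")
    magic <- readBin(con, "raw", n = 4L)
    if (!identical(magic, TRAILER_MAGIC)) {
      fq_corruption_error("archive trailer missing or damaged")
    }
    seek(con, sz - 8 - idx_len)
    index <- parse_index_json(readBin(con, "raw", n = idx_len))
    path <- x
    fetch_payload <- function(entry) {
      con2 <- file(path, "rb")
      on.exit(close(con2))
      seek(con2, entry$offset)
      readBin(con2, "raw", n = entry$length)
    }
  } else {
    fq_structure_error("archive_open: no such archive")
  }
  counter <- new.env(parent = emptyenv())
  counter$fetches <- 0L
  h <- list(index = index,
            fetch = function(entry) {
              counter$fetches <- counter$fetches + 1L
              fetch_payload(entry)
            },
            counter = counter)
  class(h) <- "fq_archive"
  h
}

read_object_file <- function(root, name) {
  f <- file.path(root, name)
  if (!file.exists(f)) fq_corruption_error(sprintf("missing object '%s'", name))
  readBin(f, "raw", n = file.size(f))
}

#' @export
print.fq_archive_index <- function(x, ...) {
  cat(sprintf("<fq_archive_index: %d record(s) in %d block container(s)>\n",
              x$total_records, x$block_count))
  invisible(x)
}

as_archive <- function(x) {
  if (inherits(x, "fq_archive")) x else archive_open(x)
}

#' Locate the blocks covering a line range
#'
#' Maps a 1-based line range of the original FASTQ file to the minimal set
#' of index entries (one per sub-stream per overlapped block container)
#' that must be decoded to reconstruct it. The start must sit on a record
#' boundary (line 1, 5, 9, ...).
#'
#' @param index An `fq_archive_index`.
#' @param start_line 1-based first line, congruent to 1 modulo 4.
#' @param line_count Number of lines requested.
#' @return A data frame of entries (one row per stream per block).
#' @export
locate_blocks <- function(index, start_line, line_count) {
  start_line <- as.numeric(start_line)
  line_count <- as.numeric(line_count)
  if (line_count < 1) fq_range_error("line_count must be positive")
  if (start_line < 1 || (start_line - 1) %% 4 != 0) {
    nearest <- floor(max(start_line - 1, 0) / 4) * 4 + 1
    fq_range_error(sprintf(
      "start_line %d is not a record boundary (nearest boundary: line %d)",
      start_line, nearest))
  }
  end_line <- start_line + line_count - 1
  if (end_line > index$total_lines) {
    fq_range_error(sprintf("requested lines up to %d but file has %d",
                           end_line, index$total_lines))
  }
  r0 <- (start_line - 1) %/% 4
  r1 <- (end_line - 1) %/% 4
  rows <- list()
  for (blk in index$blocks) {
    if (blk$first_record > r1 ||
        blk$first_record + blk$n_records - 1 < r0) next
    for (e in blk$entries) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = e$name, stream = e$stream, scheme = e$scheme,
        first_record = e$first_record, n_records = e$n_records,
        offset = if (is.null(e$offset)) NA_real_ else as.numeric(e$offset),
        length = e$length, raw_size = e$raw_size, crc = e$crc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

entry_to_block <- function(entry, payload, hash_bits) {
  structure(list(
    stream_type = entry$stream,
    scheme_tag = entry$scheme,
    first_record = entry$first_record,
    n_records = entry$n_records,
    raw_size = entry$raw_size,
    payload = payload,
    checksum = entry$crc,
    hash_bits = hash_bits
  ), class = "fq_block")
}

# decode one block container back into records
decode_block_records <- function(archive, entries) {
  idx <- archive$index
  get_stream <- function(stream, decoder) {
    e <- entries[entries$stream == stream, , drop = FALSE]
    if (nrow(e) != 1L) fq_corruption_error(sprintf("missing %s entry", stream))
    e <- as.list(e[1L, ])
    blk <- entry_to_block(e, archive$fetch(e), idx$hash_bits)
    decoder(blk)
  }
  meta <- get_stream("metadata", decompress_metadata_block)
  bases <- get_stream("bases", decompress_reads_block)
  qual <- get_stream("quality", decompress_quality_block)
  aux <- get_stream("aux", decompress_aux_block)
  new_fastq_records(meta, bases, aux, qual)
}

#' Extract a line range without full decompression
#'
#' Decodes only the block containers overlapping the requested range and
#' returns the exact bytes of the corresponding slice of the original FASTQ
#' file. The number of block payload fetches performed is attached as
#' attribute `blocks_touched`.
#'
#' @param archive An `fq_archive` handle, a path, or a sink.
#' @param start_line 1-based first line (record-aligned).
#' @param line_count Number of lines.
#' @return Raw vector of FASTQ bytes, with attribute `blocks_touched`.
#' @export
extract_range <- function(archive, start_line, line_count) {
  archive <- as_archive(archive)
  idx <- archive$index
  if (identical(idx$mode, "generic")) {
    fq_range_error("line-addressed access requires a FASTQ-mode archive")
  }
  loc <- locate_blocks(idx, start_line, line_count)
  before <- archive$counter$fetches
  blocks <- split(loc, loc$first_record)
  blocks <- blocks[order(as.numeric(names(blocks)))]
  span_first <- min(loc$first_record)
  recs <- do.call(rbind, lapply(blocks, function(entries) {
    as.data.frame(decode_block_records(archive, entries))
  }))
  eol <- if (isTRUE(idx$crlf)) "\r\n" else "\n"
  all_lines <- as.vector(rbind(paste0("@", recs$identifier),
                               recs$bases,
                               paste0("+", recs$plus_payload),
                               recs$quality))
  sel_from <- start_line - span_first * 4
  sel <- all_lines[sel_from:(sel_from + line_count - 1)]
  end_line <- start_line + line_count - 1
  terminal <- !(end_line == idx$total_lines && !isTRUE(idx$final_newline))
  txt <- paste(sel, collapse = eol)
  if (terminal) txt <- paste0(txt, eol)
  out <- charToRaw(txt)
  attr(out, "blocks_touched") <- archive$counter$fetches - before
  out
}

#' Decompress a whole archive back to FASTQ
#'
#' @param archive An `fq_archive` handle, a path, or a sink.
#' @param output Optional path; when given the FASTQ bytes are written
#'   there, otherwise they are returned.
#' @return When `output` is given, the byte count written (invisibly along
#'   with the path as attribute); otherwise the raw FASTQ bytes.
#' @export
decompress_archive <- function(archive, output = NULL) {
  archive <- as_archive(archive)
  idx <- archive$index
  if (identical(idx$mode, "generic")) {
    return(decompress_generic_archive(archive, output))
  }
  eolc <- isTRUE(idx$crlf)
  nb <- length(idx$blocks)
  parts <- vector("list", nb)
  ord <- order(vapply(idx$blocks, function(b) b$first_record, numeric(1)))
  k <- 0L
  for (bi in ord) {
    blk <- idx$blocks[[bi]]
    entries <- locate_blocks(idx, blk$first_record * 4 + 1, blk$n_records * 4)
    entries <- entries[entries$first_record == blk$first_record, , drop = FALSE]
    recs <- decode_block_records(archive, entries)
    k <- k + 1L
    last <- k == nb
    parts[[k]] <- serialize_fastq(recs,
                                  final_newline = if (last) isTRUE(idx$final_newline) else TRUE,
                                  crlf = eolc)
  }
  bytes <- do.call(c, c(parts, list(raw(0))))
  if (is.null(output)) return(bytes)
  writeBin(bytes, output)
  invisible(length(bytes))
}

decompress_generic_archive <- function(archive, output = NULL) {
  idx <- archive$index
  ord <- order(vapply(idx$blocks, function(b) b$first_record, numeric(1)))
  parts <- lapply(idx$blocks[ord], function(blk) {
    e <- blk$entries[[1L]]
    entry <- list(name = e$name, stream = e$stream, scheme = e$scheme,
                  first_record = e$first_record, n_records = e$n_records,
                  offset = if (is.null(e$offset)) NA_real_ else e$offset,
                  length = e$length, raw_size = e$raw_size, crc = e$crc)
    blk_obj <- entry_to_block(entry, archive$fetch(entry), idx$hash_bits)
    decode_payload(blk_obj, cpp_decompress_general)
  })
  bytes <- do.call(c, c(parts, list(raw(0))))
  if (is.null(output)) return(bytes)
  writeBin(bytes, output)
  invisible(length(bytes))
}
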