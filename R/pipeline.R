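# End-to-end pipeline: stream the input in blocks of records, compress the
# four sub-stream blocks of each record range (optionally on a worker
# pool), and emit them to the sink in index order. A bounded buffer of
# pending blocks provides pipe-filter backpressure: the reader stops
# pulling input while `queue_capacity` blocks are in flight, so a slow sink
# or codec throttles the producer instead of unbounded buffering.

#' Pipeline options
#'
#' @param records_per_block Records per block container (the fixed block
#'   size of the compressor).
#' @param workers Number of worker processes compressing blocks in
#'   parallel. Archives are byte-identical for any worker count.
#' @param queue_capacity Maximum blocks in flight (read but not yet
#'   emitted); must be at least `workers`.
#' @param hash_bits See [codec_params()].
#' @param retries Sink put() attempts before failing.
#' @return A list of class `fq_pipeline_options`.
#' @export
pipeline_options <- function(records_per_block = 100000L, workers = 1L,
                             queue_capacity = 2L * workers,
                             hash_bits = 18L, retries = 3L) {
  workers <- as.integer(workers)
  queue_capacity <- as.integer(queue_capacity)
  if (workers < 1L || queue_capacity < workers) {
    fq_config_error("need queue_capacity >= workers >= 1")
  }
  structure(list(records_per_block = as.integer(records_per_block),
                 workers = workers,
                 queue_capacity = queue_capacity,
                 hash_bits = as.integer(hash_bits),
                 retries = as.integer(retries)),
            class = "fq_pipeline_options")
}

compress_record_chunk <- function(records, first_record, params) {
  list(
    metadata = compress_metadata_block(records$identifier, params, first_record),
    bases = compress_reads_block(records$bases, params, first_record),
    quality = compress_quality_block(records$quality, params, first_record),
    aux = compress_aux_block(records$plus_payload, first_record)
  )
}

detect_dialect <- function(path) {
  sz <- file.size(path)
  head <- readBin(path, "raw", n = min(sz, 65536))
  con <- file(path, "rb")
  on.exit(close(con))
  last <- if (sz > 0) { seek(con, sz - 1); readBin(con, "raw", n = 1L) } else raw(0)
  list(crlf = any(head == as.raw(13L)),
       final_newline = length(last) == 1L && last == as.raw(10L))
}

#' Compress a FASTQ file into a block archive
#'
#' Reads the input in blocks of `records_per_block` records, compresses the
#' metadata/bases/quality sub-streams (plus the auxiliary `+`-line stream)
#' of each block, and streams the compressed blocks to the sink as they
#' complete, in deterministic index order regardless of worker scheduling.
#'
#' @param input Path to a FASTQ file, or a raw vector of FASTQ bytes.
#' @param output Path for a single-file archive (ignored when `sink` is
#'   given).
#' @param sink An `fq_sink`; defaults to `sink_file(output)`.
#' @param options See [pipeline_options()].
#' @return A list of class `fq_compression` with the archive `index` and a
#'   `stats` list (byte counts per stream, compression ratio in percent,
#'   maximum blocks in flight).
#' @export
compress_fastq <- function(input, output = NULL, sink = NULL,
                           options = pipeline_options()) {
  params <- codec_params(options$hash_bits)
  lines_read <- 0L
  if (is.raw(input)) {
    original_bytes <- length(input)
    all_recs <- parse_fastq(input)
    dialect <- list(crlf = isTRUE(attr(all_recs, "crlf")),
                    final_newline = isTRUE(attr(all_recs, "final_newline")))
    pulled <- 0L
    pull <- function(nmax) {
      if (pulled >= nrow(all_recs)) return(NULL)
      sel <- (pulled + 1L):min(pulled + nmax, nrow(all_recs))
      pulled <<- pulled + length(sel)
      all_recs[sel, , drop = FALSE]
    }
  } else {
    original_bytes <- file.size(input)
    dialect <- detect_dialect(input)
    con <- file(input, "r")
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    pull <- function(nmax) {
      lines <- suppressWarnings(readLines(con, n = 4L * nmax))
      if (length(lines) == 0L) return(NULL)
      rec <- records_from_lines(lines, line_offset = lines_read)
      lines_read <<- lines_read + length(lines)
      rec
    }
  }
  if (is.null(sink)) {
    if (is.null(output)) fq_config_error("either output or sink is required")
    sink <- sink_file(output)
  }
  writer <- archive_writer(sink, dialect, options$records_per_block, params,
                           options$retries)
  cleanup <- function(e) {
    if (!is.null(sink$discard)) try(sink$discard(), silent = TRUE)
    stop(e)
  }
  stream_bytes <- c(metadata = 0, bases = 0, quality = 0, aux = 0)
  payload_bytes <- stream_bytes
  max_in_flight <- 0L
  first_record <- 0L
  tryCatch({
    rpb <- options$records_per_block
    done <- FALSE
    repeat {
      # pull at most queue_capacity blocks of records before compressing
      chunks <- list()
      while (!done && length(chunks) < options$queue_capacity) {
        rec <- pull(rpb)
        if (is.null(rec)) { done <- TRUE; break }
        chunks[[length(chunks) + 1L]] <- rec
        if (nrow(rec) < rpb) { done <- TRUE; break }
      }
      if (length(chunks) == 0L) break
      max_in_flight <- max(max_in_flight, length(chunks))
      firsts <- first_record +
        c(0L, cumsum(vapply(chunks, nrow, integer(1))))[seq_along(chunks)]
      work <- Map(list, chunks, firsts)
      fun <- function(wk) compress_record_chunk(wk[[1L]], wk[[2L]], params)
      results <- if (options$workers > 1L) {
        parallel::mclapply(work, fun, mc.cores = options$workers)
      } else {
        lapply(work, fun)
      }
      for (res in results) {
        if (inherits(res, "try-error") || !is.list(res)) {
          fq_sink_error("worker failed while compressing a block")
        }
        for (st in c("metadata", "bases", "quality", "aux")) {
          append_block(writer, res[[st]])
          stream_bytes[st] <- stream_bytes[st] + res[[st]]$raw_size
          payload_bytes[st] <- payload_bytes[st] + length(res[[st]]$payload)
        }
      }
      first_record <- first_record + sum(vapply(chunks, nrow, integer(1)))
      if (done) break
    }
    index <- finalize_archive(writer)
    compressed_bytes <- if (identical(sink$kind, "file")) file.size(sink$path) else
      sum(payload_bytes)
    stats <- list(
      original_bytes = as.numeric(original_bytes),
      compressed_bytes = as.numeric(compressed_bytes),
      ratio = if (original_bytes > 0)
        compression_ratio(compressed_bytes, original_bytes) else NA_real_,
      stream_raw_bytes = stream_bytes,
      stream_payload_bytes = payload_bytes,
      max_in_flight = max_in_flight
    )
    structure(list(index = index, stats = stats), class = "fq_compression")
  }, error = cleanup)
}

#' @export
print.fq_compression <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<fq_compression: %d record(s), %s -> %s bytes (%.2f%%)>\n",
              x$index$total_records,
              format(s$original_bytes, big.mark = ","),
              format(s$compressed_bytes, big.mark = ","),
              s$ratio))
  invisible(x)
}

#' Compress an arbitrary byte stream (generic fallback mode)
#'
#' Non-FASTQ inputs are carried in the same container format: the stream is
#' cut into fixed-size chunks, each coded with the low-order byte codec.
#' Such archives decompress with [decompress_archive()] but have no
#' line-addressed random access.
#'
#' @param input Path or raw vector.
#' @param output,sink,options As in [compress_fastq()];
#'   `records_per_block` is ignored (chunking is by bytes).
#' @param bytes_per_block Chunk size in bytes.
#' @return An `fq_compression` list.
#' @export
compress_generic <- function(input, output = NULL, sink = NULL,
                             options = pipeline_options(),
                             bytes_per_block = 4L * 1024L^2) {
  bytes <- if (is.raw(input)) input else
    readBin(input, "raw", n = file.size(input))
  if (is.null(sink)) {
    if (is.null(output)) fq_config_error("either output or sink is required")
    sink <- sink_file(output)
  }
  writer <- archive_writer(sink, records_per_block = options$records_per_block,
                           params = codec_params(options$hash_bits),
                           retries = options$retries, mode = "generic")
  n <- length(bytes)
  nchunks <- if (n == 0L) 0L else ceiling(n / bytes_per_block)
  payload_total <- 0
  for (i in seq_len(nchunks)) {
    from <- (i - 1) * bytes_per_block + 1
    chunk <- bytes[from:min(n, i * bytes_per_block)]
    blk <- new_block("generic", 5L, cpp_compress_general(chunk), chunk,
                     first_record = i - 1L, n_records = 1L)
    append_block(writer, blk)
    payload_total <- payload_total + length(blk$payload)
  }
  index <- finalize_archive(writer)
  compressed <- if (identical(sink$kind, "file")) file.size(sink$path) else
    payload_total
  structure(list(index = index,
                 stats = list(original_bytes = as.numeric(n),
                              compressed_bytes = as.numeric(compressed),
                              ratio = if (n > 0)
                                compression_ratio(compressed, n) else NA_real_)),
            class = "fq_compression")
}

#' Compression ratio in percent
#'
#' Compressed size over original size, times 100; smaller means better
#' compression.
#'
#' @param compressed_bytes,original_bytes Sizes in bytes.
#' @return The ratio in percent.
#' @export
compression_ratio <- function(compressed_bytes, original_bytes) {
  if (any(original_bytes <= 0)) fq_config_error("original size must be positive")
  100 * compressed_bytes / original_bytes
}

#' Mean, standard deviation and coefficient of variation
#'
#' Summary used to compare compression ratios across datasets: arithmetic
#' mean, sample standard deviation (n - 1 denominator) and their ratio
#' CV = SD / mean, a scale-free measure of how stable a compressor's ratio
#' is across inputs.
#'
#' @param ratios Numeric vector with at least two values.
#' @return A list with `avg`, `sd` and `cv`.
#' @export
summary_stats <- function(ratios) {
  if (length(ratios) < 2L) fq_config_error("need at least two values")
  avg <- mean(ratios)
  s <- sd(ratios)
  list(avg = avg, sd = s, cv = s / avg)
}
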