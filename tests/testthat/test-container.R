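make_archive <- function(n = 20L, rpb = 7L, sink = sink_memory(), seed = 51,
                         ...) {
  fx <- generate_fastq(fixture_spec(n, read_length = 40, seed = seed, ...))
  res <- compress_fastq(fx, sink = sink,
                        options = pipeline_options(records_per_block = rpb))
  list(fx = fx, res = res, sink = sink)
}

test_that("the index describes the container tree laid out by the writer", {
  a <- make_archive(n = 20L, rpb = 2L)          # 10 block containers
  idx <- a$res$index
  expect_equal(idx$block_count, 10L)
  expect_equal(idx$total_records, 20L)
  expect_equal(idx$total_lines, 80L)
  firsts <- vapply(idx$blocks, function(b) b$first_record, numeric(1))
  ns <- vapply(idx$blocks, function(b) b$n_records, numeric(1))
  expect_equal(sort(firsts), seq(0, 18, by = 2))  # contiguous, disjoint cover
  expect_true(all(ns == 2))
  expect_equal(idx$blocks[[1L]]$first_record, 0L)
  streams <- sort(vapply(idx$blocks[[1L]]$entries, function(e) e$stream,
                         character(1)))
  expect_identical(streams, c("aux", "bases", "metadata", "quality"))
})

test_that("the index survives serialisation byte-exactly", {
  a <- make_archive()
  reread <- archive_open(a$sink)$index
  expect_identical(jsonlite::toJSON(unclass(reread), auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(unclass(reread), auto_unbox = TRUE, digits = NA))
  expect_equal(reread$total_records, a$res$index$total_records)
  expect_equal(reread$block_count, a$res$index$block_count)
})

test_that("locate_blocks finds the minimal covering entry set", {
  a <- make_archive(n = 20L, rpb = 7L)          # blocks [0,7) [7,14) [14,20)
  idx <- archive_open(a$sink)$index
  inside <- locate_blocks(idx, 4 * 14 + 1, 4 * 3)   # records 14..16
  expect_equal(unique(inside$first_record), 14)
  expect_equal(nrow(inside), 4L)
  spanning <- locate_blocks(idx, 4 * 5 + 1, 4 * 4)  # records 5..8
  expect_setequal(unique(spanning$first_record), c(0, 7))
  expect_equal(nrow(spanning), 8L)
  whole <- locate_blocks(idx, 1, 80)
  expect_equal(nrow(whole), 12L)

  err <- tryCatch(locate_blocks(idx, 6, 4), condition = identity)
  expect_s3_class(err, "fqarc_range_error")
  expect_match(conditionMessage(err), "line 5")
  expect_error(locate_blocks(idx, 81, 4), class = "fqarc_range_error")
  expect_error(locate_blocks(idx, 1, 0), class = "fqarc_range_error")
})

test_that("extract_range equals the slice of the original file", {
  a <- make_archive(n = 20L, rpb = 7L)
  h <- archive_open(a$sink)
  lines <- strsplit(rawToChar(a$fx), "\n")[[1L]]
  slice_bytes <- function(from, count) {
    charToRaw(paste0(paste(lines[from:(from + count - 1)], collapse = "\n"), "\n"))
  }
  # records 5..9 are lines 17..36
  got <- extract_range(h, 17, 20)
  expect_identical(got[seq_along(got)], slice_bytes(17, 20))
  # whole file equals full decompression
  all_bytes <- extract_range(h, 1, 80)
  expect_identical(all_bytes[seq_along(all_bytes)], a$fx)
  expect_identical(decompress_archive(h), a$fx)
  # partial line counts within a record
  got <- extract_range(h, 9, 2)
  expect_identical(got[seq_along(got)], slice_bytes(9, 2))
})

test_that("one record touches one block per stream", {
  a <- make_archive(n = 21L, rpb = 7L)          # 3 block containers
  h <- archive_open(a$sink)
  got <- extract_range(h, 4 * 8 + 1, 4)         # record 8, inside block 1
  expect_equal(attr(got, "blocks_touched"), 4L) # one fetch per stream
})

test_that("a flaky sink retried to success yields an identical archive", {
  clean <- make_archive(sink = sink_memory(), seed = 77)
  flaky_inner <- sink_memory()
  flaky <- flaky_sink(flaky_inner)
  again <- make_archive(sink = flaky, seed = 77)
  expect_identical(names(flaky_inner$objects), names(clean$sink$objects))
  for (nm in names(clean$sink$objects)) {
    expect_identical(flaky_inner$objects[[nm]], clean$sink$objects[[nm]])
  }
  expect_identical(decompress_archive(archive_open(flaky_inner)), clean$fx)
})

test_that("a sink that keeps failing surfaces a sink error", {
  always_bad <- flaky_sink(sink_memory(), fail_times = 99L)
  expect_error(
    compress_fastq(generate_fastq(fixture_spec(4, read_length = 30, seed = 1)),
                   sink = always_bad),
    class = "fqarc_sink_error")
})

test_that("an empty input makes a valid empty archive", {
  sink <- sink_memory()
  res <- compress_fastq(raw(0), sink = sink)
  expect_equal(res$index$block_count, 0L)
  expect_equal(res$index$total_records, 0L)
  expect_identical(decompress_archive(archive_open(sink)), raw(0))
})

test_that("payload corruption in the archive is reported with the block", {
  a <- make_archive(n = 20L, rpb = 7L)
  name <- grep("bases", names(a$sink$objects), value = TRUE)[2L]
  obj <- a$sink$objects[[name]]
  obj[length(obj) %/% 2L] <- xor(obj[length(obj) %/% 2L], as.raw(0x08))
  a$sink$objects[[name]] <- obj
  err <- tryCatch(decompress_archive(archive_open(a$sink)), condition = identity)
  expect_s3_class(err, "fqarc_corruption_error")
  expect_match(conditionMessage(err), "bases")
})

test_that("directory and single-file sinks read back like memory sinks", {
  fx <- generate_fastq(fixture_spec(15, read_length = 35, seed = 91))
  fdir <- tempfile("arcdir")
  compress_fastq(fx, sink = sink_dir(fdir),
                 options = pipeline_options(records_per_block = 6L))
  expect_identical(decompress_archive(fdir), fx)
  farc <- tempfile(fileext = ".fqar")
  compress_fastq(fx, output = farc,
                 options = pipeline_options(records_per_block = 6L))
  expect_identical(decompress_archive(farc), fx)
  got <- extract_range(farc, 21, 8)
  lines <- strsplit(rawToChar(fx), "\n")[[1L]]
  expect_identical(rawToChar(got[seq_along(got)]),
                   paste0(paste(lines[21:28], collapse = "\n"), "\n"))
  unlink(fdir, recursive = TRUE); unlink(farc)
})
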