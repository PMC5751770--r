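test_that("a canonical 4-line record parses to its fields and round-trips", {
  rec <- parse_fastq(table1_text)
  expect_s3_class(rec, "fastq_records")
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$identifier, table1_identifier)
  expect_identical(rec$bases, table1_bases)
  expect_identical(rec$quality, table1_quality)
  expect_identical(rec$plus_payload, "")
  expect_equal(nchar(rec$bases), 37L)
  expect_equal(nchar(rec$quality), 37L)
  expect_identical(serialize_fastq(rec), charToRaw(table1_text))
})

test_that("empty input gives zero records and serialises to empty bytes", {
  rec <- parse_fastq(raw(0))
  expect_equal(nrow(rec), 0L)
  expect_identical(serialize_fastq(rec), raw(0))
})

test_that("malformed input raises parse errors with line numbers", {
  five <- paste0(table1_text, "@orphan\n")
  err <- tryCatch(parse_fastq(five), condition = identity)
  expect_s3_class(err, "fqarc_parse_error")
  expect_equal(err$line, 5L)

  no_at <- sub("^@", "x", table1_text)
  err <- tryCatch(parse_fastq(no_at), condition = identity)
  expect_s3_class(err, "fqarc_parse_error")
  expect_equal(err$line, 1L)

  bad_len <- sub("CC@", "CC", table1_text, fixed = TRUE)
  expect_error(parse_fastq(bad_len), class = "fqarc_parse_error")

  no_plus <- sub("\\+", "&", table1_text)
  err <- tryCatch(parse_fastq(no_plus), condition = identity)
  expect_s3_class(err, "fqarc_parse_error")
  expect_equal(err$line, 3L)
})

test_that("parse/serialize is the byte-level identity across dialects", {
  for (crlf in c(FALSE, TRUE)) {
    for (fnl in c(TRUE, FALSE)) {
      fx <- generate_fastq(fixture_spec(25, read_length = c(30, 60),
                                        crlf = crlf, final_newline = fnl,
                                        plus_rate = 0.3, seed = 11))
      rec <- parse_fastq(fx)
      expect_identical(attr(rec, "crlf"), crlf)
      expect_identical(attr(rec, "final_newline"), fnl)
      expect_identical(serialize_fastq(rec), fx)
    }
  }
})

test_that("split/merge preserve positional correspondence and invert", {
  rec <- parse_fastq(table1_text)
  s <- split_streams(rec)
  expect_identical(s$metadata_lines, table1_identifier)
  expect_identical(s$base_lines, table1_bases)
  expect_identical(s$quality_lines, table1_quality)
  expect_identical(s$plus_payloads, "")
  expect_equal(s$record_count, 1L)
  expect_identical(as.data.frame(merge_streams(s)), as.data.frame(rec))

  empty <- split_streams(parse_fastq(raw(0)))
  expect_equal(empty$record_count, 0L)
  expect_length(empty$base_lines, 0L)
  expect_equal(nrow(merge_streams(empty)), 0L)

  fx <- generate_fastq(fixture_spec(40, read_length = 50, plus_rate = 0.2,
                                    seed = 4))
  rec <- parse_fastq(fx)
  s <- split_streams(rec)
  expect_length(s$base_lines, 40L)
  expect_identical(s$base_lines, rec$bases)
  back <- merge_streams(s)
  expect_identical(back$identifier, rec$identifier)
  expect_identical(serialize_fastq(back, final_newline = TRUE, crlf = FALSE),
                   serialize_fastq(rec, final_newline = TRUE, crlf = FALSE))

  s$quality_lines <- s$quality_lines[-1]
  expect_error(merge_streams(s), class = "fqarc_structure_error")
})
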