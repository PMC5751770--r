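test_that("tokenisation splits at punctuation and inverts exactly", {
  t1 <- tokenize_identifier(table1_identifier)
  expect_identical(t1$fields,
                   c("ERR194147", "1", "HSQ1004", "134", "C0D8DACXX", "1",
                     "1104", "3874", "86", "238", "1"))
  expect_identical(t1$delimiters,
                   c(".", ".", ":", ":", ":", ":", ":", ":", ",", "/"))
  expect_identical(detokenize_identifier(t1), table1_identifier)

  expect_identical(tokenize_identifier("ABC")$fields, "ABC")
  expect_length(tokenize_identifier("ABC")$delimiters, 0L)
  expect_identical(detokenize_identifier(tokenize_identifier("")), "")

  set.seed(41)
  pool <- c(LETTERS, letters, 0:9, ".", ":", "/", " ", "_", "=", "#")
  for (i in 1:50) {
    line <- paste(sample(pool, sample(0:40, 1), replace = TRUE), collapse = "")
    expect_identical(detokenize_identifier(tokenize_identifier(line)), line)
  }

  bad <- list(fields = c("a", "b"), delimiters = character(0))
  expect_error(detokenize_identifier(bad), class = "fqarc_structure_error")
})

test_that("field columns classify by their stated rules", {
  expect_identical(classify_field(c("1", "2", "3", "4")), "incremental")
  expect_identical(classify_field(rep("HSQ1004", 1000)), "runlength")
  set.seed(42)
  rand <- vapply(1:200, function(i)
    paste(sample(c(LETTERS, 0:9), 8, replace = TRUE), collapse = ""),
    character(1))
  expect_identical(classify_field(rand), "general")
  varied <- as.character(sample.int(99999L, 200))
  expect_identical(classify_field(varied), "varint_numeric")
})

test_that("digit-wise incremental coding reproduces the worked example", {
  expect_identical(delta_encode_digits("3458644"), c(3L, 1L, 1L, 3L, -2L, -2L, 0L))
  expect_identical(delta_encode_digits("7"), 7L)
  expect_identical(delta_encode_digits("1111"), c(1L, 0L, 0L, 0L))
  expect_identical(delta_decode_digits(c(1L, 0L, 0L, 0L)), "1111")
  expect_identical(delta_decode_digits(delta_encode_digits("3458644")), "3458644")
  expect_error(delta_encode_digits("12a"), class = "fqarc_structure_error")
})

test_that("run-length-limited coding caps runs and inverts", {
  p <- rle_encode("AAAABBB")
  expect_identical(p$value, c("A", "B"))
  expect_identical(p$run, c(4L, 3L))
  expect_identical(rle_decode(p), "AAAABBB")
  expect_equal(nrow(rle_encode(character(0))), 0L)
  expect_equal(nrow(rle_encode("")), 0L)
  expect_identical(rle_decode(rle_encode("")), "")
  long <- rle_encode(rep("x", 300), cap = 255L)
  expect_identical(long$run, c(255L, 45L))
  expect_identical(rle_decode(long), rep("x", 300))
  expect_equal(sum(long$run), 300L)
})

test_that("varints are self-delimiting and prefix-free", {
  expect_length(varint_encode(0), 1L)
  expect_length(varint_encode(127), 1L)
  expect_length(varint_encode(128), 2L)
  expect_equal(varint_decode(varint_encode(0)), 0)
  expect_equal(varint_decode(varint_encode(c(86, 238, 1))), c(86, 238, 1))
  set.seed(43)
  for (i in 1:25) {
    v <- sample.int(2^20, sample(1:30, 1))
    expect_equal(varint_decode(varint_encode(v)), v)
  }
  big <- varint_encode(c(2^40, 5))
  expect_equal(varint_decode(big), c(2^40, 5))
  trunc <- varint_encode(300)
  expect_error(varint_decode(trunc[1]), class = "fqarc_corruption_error")
})

test_that("identifier blocks round-trip and compress counters hard", {
  ids <- sprintf("SIMRUN947.%d.HSQ1004:134:C0D8DACXX:1:1104:3874:86,238/1",
                 seq_len(1000))
  blk <- compress_metadata_block(ids)
  expect_identical(decompress_metadata_block(blk), ids)
  expect_lt(length(blk$payload), 0.10 * blk$raw_size)

  expect_identical(decompress_metadata_block(compress_metadata_block("just one")),
                   "just one")
  expect_identical(decompress_metadata_block(compress_metadata_block(character(0))),
                   character(0))
})

test_that("template changes inside a block are handled by grouping", {
  set.seed(44)
  a <- sprintf("RUN.%d.X:%d/2", 1:40, sample.int(500, 40))
  b <- sprintf("other_%d format=%d", 1:25, sample.int(500, 25))
  mixed <- character(65)
  sel <- sample(65, 40)
  mixed[sel] <- a
  mixed[-sel] <- b
  blk <- compress_metadata_block(mixed)
  expect_identical(decompress_metadata_block(blk), mixed)
})

test_that("metadata payload tampering is detected", {
  ids <- sprintf("SIM.%d.X:%d", 1:100, 100:1)
  blk <- compress_metadata_block(ids)
  i <- length(blk$payload) %/% 2L
  blk$payload[i] <- xor(blk$payload[i], as.raw(0x20))
  expect_error(decompress_metadata_block(blk), class = "fqarc_corruption_error")
})
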