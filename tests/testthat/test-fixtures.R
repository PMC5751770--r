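test_that("identical specs generate identical bytes", {
  sp <- fixture_spec(100, read_length = c(40, 60), quality_alphabet = 7,
                     seed = 71)
  expect_identical(generate_fastq(sp), generate_fastq(sp))
  expect_identical(generate_fastq(fixture_spec(0)), raw(0))
})

test_that("generated corpora are valid FASTQ with the declared structure", {
  fx <- generate_fastq(fixture_spec(300, read_length = c(30, 90),
                                    quality_alphabet = 6, seed = 72))
  rec <- parse_fastq(fx)
  expect_equal(nrow(rec), 300L)
  expect_equal(nchar(rec$bases), nchar(rec$quality))
  qchars <- unique(unlist(strsplit(rec$quality, "")))
  expect_lte(length(qchars), 6L)
  expect_equal(length(qchars), 6L)   # large n exercises the whole alphabet
})

test_that("alpha = 1 draws uniform symbols", {
  s <- generate_markov_sequence(20000, 1, 1, c("A", "C", "G", "T"), seed = 73)
  counts <- table(strsplit(s, "")[[1L]])
  expect_length(counts, 4L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("small alpha produces long runs at order 1", {
  s <- generate_markov_sequence(20000, 1, 0.05, c("A", "C", "G", "T"), seed = 74)
  mean_run <- mean(rle(strsplit(s, "")[[1L]])$lengths)
  expect_gt(mean_run, 4 / 3)   # uniform expectation is 1/(1 - 1/4)
})

test_that("empirical conditional entropy decreases with sharpness", {
  cond_entropy <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    tab <- table(head(ch, -1), tail(ch, -1))
    tot <- sum(tab)
    rowp <- rowSums(tab) / tot
    h <- apply(tab, 1, function(r) {
      p <- r[r > 0] / sum(r)
      -sum(p * log2(p))
    })
    sum(rowp * h)
  }
  hs <- vapply(c(1, 0.4, 0.1), function(a)
    cond_entropy(generate_markov_sequence(30000, 1, a, c("A", "C", "G", "T"),
                                          seed = 75)),
    numeric(1))
  expect_true(all(diff(hs) < 0))
})

test_that("every generated corpus survives the full pipeline byte-exactly", {
  for (sp in list(fixture_spec(50, read_length = 40, quality_alphabet = 6,
                               seed = 76),
                  fixture_spec(35, read_length = c(25, 60), crlf = TRUE,
                               quality_alphabet = 39, seed = 77))) {
    fx <- generate_fastq(sp)
    sink <- sink_memory()
    compress_fastq(fx, sink = sink,
                   options = pipeline_options(records_per_block = 12L))
    expect_identical(decompress_archive(archive_open(sink)), fx)
  }
})

test_that("smaller quality alphabets never compress worse, other things equal", {
  ratio_for <- function(m) {
    lines <- markov_quality_lines(400, 60, m, order = 2, alpha = 0.3, seed = 78)
    blk <- compress_quality_block(lines)
    length(blk$payload) / blk$raw_size
  }
  expect_lte(ratio_for(6), ratio_for(39))
})
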