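test_that("the transform matches the sort-all-rotations oracle", {
  b <- bwt_forward("banana")
  oracle <- naive_bwt(charToRaw("banana"))
  expect_identical(b$permuted, oracle$permuted)
  expect_identical(b$primary_index, as.integer(oracle$primary_index))
  # frozen from the oracle: sorted rotations of banana$ end in "annb$aa"
  expect_identical(rawToChar(b$permuted), "annbaa")
  expect_identical(b$primary_index, 4L)

  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:64, 1)
    bytes <- as.raw(sample(c(65:90, 97:122, 0, 255), n, replace = TRUE))
    got <- bwt_forward(bytes)
    want <- naive_bwt(bytes)
    expect_identical(got$permuted, want$permuted)
    expect_equal(got$primary_index, want$primary_index)
  }
})

test_that("the inverse matches the iterated-sort oracle and the identity", {
  set.seed(22)
  for (i in 1:60) {
    n <- sample(1:48, 1)
    bytes <- as.raw(sample(c(65:70, 97:99), n, replace = TRUE))
    fwd <- bwt_forward(bytes)
    expect_identical(bwt_inverse(fwd), bytes)
    expect_identical(naive_bwt_inverse(fwd$permuted, fwd$primary_index), bytes)
  }
  expect_identical(rawToChar(bwt_inverse(bwt_forward("A"))), "A")
  expect_identical(rawToChar(bwt_inverse(bwt_forward("AAAAAAAA"))), "AAAAAAAA")
})

test_that("forward/inverse is the identity on 4 KiB blocks", {
  set.seed(23)
  for (i in 1:3) {
    bytes <- charToRaw(paste(sample(c("A", "C", "G", "T", "N"), 4096,
                                    replace = TRUE), collapse = ""))
    fwd <- bwt_forward(bytes)
    expect_identical(sort(as.integer(fwd$permuted)), sort(as.integer(bytes)))
    expect_identical(bwt_inverse(fwd), bytes)
  }
})

test_that("repetitive input comes out in longer runs", {
  s <- strrep("ACGGTTCA", 512)   # low-entropy periodic block
  mean_run <- function(x) mean(rle(strsplit(x, "")[[1L]])$lengths)
  fwd <- bwt_forward(s)
  expect_gte(mean_run(rawToChar(fwd$permuted)), mean_run(s))
})

test_that("degenerate inputs are rejected", {
  expect_error(bwt_forward(raw(0)), class = "fqarc_structure_error")
  fwd <- bwt_forward("banana")
  expect_error(bwt_inverse(fwd$permuted, primary_index = 99L),
               class = "fqarc_corruption_error")
})
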