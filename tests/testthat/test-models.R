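test_that("an empty model predicts the uniform smoothed distribution", {
  m <- context_model(c("A", "C", "G", "T"), orders = 0L)
  p <- model_predict(m, 0L, character(0))
  expect_equal(unname(p), rep(0.25, 4))
})

test_that("observed continuations dominate the prediction", {
  m <- context_model(c("X", "Y"), orders = 4L)
  ctx <- c("A", "B", "C", "D")   # contexts may use symbols outside the coded alphabet
  for (i in 1:10) model_update(m, ctx, "X")
  model_update(m, ctx, "Y")
  p <- model_predict(m, 4L, ctx)
  expect_gt(p[["X"]], p[["Y"]])
  expect_equal(unname(p[["X"]]), 11 / 13)
})

test_that("count-and-smooth matches the closed form on a tiny history", {
  # history "ABAB": context "A" saw B twice; P(B|A) = (2+1)/(2+2)
  m <- context_model(c("A", "B"), orders = 1L)
  h <- c("A", "B", "A", "B")
  for (i in seq_along(h)) {
    model_update(m, if (i == 1L) character(0) else h[i - 1L], h[i])
  }
  p <- model_predict(m, 1L, "A")
  expect_equal(unname(p[["B"]]), 0.75)
})

test_that("context totals halve at the rescale cap and stay bounded", {
  m <- context_model(c("A", "B"), orders = 1L, cap = 256L)
  for (i in 1:255) model_update(m, "C", "A")
  cnt <- m$tables[["1"]][[fqarc:::ctx_key("C", 1L)]]
  expect_equal(sum(cnt), 255L)
  model_update(m, "C", "A")       # reaches the cap -> halving
  cnt <- m$tables[["1"]][[fqarc:::ctx_key("C", 1L)]]
  expect_equal(sum(cnt), 128L)
  for (i in 1:500) model_update(m, "C", sample(c("A", "B"), 1L))
  cnt <- m$tables[["1"]][[fqarc:::ctx_key("C", 1L)]]
  expect_lte(sum(cnt), 256L)
})

test_that("interleaved predict/update is reproducible run to run", {
  run <- function() {
    m <- context_model(c("A", "C", "G", "T"), orders = c(0L, 1L, 2L))
    h <- strsplit("ACGTACGGGTTACGATCG", "")[[1L]]
    out <- numeric(0)
    for (i in seq_along(h)) {
      ctx <- h[seq_len(i - 1L)]
      out <- c(out, model_predict(m, 2L, ctx))
      model_update(m, ctx, h[i])
    }
    out
  }
  expect_identical(run(), run())
})

test_that("the matching model proposes the continuation of the last match", {
  h <- strsplit("QQRSQQRSQQR", "")[[1L]]
  res <- match_predict(h, min_match = 3L)
  expect_identical(res$symbol, "S")
  expect_gt(res$confidence, 0)

  expect_null(match_predict(c("Q", "R"), min_match = 3L))
  expect_null(match_predict(strsplit("ABCDEFGH", "")[[1L]], min_match = 3L))

  # confidence grows with the matched run length
  short <- match_predict(strsplit("ABA", "")[[1L]], min_match = 1L)
  long <- match_predict(strsplit("ABCABCAB", "")[[1L]], min_match = 1L)
  expect_gt(long$confidence, short$confidence)
})

test_that("mixing is convex, permutation-invariant and degenerate-safe", {
  d1 <- c(0.7, 0.2, 0.1)
  d2 <- c(0.1, 0.1, 0.8)
  expect_equal(mix_distributions(list(d1, d1), c(2, 5)), d1)
  expect_equal(mix_distributions(list(d1, d2), c(1, 0)), d1)
  expect_equal(mix_distributions(list(d1, d2), c(0.5, 0.5)), (d1 + d2) / 2)
  expect_equal(mix_distributions(list(d1, d2), c(0.3, 0.7)),
               mix_distributions(list(d2, d1), c(0.7, 0.3)))
  expect_equal(sum(mix_distributions(list(d1, d2), c(0.123, 3))), 1)
  expect_error(mix_distributions(list(d1, d2), c(0, 0)),
               class = "fqarc_config_error")
})

test_that("weight adaptation rewards the better predictor but keeps a floor", {
  w <- c(0.5, 0.5)
  expect_equal(adapt_weights(w, c(0.3, 0.3)), w)
  for (i in 1:200) w <- adapt_weights(w, c(0.9, 0.1))
  expect_gte(w[1], 1 - 0.01 - 1e-9)
  expect_gte(w[2], 0.01 - 1e-12)
  set.seed(3)
  for (i in 1:50) {
    w <- adapt_weights(runif(4), runif(4, 0.01, 1))
    expect_true(all(w >= 0.01 / (1 + 4 * 0.01)))
    expect_equal(sum(w), 1)
  }
})

test_that("quantisation conserves the grid total and floors every symbol", {
  # exact multiples of the grid scale with every entry above the floor
  p <- c(8192, 4096, 4096) / 16384
  expect_identical(quantize_interpolate(p, 14L, 1L), c(8192L, 4096L, 4096L))
  f <- quantize_interpolate(c(0.5, 0.5, 0), 14L, 1L)
  expect_equal(f[3], 1L)
  expect_equal(sum(f), 16384L)
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1)); p <- p / sum(p)
    f <- quantize_interpolate(p, 14L, 1L)
    expect_equal(sum(f), 16384L)
    expect_true(all(f >= 1L))
  }
  expect_error(quantize_interpolate(rep(1 / 40, 40), grid_bits = 5L, floor = 1L),
               class = "fqarc_config_error")
})
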