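# Shared fixtures: the canonical worked-example record and generated corpora.

table1_text <- paste0(
  "@ERR194147.1.HSQ1004:134:C0D8DACXX:1:1104:3874:86,238/1\n",
  "GGTTCCTACTTNAGGGTCATTAAATAGCCCACACGTC\n",
  "+\n",
  "CC@FFFFFHHH#JJJFHIIJJJJJJJIJHIJJJJJJJ\n")

table1_identifier <- "ERR194147.1.HSQ1004:134:C0D8DACXX:1:1104:3874:86,238/1"
table1_bases <- "GGTTCCTACTTNAGGGTCATTAAATAGCCCACACGTC"
table1_quality <- "CC@FFFFFHHH#JJJFHIIJJJJJJJIJHIJJJJJJJ"

random_reads <- function(n, len, alphabet = c("A", "C", "G", "T"), seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

markov_quality_lines <- function(n, len, n_symbols, order = 2, alpha = 0.1,
                                 seed = 1) {
  syms <- fqarc:::quality_symbols(n_symbols)
  s <- generate_markov_sequence(n * len, order, alpha, syms, seed = seed)
  substring(s, seq(1, n * len, len), seq(len, n * len, len))
}

# in-memory sink whose put() fails transiently (first attempt per object)
flaky_sink <- function(inner, fail_times = 1L) {
  s <- new.env(parent = emptyenv())
  s$kind <- inner$kind
  s$attempts <- list()
  s$put <- function(name, data) {
    k <- if (is.null(s$attempts[[name]])) 0L else s$attempts[[name]]
    s$attempts[[name]] <- k + 1L
    if (k < fail_times) stop("transient sink outage")
    inner$put(name, data)
  }
  s$get <- inner$get
  s$object_offset <- inner$object_offset
  s$finalize <- inner$finalize
  s$discard <- inner$discard
  class(s) <- "fq_sink"
  s
}

# naive BWT oracle: sort all rotations of block + sentinel, keep last column
naive_bwt <- function(bytes) {
  t <- c(as.integer(bytes) + 1L, 0L)
  N <- length(t)
  rot <- vapply(seq_len(N), function(i) t[((seq_len(N) + i - 2L) %% N) + 1L],
                integer(N))     # column i = rotation starting at i-1
  ord <- do.call(order, as.data.frame(t(rot)))
  last <- rot[N, ord]
  primary <- which(last == 0L) - 1L
  list(permuted = as.raw(last[last != 0L] - 1L), primary_index = primary)
}

# naive inverse: iteratively prepend the last column and re-sort; row
# `primary` (0-based) of the final table is the original block + sentinel
naive_bwt_inverse <- function(permuted, primary) {
  N <- length(permuted) + 1L
  last <- integer(N)
  last[primary + 1L] <- 0L
  last[setdiff(seq_len(N), primary + 1L)] <- as.integer(permuted) + 1L
  tbl <- matrix(integer(0), nrow = N, ncol = 0)
  for (i in seq_len(N)) {
    tbl <- cbind(last, tbl)
    ord <- do.call(order, as.data.frame(tbl))
    tbl <- tbl[ord, , drop = FALSE]
  }
  row <- tbl[primary + 1L, ]
  as.raw(row[-N] - 1L)
}
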