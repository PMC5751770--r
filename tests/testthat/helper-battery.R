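# The fixture battery: corpora crossing read length, quality-alphabet size,
# Markov structure and newline dialect, plus one large corpus.

battery_specs <- function() {
  specs <- list()
  add <- function(...) specs[[length(specs) + 1L]] <<- fixture_spec(...)
  sd <- 100L
  for (rl in c(50L, 100L, 150L)) {
    for (qa in c(6L, 7L, 38L, 39L)) {
      sd <- sd + 1L
      add(n_records = 200L, read_length = rl, quality_alphabet = qa,
          base_alpha = 0.6, quality_order = 2L, quality_alpha = 0.4, seed = sd)
    }
  }
  add(n_records = 400L, read_length = 100L, crlf = TRUE, seed = 201)
  add(n_records = 400L, read_length = 100L, final_newline = FALSE, seed = 202)
  add(n_records = 300L, read_length = 60L, crlf = TRUE, final_newline = FALSE,
      quality_alphabet = 7L, seed = 203)
  add(n_records = 500L, read_length = c(30L, 140L), plus_rate = 0.1, seed = 204)
  add(n_records = 2000L, read_length = 50L, quality_alphabet = 6L,
      quality_order = 2L, quality_alpha = 0.2, base_alpha = 0.3, seed = 205)
  add(n_records = 1000L, read_length = 150L, quality_alphabet = 39L, seed = 206)
  add(n_records = 100L, read_length = 50L, quality_alphabet = 38L,
      base_alpha = 0.1, seed = 207)
  add(n_records = 100000L, read_length = 50L, quality_alphabet = 39L,
      base_alpha = 0.5, quality_order = 2L, quality_alpha = 0.4, seed = 208)
  specs
}
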