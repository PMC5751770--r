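# Deterministic synthetic-FASTQ generator. Corpora with controlled read
# length, base/quality Markov structure, quality-alphabet size (real
# datasets range from 6 binned Illumina 1.8+ levels to 39 Sanger levels)
# and identifier templates shaped like real instrument ids (constant run
# and instrument fields, an incrementing record counter, free-running
# tile/x/y coordinates) — so every metadata scheme, both stream codecs and
# the end-to-end pipeline can be exercised without downloading anything.

#' Specify a synthetic FASTQ corpus
#'
#' @param n_records Number of records.
#' @param read_length Fixed read length, or `c(min, max)` for
#'   variable-length reads.
#' @param base_order,base_alpha Order and transition sharpness of the
#'   Markov chain generating bases (`alpha = 1` is i.i.d. uniform; smaller
#'   alpha concentrates each context on a preferred successor).
#' @param quality_alphabet Number of distinct quality symbols (e.g. 6 for
#'   binned Illumina 1.8+, 39 for Sanger-range scores).
#' @param quality_order,quality_alpha Markov structure of the quality
#'   stream, as for bases.
#' @param crlf,final_newline Newline dialect of the serialised file.
#' @param plus_rate Fraction of records whose `+` line repeats the
#'   identifier (exercises the auxiliary stream's exception list).
#' @param seed Integer seed; identical specs generate identical bytes.
#' @param id_run,instrument,flowcell,lane Identifier template constants.
#' @return A list of class `fq_fixture_spec`.
#' @export
fixture_spec <- function(n_records, read_length = 100L,
                         base_order = 1L, base_alpha = 1,
                         quality_alphabet = 39L,
                         quality_order = 0L, quality_alpha = 1,
                         crlf = FALSE, final_newline = TRUE,
                         plus_rate = 0, seed = 1L,
                         id_run = "SIMR001", instrument = "SIMQ01",
                         flowcell = "C0SIMACXX", lane = 1L) {
  structure(list(n_records = as.integer(n_records),
                 read_length = as.integer(read_length),
                 base_order = as.integer(base_order),
                 base_alpha = base_alpha,
                 quality_alphabet = as.integer(quality_alphabet),
                 quality_order = as.integer(quality_order),
                 quality_alpha = quality_alpha,
                 crlf = isTRUE(crlf), final_newline = isTRUE(final_newline),
                 plus_rate = plus_rate, seed = as.integer(seed),
                 id_run = id_run, instrument = instrument,
                 flowcell = flowcell, lane = as.integer(lane)),
            class = "fq_fixture_spec")
}

quality_symbols <- function(m) {
  # small alphabets start at '#' (binned Illumina 1.8+ style), large ones
  # at '!' (Sanger offset 33)
  off <- if (m <= 8L) 35L else 33L
  vapply(off + seq_len(m) - 1L, function(x) rawToChar(as.raw(x)), character(1))
}

#' Generate a synthetic Markov text sequence
#'
#' Order-`order` Markov chain over `alphabet` with transition sharpness
#' `alpha`: each context draws uniformly with probability `alpha` and
#' otherwise emits its preferred successor (the previous symbol for order
#' 1, a context-hash for higher orders), so the conditional entropy
#' decreases as `alpha` approaches 0.
#'
#' @param length Sequence length.
#' @param order Context order (0 for i.i.d.).
#' @param alpha Transition sharpness in (0, 1].
#' @param alphabet Character vector of single symbols.
#' @param seed Integer seed.
#' @return A single string of `length` symbols.
#' @export
generate_markov_sequence <- function(length, order, alpha, alphabet, seed = 1L) {
  if (alpha <= 0 || alpha > 1) fq_config_error("alpha must be in (0, 1]")
  if (order < 0L) fq_config_error("order must be >= 0")
  bytes <- cpp_markov_bytes(length, as.integer(order), alpha,
                            charToRaw(paste(alphabet, collapse = "")), seed)
  rawToChar(bytes)
}

#' Generate a synthetic FASTQ corpus
#'
#' @param spec An `fq_fixture_spec`.
#' @param path Optional output path; when given, the bytes are written
#'   there.
#' @return Raw FASTQ bytes (invisibly when `path` is given).
#' @export
generate_fastq <- function(spec, path = NULL) {
  n <- spec$n_records
  if (n == 0L) {
    out <- raw(0)
    if (!is.null(path)) { writeBin(out, path); return(invisible(out)) }
    return(out)
  }
  set.seed(spec$seed)
  lens <- if (length(spec$read_length) == 2L) {
    sample(spec$read_length[1L]:spec$read_length[2L], n, replace = TRUE)
  } else {
    rep(spec$read_length[1L], n)
  }
  total <- sum(lens)
  bases_all <- rawToChar(cpp_markov_bytes(total, spec$base_order,
                                          spec$base_alpha, charToRaw("ACGT"),
                                          spec$seed * 7 + 1))
  qsyms <- quality_symbols(spec$quality_alphabet)
  qual_all <- rawToChar(cpp_markov_bytes(total, spec$quality_order,
                                         spec$quality_alpha,
                                         charToRaw(paste(qsyms, collapse = "")),
                                         spec$seed * 7 + 3))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  bases <- substring(bases_all, starts, ends)
  qual <- substring(qual_all, starts, ends)
  tile <- 1100L + sample.int(4L, n, replace = TRUE)
  x <- sample.int(99999L, n, replace = TRUE)
  y <- sample.int(99999L, n, replace = TRUE)
  extra <- sample.int(999L, n, replace = TRUE)
  ids <- sprintf("%s.%d.%s:%d:%s:%d:%d:%d:%d,%d/1",
                 spec$id_run, seq_len(n), spec$instrument, 134L,
                 spec$flowcell, spec$lane, tile, x, y, extra)
  plus <- rep("", n)
  if (spec$plus_rate > 0) {
    k <- which(runif(n) < spec$plus_rate)
    plus[k] <- ids[k]
  }
  rec <- new_fastq_records(ids, bases, plus, qual,
                           final_newline = spec$final_newline,
                           crlf = spec$crlf)
  out <- serialize_fastq(rec)
  if (!is.null(path)) { writeBin(out, path); return(invisible(out)) }
  out
}
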