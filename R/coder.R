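# User-facing surface of the arithmetic coder. The production stream codecs
# keep their models on the C++ side; these entry points expose the same coder
# for experimentation, oracles and the generic fallback paths.

#' Model descriptors for the arithmetic coder
#'
#' `static_model()` codes every symbol with one fixed integer frequency
#' table; `adaptive_order0()` starts from add-one counts over the alphabet
#' and updates after every coded symbol (counts halve when a total reaches
#' the rescale cap of 256). A plain R function can be used instead: it
#' receives the already-coded prefix (integer symbols, 1-based) and must
#' return the integer frequency table for the next position — the decoder
#' replays it against the identical history, so it must be deterministic.
#'
#' @param freqs Integer vector of symbol frequencies, all `>= 1`, summing to
#'   at most `2^16`.
#' @param alphabet_size Number of distinct symbols.
#' @return A model descriptor for [encode_symbols()] / [decode_symbols()].
#' @export
static_model <- function(freqs) {
  freqs <- as.integer(freqs)
  if (any(freqs < 1L)) fq_config_error("static_model: every symbol needs frequency >= 1")
  if (sum(as.numeric(freqs)) > 65536) fq_config_error("static_model: total exceeds 2^16")
  structure(list(kind = "static", freqs = freqs), class = "fq_coder_model")
}

#' @rdname static_model
#' @export
adaptive_order0 <- function(alphabet_size) {
  structure(list(kind = "order0", alphabet_size = as.integer(alphabet_size)),
            class = "fq_coder_model")
}

#' Arithmetic-code a symbol sequence
#'
#' Encodes `symbols` (integers in `1..alphabet_size`) into a compact payload
#' under `model`, and decodes it back. The payload is framed with a 4-byte
#' length so that a truncated payload is detected deterministically;
#' `frame = FALSE` yields the bare coder output (final-interval bits plus a
#' 2-byte tail guard).
#'
#' @param symbols Integer vector of 1-based symbols.
#' @param model A descriptor from [static_model()] / [adaptive_order0()], or
#'   a driver function (see [static_model()]).
#' @param frame Prepend the 4-byte length frame?
#' @return `encode_symbols()`: a raw payload. `decode_symbols()`: the integer
#'   symbol vector.
#' @export
encode_symbols <- function(symbols, model, frame = TRUE) {
  syms0 <- as.integer(symbols) - 1L
  core <- if (is.function(model)) {
    cpp_ac_encode_driver(syms0, function(h) as.integer(model(h)))
  } else if (inherits(model, "fq_coder_model") && model$kind == "static") {
    cpp_ac_encode_static(syms0, model$freqs)
  } else if (inherits(model, "fq_coder_model") && model$kind == "order0") {
    cpp_ac_encode_order0(syms0, model$alphabet_size)
  } else {
    fq_config_error("unknown coder model")
  }
  if (!frame) return(core)
  c(writeBin(length(core), raw(), size = 4L, endian = "big"), core)
}

#' @rdname encode_symbols
#' @param payload Raw payload produced by [encode_symbols()] with an
#'   identical model.
#' @param count Number of symbols to decode.
#' @export
decode_symbols <- function(payload, model, count, frame = TRUE) {
  if (frame) {
    if (length(payload) < 4L) fq_corruption_error("coder payload truncated")
    stored <- readBin(payload[1:4], "integer", size = 4L, endian = "big")
    if (length(payload) - 4L != stored) {
      fq_corruption_error(sprintf(
        "coder payload truncated: expected %d byte(s), found %d",
        stored, length(payload) - 4L))
    }
    payload <- payload[-(1:4)]
  }
  out <- tryCatch({
    if (is.function(model)) {
      cpp_ac_decode_driver(payload, function(h) as.integer(model(h)), count)
    } else if (inherits(model, "fq_coder_model") && model$kind == "static") {
      cpp_ac_decode_static(payload, model$freqs, count)
    } else if (inherits(model, "fq_coder_model") && model$kind == "order0") {
      cpp_ac_decode_order0(payload, model$alphabet_size, count)
    } else {
      fq_config_error("unknown coder model")
    }
  }, error = function(e) {
    if (inherits(e, "fqarc_error")) stop(e)
    fq_corruption_error(conditionMessage(e))
  })
  out + 1L
}

#' Shannon entropy of a distribution
#'
#' @param p Numeric vector of probabilities (normalised internally).
#' @return Entropy in bits per symbol.
#' @export
entropy_bits <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}
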