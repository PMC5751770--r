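# Structured conditions so callers (and the CLI exit-code mapping) can
# distinguish malformed input, corrupt archives, sink failures and bad ranges.

fq_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "fqarc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

fq_parse_error <- function(message, line = NA_integer_) {
  fq_abort("fqarc_parse_error", message, line = line)
}

fq_corruption_error <- function(message, block = NULL) {
  fq_abort("fqarc_corruption_error", message, block = block)
}

fq_sink_error <- function(message, object = NULL) {
  fq_abort("fqarc_sink_error", message, object = object)
}

fq_range_error <- function(message) {
  fq_abort("fqarc_range_error", message)
}

fq_structure_error <- function(message) {
  fq_abort("fqarc_structure_error", message)
}

fq_config_error <- function(message) {
  fq_abort("fqarc_config_error", message)
}
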