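# Burrows-Wheeler transform over block bytes. The transform sorts all
# rotations of the block (with an implicit sentinel smaller than every byte)
# and keeps the last column; symbols followed by similar contexts end up
# adjacent, turning genomic repeats into runs a low-order model codes well.

#' Burrows-Wheeler transform of a block
#'
#' @param block A raw vector or a length-1 character string; must be
#'   non-empty.
#' @return A list of class `fq_bwt` with `permuted` (raw, same multiset of
#'   bytes as the input) and `primary_index` (0-based row of the stripped
#'   sentinel, needed for inversion).
#' @export
#' @examples
#' b <- bwt_forward("banana")
#' rawToChar(bwt_inverse(b))
bwt_forward <- function(block) {
  if (is.character(block)) block <- charToRaw(block)
  if (length(block) == 0L) fq_structure_error("bwt_forward: empty block")
  res <- cpp_bwt_forward(block)
  res$primary_index <- as.integer(res$primary_index)
  class(res) <- "fq_bwt"
  res
}

#' Invert a Burrows-Wheeler transform
#'
#' @param b An `fq_bwt` object, or a raw vector (then `primary_index` must
#'   be given).
#' @param primary_index 0-based sentinel row recorded by [bwt_forward()].
#' @return The original block as a raw vector.
#' @export
bwt_inverse <- function(b, primary_index = NULL) {
  if (inherits(b, "fq_bwt")) {
    permuted <- b$permuted
    primary_index <- b$primary_index
  } else {
    permuted <- b
  }
  if (is.null(primary_index) || is.na(primary_index) ||
      primary_index < 0 || primary_index > length(permuted)) {
    fq_corruption_error("bwt_inverse: primary index out of range")
  }
  tryCatch(cpp_bwt_inverse(permuted, primary_index),
           error = function(e) fq_corruption_error(conditionMessage(e)))
}
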