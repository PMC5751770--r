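# Reference implementation of the adaptive context-modelling primitives:
# order-k prediction tables with add-one smoothing, a matching model,
# weighted mixing with multiplicative weight adaptation, and quantisation of
# a probability vector onto the coder's integer grid. The compiled stream
# codecs mirror this arithmetic; this surface is the documented, testable
# form of it.

BOUNDARY_SYMBOL <- "\x02"   # start-of-sequence context padding

#' Create an adaptive context model
#'
#' Maintains one count table per requested order. Contexts shorter than an
#' order (at sequence start) are padded with a reserved boundary symbol.
#' Counts at a context halve when the context total reaches `cap`, so the
#' model keeps adapting to local statistics.
#'
#' @param alphabet Character vector of single-symbol strings.
#' @param orders Integer vector of context orders to track.
#' @param cap Per-context count total that triggers halving.
#' @return An object of class `fq_context_model`.
#' @export
context_model <- function(alphabet, orders = c(0L, 1L), cap = 256L) {
  st <- new.env(parent = emptyenv())
  st$alphabet <- as.character(alphabet)
  st$orders <- sort(unique(as.integer(orders)))
  st$cap <- as.integer(cap)
  st$tables <- lapply(st$orders, function(k) new.env(parent = emptyenv()))
  names(st$tables) <- as.character(st$orders)
  class(st) <- "fq_context_model"
  st
}

ctx_key <- function(context, k) {
  context <- as.character(context)
  if (length(context) < k) {
    context <- c(rep(BOUNDARY_SYMBOL, k - length(context)), context)
  } else if (length(context) > k) {
    context <- context[(length(context) - k + 1L):length(context)]
  }
  paste0("k", if (k == 0L) "" else paste(context, collapse = "\x01"))
}

#' Predict the next-symbol distribution
#'
#' Add-one-smoothed relative frequencies of the symbols observed after
#' `context` at the given order; never zero for any alphabet symbol, so every
#' prediction is decodable.
#'
#' @param model An `fq_context_model`.
#' @param order Which tracked order to query.
#' @param context Character vector of preceding symbols (most recent last);
#'   shorter contexts are boundary-padded.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
model_predict <- function(model, order, context = character(0)) {
  order <- as.integer(order)
  tab <- model$tables[[as.character(order)]]
  if (is.null(tab)) fq_config_error(sprintf("order %d is not tracked", order))
  key <- ctx_key(context, order)
  cnt <- tab[[key]]
  if (is.null(cnt)) cnt <- rep(0L, length(model$alphabet))
  p <- (cnt + 1) / (sum(cnt) + length(model$alphabet))
  names(p) <- model$alphabet
  p
}

#' Record an observed symbol
#'
#' Increments the `(context, symbol)` cell of every tracked order (with
#' boundary padding as in [model_predict()]); a context whose total reaches
#' the cap has all its counts halved.
#'
#' @inheritParams model_predict
#' @param symbol The observed symbol (must be in the alphabet).
#' @return The model, invisibly (updated in place).
#' @export
model_update <- function(model, context, symbol) {
  i <- match(symbol, model$alphabet)
  if (is.na(i)) fq_config_error(sprintf("symbol '%s' not in alphabet", symbol))
  for (kc in as.character(model$orders)) {
    k <- as.integer(kc)
    tab <- model$tables[[kc]]
    key <- ctx_key(context, k)
    cnt <- tab[[key]]
    if (is.null(cnt)) cnt <- rep(0L, length(model$alphabet))
    cnt[i] <- cnt[i] + 1L
    if (sum(cnt) >= model$cap) cnt <- cnt %/% 2L
    tab[[key]] <- cnt
  }
  invisible(model)
}

#' Matching-model prediction
#'
#' Looks for the most recent earlier occurrence of the current
#' `min_match`-symbol context in `history`; if found, proposes the symbol
#' that followed it, with a confidence that grows with the length of the
#' matched context run.
#'
#' @param history Character vector of symbols seen so far (or one string).
#' @param min_match Minimum context length required for a match.
#' @return `NULL` when no match exists, otherwise
#'   `list(symbol =, confidence =)` with confidence in (0, 1).
#' @export
match_predict <- function(history, min_match = 6L) {
  if (length(history) == 1L && nchar(history) > 1L) {
    history <- strsplit(history, "", fixed = TRUE)[[1L]]
  }
  n <- length(history)
  if (n < min_match + 1L) return(NULL)
  ctx <- history[(n - min_match + 1L):n]
  # most recent earlier end-position of the same context
  for (p in seq.int(n - 1L, min_match, by = -1L)) {
    if (all(history[(p - min_match + 1L):p] == ctx)) {
      # extend the match backwards to measure the full run length
      m <- min_match
      while (p - m >= 1L && n - m >= 1L && history[p - m] == history[n - m]) {
        m <- m + 1L
      }
      return(list(symbol = history[p + 1L], confidence = m / (m + 1)))
    }
  }
  NULL
}

#' Mix predicted distributions
#'
#' Convex combination of distributions over a common alphabet with
#' normalised non-negative weights; invariant under permutation of the
#' (distribution, weight) pairs.
#'
#' @param dists List of numeric probability vectors of equal length.
#' @param weights Numeric weights, at least one positive.
#' @return A probability vector summing to 1.
#' @export
mix_distributions <- function(dists, weights) {
  if (length(dists) != length(weights)) {
    fq_config_error("one weight per distribution required")
  }
  if (all(weights <= 0)) fq_config_error("at least one positive mixing weight required")
  w <- weights / sum(weights)
  out <- Reduce(`+`, Map(function(d, wi) wi * d, dists, w))
  out / sum(out)
}

#' Adapt mixing weights
#'
#' Multiplicative update: each weight is scaled by the probability its model
#' assigned to the symbol actually coded (raised to `gamma`), renormalised,
#' floored at `floor` and renormalised again. Models that predict well gain
#' weight; no model's weight ever falls below the floor, so a model can
#' recover when the local statistics change.
#'
#' @param weights Current weights.
#' @param probs Per-model probability assigned to the coded symbol, in (0,1].
#' @param gamma Update exponent.
#' @param floor Minimum weight.
#' @return Updated, normalised weights.
#' @export
adapt_weights <- function(weights, probs, gamma = 1, floor = 0.01) {
  w <- weights * probs^gamma
  w <- w / sum(w)
  low <- w < floor
  if (any(low)) {
    added <- sum(floor - w[low])
    w[low] <- floor
    i <- which.max(w)
    w[i] <- w[i] - added
  }
  w
}

#' Quantise a distribution onto the coder grid
#'
#' Maps probabilities to integer counts summing to exactly `2^grid_bits`,
#' with every symbol receiving at least `floor` counts (the interpolation
#' step: zero-probability symbols keep coding mass so any symbol remains
#' decodable). Rounding residue is pushed onto the largest entries.
#'
#' @param p Numeric probability vector.
#' @param grid_bits Log2 of the target total.
#' @param floor Minimum integer count per symbol.
#' @return Integer vector of counts summing to `2^grid_bits`.
#' @export
quantize_interpolate <- function(p, grid_bits = 14L, floor = 1L) {
  A <- length(p)
  G <- 2L^as.integer(grid_bits)
  if (A * floor > G) {
    fq_config_error("alphabet size times floor exceeds the grid total")
  }
  p <- p / sum(p)
  f <- pmax(as.integer(round(p * G)), floor)
  resid <- G - sum(f)
  while (resid != 0L) {
    if (resid > 0L) {
      i <- which.max(f)
      f[i] <- f[i] + resid
      resid <- 0L
    } else {
      adj <- which(f > floor)
      i <- adj[which.max(f[adj])]
      take <- min(f[i] - floor, -resid)
      f[i] <- f[i] - take
      resid <- resid + take
    }
  }
  f
}
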