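# internal helpers shared across the optimizers and the experiment harness

# elementwise box clipping (the only boundary policy offered)
clip_bounds <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# evaluate an objective over the rows of a matrix
eval_rows <- function(objective, mat) {
  n <- nrow(mat)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- objective(mat[i, ])
  out
}

#' Derive a reproducible seed from a root seed and labels
#'
#' Experiment cells (algorithm x problem x run) get their own seed by
#' hashing the labels into the root seed with a 31-multiplier string hash
#' modulo 2^31 - 1, so published runs are replayable and independent of
#' execution order.
#'
#' @param root Integer root seed.
#' @param ... Labels (coerced to character) folded into the hash.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(root, ...) {
  h <- as.numeric(root) %% 2147483647
  for (tok in as.character(unlist(list(...)))) {
    for (b in utf8ToInt(tok)) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# resolve a possibly-missing seed; NULL draws one from the session RNG
resolve_seed <- function(seed) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  as.integer(seed)
}

# lightweight population container used inside the optimizer loops:
# positions (N x D), values (length N), and whether rows are sorted
# ascending by value (row 1 = incumbent best, row 2 = second best)
new_population <- function(pos, val, sorted = FALSE) {
  list(pos = pos, val = val, sorted = sorted)
}

sort_population <- function(pop) {
  ord <- order(pop$val)   # stable: earlier habitat entries win ties
  new_population(pop$pos[ord, , drop = FALSE], pop$val[ord], sorted = TRUE)
}
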