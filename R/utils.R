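# Small internal helpers shared across modules.

# Clamp predicted probabilities away from 0/1 before taking logs.
# Values outside [eps, 1 - eps] are pulled to the boundary; callers that care
# can ask for a count of clamped entries via attribute.
clamp_unit <- function(u, eps = 1e-7) {
  pmin(pmax(u, eps), 1 - eps)
}

# Stop with a classed error so tests can match on class rather than message.
vq_abort <- function(message, class) {
  abort(message, class = c(class, "vqtarget_error"))
}

assert_unique_ids <- function(ids, what, class) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    vq_abort(
      sprintf("duplicate %s id(s): %s", what, paste(dup, collapse = ", ")),
      class
    )
  }
  invisible(ids)
}

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise draw from the ambient stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
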