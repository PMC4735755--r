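## Internal helpers: seed derivation and seeded evaluation.

# 2^31 - 1; all derived seeds stay below this so they remain valid R integers.
.SEED_MOD <- 2147483647

#' Derive a reproducible child seed from a base seed and integer coordinates
#'
#' Mixes the base seed with any number of integer tags (condition index, grid
#' coordinates, ...) through a multiplicative-congruential hash so that every
#' stochastic step of a run has its own stable stream.
#'
#' @param seed Base integer seed.
#' @param ... Integer tags identifying the consumer.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- as.double(c(...))
  h <- as.double(seed) %% .SEED_MOD
  for (p in parts) {
    h <- (h * 48271 + p + 11) %% .SEED_MOD
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .SEED_MOD), code)
}

# Largest-magnitude entry of each column made positive; reproducible across
# eigensolver sign ambiguity.
fix_signs <- function(mat) {
  if (ncol(mat) == 0L) return(mat)
  flip <- apply(mat, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(mat, 2L, flip, `*`)
}

# Property name -> two-letter condition code used throughout the results.
property_code <- function(property) {
  codes <- c(identity = "ID", sex = "SE", race = "RA", expression = "EX")
  if (!property %in% names(codes)) {
    abort(paste0("unknown facial property '", property, "'; expected one of ",
                 paste(names(codes), collapse = ", ")))
  }
  unname(codes[property])
}

condition_label <- function(train_property, test_property) {
  paste0(property_code(train_property), ":", property_code(test_property))
}
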