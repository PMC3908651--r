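# Brute-force oracles used across the suite.  These deliberately follow the
# definitions literally (full enumeration), independent of the package's
# dynamic programs and scanning kernels.

# Distribution of the symmetric set distance between C and the character set
# of a random string of length L, by enumerating all |ids|^L strings.
enum_distance_distribution <- function(prob, ids, C, L) {
  grid <- do.call(expand.grid, rep(list(seq_along(ids)), L))
  out <- numeric(length(C) + length(ids) + 1L)
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    w <- prod(prob[idx])
    cs <- unique(ids[idx])
    d <- length(setdiff(C, cs)) + length(setdiff(cs, C))
    out[d + 1L] <- out[d + 1L] + w
  }
  out
}

# Probability that a random string of length l over alphabet 'ids' with
# probabilities 'prob' misses exactly d of the characters in C.
enum_missing <- function(prob, ids, C, l) {
  out <- numeric(length(C) + 1L)
  if (l == 0) {
    out[length(C) + 1L] <- 1
    return(out)
  }
  grid <- do.call(expand.grid, rep(list(seq_along(ids)), l))
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    miss <- length(setdiff(C, ids[idx]))
    out[miss + 1L] <- out[miss + 1L] + prod(prob[idx])
  }
  out
}

# Probability of exactly h distinct characters in a random string of
# length l over alphabet 'ids' with probabilities 'prob'.
enum_distinct <- function(prob, ids, l) {
  out <- numeric(length(ids) + 1L)
  if (l == 0) {
    out[1L] <- 1
    return(out)
  }
  grid <- do.call(expand.grid, rep(list(seq_along(ids)), l))
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    h <- length(unique(idx))
    out[h + 1L] <- out[h + 1L] + prod(prob[idx])
  }
  out
}

# All delta-locations of C in an integer vector, by literal definition.
enum_delta_locations <- function(S, C, delta) {
  out <- NULL
  n <- length(S)
  for (a in seq_len(n)) for (b in a:n) {
    cs <- unique(S[a:b])
    d <- length(setdiff(C, cs)) + length(setdiff(cs, C))
    if (d <= delta && length(intersect(C, cs)) > 0)
      out <- rbind(out, c(a = a, b = b, distance = d))
  }
  out
}

# Random single-chromosome frequency model where every gene occurs.
random_model <- function(sigma, n) {
  frequency_model(c(seq_len(sigma), sample(sigma, n - sigma, replace = TRUE)))
}

# Force a component's random-string length.
with_length <- function(model, n) {
  comp <- model$components[[1L]]
  comp$n <- as.integer(n)
  comp
}
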