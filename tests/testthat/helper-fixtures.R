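# Shared fixtures, built in code.

tiny_phantom <- function(shape = c(16L, 16L), n_channels = 2L, noise_cv = 0.1,
                         seed = 1L) {
  generate_phantom(phantom_spec(shape = shape, n_channels = n_channels,
                                noise_cv = noise_cv, seed = seed))
}

# a two-region step image: left half low, right half high
step_image <- function(n = 8L, m = 8L, lo = 1, hi = 10) {
  img <- matrix(lo, n, m)
  img[, (m %/% 2 + 1):m] <- hi
  img
}

# measurement state with a given random mask over a single-channel image
masked_state <- function(img, fraction, seed = 1L) {
  st <- new_measurement_state(dim(img), "x")
  measure(st, random_mask(dim(img), fraction, seed = seed),
          channel_stack(array(img, c(dim(img), 1L))))
}

# independent brute-force argmax over unmeasured pixels with lexicographic
# (row, col) tie-break
argmax_oracle <- function(erd, measured) {
  best <- NULL
  best_val <- -Inf
  for (r in seq_len(nrow(erd))) {
    for (cc in seq_len(ncol(erd))) {
      if (measured[r, cc]) next
      if (erd[r, cc] > best_val) {
        best_val <- erd[r, cc]
        best <- c(r, cc)
      }
    }
  }
  best
}

# independent exhaustive Otsu: evaluates the between-class variance of every
# split between consecutive distinct sorted values directly from class
# means/weights and returns the selected (above-threshold) subset
otsu_oracle_partition <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2) return(NULL)
  best_sb <- -Inf
  best_cut <- NULL
  for (i in seq_len(length(v) - 1)) {
    cut <- (v[i] + v[i + 1]) / 2
    g0 <- values[values <= cut]
    g1 <- values[values > cut]
    sb <- (length(g0) / length(values)) * (length(g1) / length(values)) *
      (mean(g0) - mean(g1))^2
    if (sb > best_sb) {
      best_sb <- sb
      best_cut <- cut
    }
  }
  values > best_cut
}
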