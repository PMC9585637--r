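# Internal helpers shared across modules.

# Deterministic child seed derivation; keeps results < 2^31 - 1 so they are
# valid R integer seeds.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629 + 1)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x) && x >= 0

check_shape <- function(shape, what = "shape") {
  if (!is.numeric(shape) || length(shape) != 2 || any(!is.finite(shape)) ||
      any(shape < 1) || any(shape != floor(shape))) {
    abort(sprintf("`%s` must be two positive integers (N rows, M columns).", what))
  }
  as.integer(shape)
}

# linear (column-major) index of pixel (row, col) on an N x M grid
px_index <- function(row, col, n_rows) (col - 1L) * n_rows + row

# inverse of px_index
px_rowcol <- function(idx, n_rows) {
  idx <- as.integer(idx)
  row <- ((idx - 1L) %% n_rows) + 1L
  col <- ((idx - 1L) %/% n_rows) + 1L
  tibble(row = row, col = col)
}

# normalise a pixel-set argument (tibble/data.frame with row, col) to a
# validated integer tibble
as_pixel_set <- function(locations, shape) {
  if (is.null(locations) || NROW(locations) == 0) {
    abort("empty pixel selection")
  }
  if (!all(c("row", "col") %in% names(locations))) {
    abort("pixel locations need `row` and `col` columns")
  }
  row <- as.integer(locations$row)
  col <- as.integer(locations$col)
  if (any(row < 1L) || any(row > shape[1]) || any(col < 1L) || any(col > shape[2])) {
    abort("pixel locations out of grid bounds")
  }
  out <- tibble(row = row, col = col)
  if (anyDuplicated(px_index(row, col, shape[1]))) {
    abort("duplicate pixel locations")
  }
  out
}
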