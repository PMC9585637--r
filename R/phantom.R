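#' Multi-channel ion-image stack
#'
#' A `channel_stack` holds `d` co-registered `N x M` ion-intensity images,
#' one per m/z channel — either fully measured ground truth or a sparse
#' reconstruction. Intensities are nonnegative, in arbitrary ion-count units.
#'
#' @param data numeric array of dimension `c(N, M, d)` (rows are scan lines,
#'   columns are along-line pixels) or an `N x M` matrix for `d = 1`.
#' @param channel_labels character vector of `d` unique channel identifiers
#'   (conventionally nominal m/z strings). Defaults to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `channel_stack` with fields `data` (N x M x d
#'   array) and `channel_labels`.
#' @export
channel_stack <- function(data, channel_labels = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be an N x M x d array (or an N x M matrix).")
  }
  dm <- dim(data)
  if (dm[1] < 2 || dm[2] < 2 || dm[3] < 1) {
    abort("a channel stack needs N >= 2, M >= 2 and d >= 1.")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    abort("all intensities must be finite and >= 0.")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dm[3]))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != dm[3] || anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique and of length d.")
  }
  structure(
    list(data = data, channel_labels = channel_labels),
    class = "channel_stack"
  )
}

#' @export
dim.channel_stack <- function(x) dim(x$data)

#' Number of channels in a stack
#' @param x a [channel_stack()].
#' @return integer channel count.
#' @export
n_channels <- function(x) dim(x$data)[3]

#' @export
print.channel_stack <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<channel_stack> %d x %d pixels, %d channel(s)\n", dm[1], dm[2], dm[3]))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Specification of a synthetic tissue phantom
#'
#' Describes a tissue-like multi-channel phantom with nested anatomical
#' regions on an off-tissue background: an outer ring, an inner region and a
#' core (analogues of cortex, inner cortex and medulla in a kidney section).
#' Different channels are enhanced in different regions, mimicking ion images
#' whose species localise to distinct anatomical structures, e.g. one lipid
#' concentrated in the inner cortex and another enhanced in the medulla.
#'
#' @param shape integer `c(N, M)` grid size.
#' @param n_channels number of m/z channels to synthesise.
#' @param region_layout list with `semi_axes`, a decreasing sequence of three
#'   fractions of the half-extent giving the outer, middle and inner ellipse
#'   sizes. Default `c(0.45, 0.30, 0.15)`.
#' @param channel_region_weights `n_channels x 4` matrix of mean intensity per
#'   region, columns ordered (background, ring, inner, core). Default: each
#'   channel is enhanced (weight 1) in one tissue region in rotation, weight
#'   0.3 in the other tissue regions, 0.05 off tissue.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   pixel noise; 0 gives the noiseless piecewise-constant template.
#' @param seed integer seed making the generated stack deterministic.
#'
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(64L, 64L), n_channels = 6L,
                         region_layout = list(semi_axes = c(0.45, 0.30, 0.15)),
                         channel_region_weights = NULL,
                         noise_cv = 0.1, seed = 1L) {
  shape <- check_shape(shape)
  if (!is_count(n_channels) || n_channels < 1) abort("`n_channels` must be >= 1.")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0) {
    abort("`noise_cv` must be a nonnegative scalar.")
  }
  ax <- region_layout$semi_axes
  if (is.null(ax) || length(ax) != 3 || any(diff(ax) >= 0) || any(ax <= 0) || any(ax > 0.5)) {
    abort("`region_layout$semi_axes` must be three decreasing fractions in (0, 0.5].")
  }
  if (is.null(channel_region_weights)) {
    w <- matrix(0.3, nrow = n_channels, ncol = 4)
    w[, 1] <- 0.05
    for (c in seq_len(n_channels)) w[c, 2L + (c - 1L) %% 3L] <- 1
    channel_region_weights <- w
  }
  channel_region_weights <- as.matrix(channel_region_weights)
  if (!identical(dim(channel_region_weights), c(as.integer(n_channels), 4L)) ||
      any(channel_region_weights < 0)) {
    abort("`channel_region_weights` must be a nonnegative n_channels x 4 matrix.")
  }
  if (any(rowSums(channel_region_weights[, -1, drop = FALSE]) == 0)) {
    abort("every channel needs nonzero enhancement in at least one tissue region.")
  }
  structure(
    list(shape = shape, n_channels = as.integer(n_channels),
         region_layout = region_layout,
         channel_region_weights = channel_region_weights,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Region label map of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return integer `N x M` matrix with 0 = background, 1 = outer ring,
#'   2 = inner region, 3 = core.
#' @export
phantom_regions <- function(spec) {
  n <- spec$shape[1]; m <- spec$shape[2]
  # normalised coordinates in [-1, 1], ellipse axes aligned with the grid
  y <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  x <- (seq_len(m) - (m + 1) / 2) / (m / 2)
  r2 <- outer(y^2, x^2, `+`)  # squared radius of the unit circle
  ax <- spec$region_layout$semi_axes * 2  # fractions of half-extent -> unit radius
  reg <- matrix(0L, n, m)
  reg[r2 <= ax[1]^2] <- 1L
  reg[r2 <= ax[2]^2] <- 2L
  reg[r2 <= ax[3]^2] <- 3L
  reg
}

#' Generate a synthetic multi-channel MSI phantom
#'
#' Builds the ground-truth stack from the region template: channel `c` has
#' mean intensity `channel_region_weights[c, r]` in region `r`, corrupted by
#' multiplicative lognormal noise with coefficient of variation `noise_cv`
#' and a small nonnegative additive floor that scales with `noise_cv` (so the
#' noiseless phantom equals the template exactly). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A [channel_stack()].
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  n <- spec$shape[1]; m <- spec$shape[2]; d <- spec$n_channels
  reg <- phantom_regions(spec)
  out <- array(0, dim = c(n, m, d))
  cv <- spec$noise_cv
  sdlog <- sqrt(log1p(cv^2))
  withr::with_seed(spec$seed, {
    for (c in seq_len(d)) {
      template <- matrix(spec$channel_region_weights[c, reg + 1L], n, m)
      if (cv > 0) {
        noise <- matrix(exp(rnorm(n * m, mean = -sdlog^2 / 2, sd = sdlog)), n, m)
        floor_amp <- 0.02 * cv * max(template)
        additive <- matrix(abs(rnorm(n * m, 0, floor_amp)), n, m)
        template <- template * noise + additive
      }
      out[, , c] <- template
    }
  })
  channel_stack(out, paste0("mz", sprintf("%03d", seq_len(d))))
}

#' Uniform random sampling mask
#'
#' Draws `round(fraction * N * M)` distinct pixel locations uniformly without
#' replacement (rounding half away from zero, never fewer than one pixel).
#' Used both for sampling-policy initialisation and to resample fully
#' measured data to densities of 1--30% when building training sets.
#'
#' @param shape integer `c(N, M)`.
#' @param fraction sampling density in (0, 1].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return tibble with columns `row`, `col`.
#' @export
random_mask <- function(shape, fraction, seed = 1L) {
  shape <- check_shape(shape)
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  total <- prod(shape)
  n_pick <- max(1L, as.integer(round_half_up(fraction * total)))
  idx <- withr::with_seed(as.integer(seed), sample.int(total, n_pick))
  px_rowcol(sort(idx), shape[1])
}
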