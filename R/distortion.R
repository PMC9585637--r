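#' Ground-truth reduction-in-distortion (RD) training label
#'
#' The RD of a location is the decrease in total reconstruction error that
#' measuring it would produce. Computing that exactly for every pixel costs
#' one reconstruction per pixel, so training labels use the dense surrogate
#' from the SLADS/DLADS lineage: the per-pixel absolute reconstruction error
#' `|truth - reconstruction|`, smoothed by a Gaussian window whose width
#' tracks local sampling sparsity (per-pixel sigma = distance to the nearest
#' measured pixel, kernel truncated at 3 sigma and left unnormalised so the
#' label grows with the measurement's area of influence), then zeroed at
#' measured locations. [rd_exact()] is the slow exact oracle it is validated
#' against.
#'
#' @param truth_channel `N x M` ground-truth ion image.
#' @param state a `measurement_state` with >= 1 measured location.
#' @param recon optional precomputed reconstruction of this channel (saves
#'   the interpolation when the caller already has it).
#' @param sigma_cap upper bound on the per-pixel Gaussian sigma, in pixels.
#' @param normalize if `TRUE`, rescale the map by its maximum (when > 0), the
#'   form used for network training targets.
#' @param dmap optional precomputed distance-to-nearest-measured map (saves
#'   the distance transform when the caller already has it).
#' @return `N x M` nonnegative matrix with attributes `density` and `kind`
#'   (`"filtered_label"`); zero at measured locations.
#' @export
rd_label <- function(truth_channel, state, recon = NULL, sigma_cap = 8,
                     normalize = FALSE, dmap = NULL) {
  stopifnot(inherits(state, "measurement_state"))
  truth_channel <- as.matrix(truth_channel)
  if (!identical(dim(truth_channel), as.integer(state$shape))) {
    abort("truth channel shape does not match the measurement state")
  }
  if (!any(state$measured)) abort("need at least one measured location")
  if (is.null(recon)) {
    ch <- 1L
    # reconstruct from the truth values at the measured mask of `state`
    tmp <- new_measurement_state(state$shape, "x")
    tmp$measured <- state$measured
    tmp$values[, , 1][state$measured] <- truth_channel[state$measured]
    recon <- reconstruct_channel(tmp, 1L)
  } else {
    recon <- as.matrix(recon)
  }
  err <- abs(truth_channel - recon)
  err[state$measured] <- 0
  out <- gaussian_filter_adaptive(err, state$measured, sigma_cap = sigma_cap,
                                  dmap = dmap)
  out[state$measured] <- 0
  out[out < 0] <- 0
  if (normalize) {
    mx <- max(out)
    if (mx > 0) out <- out / mx
  }
  attr(out, "density") <- sampling_density(state)
  attr(out, "kind") <- "filtered_label"
  out
}

# Separable Gaussian blur with replicate (edge-extend) boundary; the kernel
# is truncated at 3 sigma and works for kernels larger than the image. With
# `normalize = FALSE` the kernel keeps unit peak height, so the result is a
# local error *sum* over the window rather than a mean — a wider window
# (sparser sampling) then yields a larger value, reflecting the larger area
# of influence of a measurement there.
gaussian_blur_replicate <- function(img, sigma, normalize = TRUE) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  if (normalize) k <- k / sum(k)
  blur_rows <- function(m) {
    n <- nrow(m)
    padded <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

# Spatially adaptive Gaussian smoothing: each pixel's sigma is its Euclidean
# distance to the nearest measured pixel (>= 1), so smoothing widens where
# sampling is sparse. Implemented as a small stack of fixed-sigma blurs
# indexed by the rounded distance map (EBImage provides the distance
# transform).
gaussian_filter_adaptive <- function(img, measured, sigma_cap = 8, dmap = NULL) {
  if (all(measured)) return(img * 0)
  if (is.null(dmap)) dmap <- as.matrix(EBImage::distmap(EBImage::Image(1 - measured)))
  sig <- pmin(pmax(round(dmap), 1), sigma_cap)
  levels <- sort(unique(sig[!measured]))
  out <- matrix(0, nrow(img), ncol(img))
  for (s in levels) {
    blurred <- gaussian_blur_replicate(img, s, normalize = FALSE)
    sel <- sig == s & !measured
    out[sel] <- blurred[sel]
  }
  out
}

#' Exact reduction in distortion of a single candidate measurement
#'
#' Brute-force oracle: the drop in total absolute reconstruction error from
#' measuring `location`, i.e. `sum(|truth - rec_without|) -
#' sum(|truth - rec_with|)`, clamped at zero. Re-runs the reconstruction, so
#' it is intended for small grids and tests; the unclamped value is attached
#' as attribute `"unclamped"` for diagnostics.
#'
#' @inheritParams rd_label
#' @param location one-row tibble/data.frame with `row`, `col` of an
#'   unmeasured pixel.
#' @return nonnegative scalar.
#' @export
rd_exact <- function(truth_channel, state, location) {
  stopifnot(inherits(state, "measurement_state"))
  truth_channel <- as.matrix(truth_channel)
  loc <- as_pixel_set(location, state$shape)
  if (nrow(loc) != 1) abort("`location` must be a single pixel")
  if (state$measured[loc$row, loc$col]) {
    abort("RD is defined only for unmeasured locations")
  }
  base <- new_measurement_state(state$shape, "x")
  base$measured <- state$measured
  base$values[, , 1][state$measured] <- truth_channel[state$measured]
  rec0 <- reconstruct_channel(base, 1L)
  with_st <- measure(base, loc, matrix(truth_channel[loc$row, loc$col], 1, 1))
  rec1 <- reconstruct_channel(with_st, 1L)
  raw <- sum(abs(truth_channel - rec0)) - sum(abs(truth_channel - rec1))
  structure(max(raw, 0), unclamped = raw)
}

#' Assemble a network training set from fully measured stacks
#'
#' For every stack x density, one random mask is drawn (all channels of a
#' stack share a mask, as they would in a real acquisition); for every
#' channel this yields one training sample whose input is the three-array
#' triple (reconstruction, measured values, measured-location indicator) and
#' whose target is the Gaussian-filtered RD label, formed independently per
#' channel. Default densities are 1--30% at 1% intervals.
#'
#' Per-sample normalisation (when `normalize = TRUE`): the reconstruction and
#' measured-value arrays are divided by the maximum measured intensity of the
#' channel, and the target by its own maximum — making training invariant to
#' the instrument intensity scale.
#'
#' @param stacks list of [channel_stack()] ground truths.
#' @param densities sampling densities in (0, 1); default `seq(0.01, 0.30, 0.01)`.
#' @param seed integer; the sample set is identical across runs for a fixed seed.
#' @param normalize apply the per-sample normalisation above.
#' @param sigma_cap passed to [rd_label()].
#' @return list of samples, each `list(input = list(recon, values, mask),
#'   target, meta)` with `meta` a tibble row (stack, channel, density, seed).
#' @export
build_training_set <- function(stacks, densities = seq(0.01, 0.30, by = 0.01),
                               seed = 1L, normalize = TRUE, sigma_cap = 8) {
  if (!is.list(stacks) || length(stacks) == 0) {
    abort("`stacks` must be a non-empty list of channel stacks")
  }
  if (inherits(stacks, "channel_stack")) stacks <- list(stacks)
  if (any(densities <= 0 | densities > 1)) abort("densities must lie in (0, 1]")
  samples <- list()
  n_out <- 0L
  for (si in seq_along(stacks)) {
    stack <- stacks[[si]]
    stopifnot(inherits(stack, "channel_stack"))
    shape <- dim(stack$data)[1:2]
    d <- n_channels(stack)
    for (di in seq_along(densities)) {
      mask_seed <- child_seed(seed, si * 1000L + di)
      loc <- random_mask(shape, densities[di], seed = mask_seed)
      st <- new_measurement_state(shape, stack$channel_labels)
      st <- measure(st, loc, stack, iteration = 0L)
      recon <- reconstruct_all(st)
      for (c in seq_len(d)) {
        truth_c <- stack$data[, , c]
        target <- rd_label(truth_c, st, recon = recon$data[, , c],
                           sigma_cap = sigma_cap, normalize = normalize)
        vals <- st$values[, , c]
        vals[!st$measured] <- 0
        rec_c <- recon$data[, , c]
        if (normalize) {
          mx <- max(vals)
          if (mx > 0) {
            vals <- vals / mx
            rec_c <- rec_c / mx
          }
        }
        n_out <- n_out + 1L
        samples[[n_out]] <- list(
          input = list(recon = rec_c, values = vals,
                       mask = state_mask_numeric(st)),
          target = target,
          meta = tibble(stack = si, channel = c, density = densities[di],
                        seed = mask_seed)
        )
      }
    }
  }
  samples
}

state_mask_numeric <- function(state) {
  matrix(as.numeric(state$measured), state$shape[1], state$shape[2])
}
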