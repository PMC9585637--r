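#' Measurement state of a sparse-sampling run
#'
#' Tracks the partition of the grid into measured locations `S` and
#' unmeasured locations `T`, the measured ion intensities per channel, and
#' the order in which locations were acquired.
#'
#' @param shape integer `c(N, M)` grid size.
#' @param channel_labels character vector of channel identifiers.
#' @return A `measurement_state` with an all-unmeasured grid. Fields:
#'   `shape`, `measured` (N x M logical), `values` (N x M x d, `NA` where
#'   unmeasured) and `order` (tibble of `iteration`, `row`, `col`).
#' @export
new_measurement_state <- function(shape, channel_labels) {
  shape <- check_shape(shape)
  d <- length(channel_labels)
  if (d < 1) abort("need at least one channel label")
  structure(
    list(
      shape = shape,
      channel_labels = as.character(channel_labels),
      measured = matrix(FALSE, shape[1], shape[2]),
      values = array(NA_real_, dim = c(shape[1], shape[2], d)),
      order = tibble(iteration = integer(), row = integer(), col = integer())
    ),
    class = "measurement_state"
  )
}

#' Sampling density of a state
#' @param state a `measurement_state`.
#' @return fraction of grid pixels measured so far, in `[0, 1]`.
#' @export
sampling_density <- function(state) {
  sum(state$measured) / prod(state$shape)
}

#' @export
print.measurement_state <- function(x, ...) {
  cat(sprintf(
    "<measurement_state> %d x %d, %d channel(s), %d measured (%.1f%%)\n",
    x$shape[1], x$shape[2], length(x$channel_labels),
    sum(x$measured), 100 * sampling_density(x)
  ))
  invisible(x)
}

#' Record measurements at a set of pixel locations
#'
#' Imports the ground-truth (or instrument-delivered) intensities at the
#' selected locations into the state. Attempting to re-measure an already
#' measured location is an error, since it indicates a selection-policy bug.
#'
#' @param state a [new_measurement_state()].
#' @param locations tibble/data.frame with `row`, `col` of currently
#'   unmeasured pixels; must be non-empty.
#' @param truth a [channel_stack()] the values are read from, or a plain
#'   `n x d` matrix of per-location values aligned with `locations`.
#' @param iteration iteration index recorded in the measurement log.
#' @return The updated `measurement_state` (density strictly increased).
#' @export
measure <- function(state, locations, truth, iteration = NULL) {
  stopifnot(inherits(state, "measurement_state"))
  loc <- as_pixel_set(locations, state$shape)
  idx <- px_index(loc$row, loc$col, state$shape[1])
  if (any(state$measured[idx])) {
    abort("attempt to re-measure an already measured location (policy bug?)")
  }
  d <- length(state$channel_labels)
  nm <- prod(state$shape)
  if (inherits(truth, "channel_stack")) {
    if (!identical(dim(truth$data)[1:2], as.integer(state$shape)) ||
        dim(truth$data)[3] != d) {
      abort("`truth` shape does not match the measurement state")
    }
    vals <- matrix(truth$data, nm, d)[idx, , drop = FALSE]
  } else {
    vals <- as.matrix(truth)
    if (nrow(vals) != nrow(loc) || ncol(vals) != d) {
      abort("per-location value matrix must be n_locations x d")
    }
  }
  if (is.null(iteration)) {
    iteration <- if (nrow(state$order)) max(state$order$iteration) + 1L else 0L
  }
  state$measured[idx] <- TRUE
  vmat <- matrix(state$values, nm, d)
  vmat[idx, ] <- vals
  state$values <- array(vmat, dim = c(state$shape, d))
  state$order <- dplyr::bind_rows(
    state$order,
    tibble(iteration = as.integer(iteration), row = loc$row, col = loc$col)
  )
  state
}

# Shared neighbour search for IDW interpolation: k nearest measured
# neighbours of every unmeasured pixel, with weights 1 / (dist^2 + eps).
# aspect scales (row, col) pixel units for anisotropic grids.
idw_neighbours <- function(state, k = 10L, eps = 1e-12, aspect = c(1, 1)) {
  meas_idx <- which(state$measured)
  if (length(meas_idx) == 0) abort("cannot interpolate: no measured locations")
  unmeas_idx <- which(!state$measured)
  n <- state$shape[1]
  k_eff <- min(k, length(meas_idx))
  if (length(unmeas_idx) == 0) {
    return(list(meas_idx = meas_idx, unmeas_idx = unmeas_idx,
                nn = matrix(integer(), 0, k_eff), w = matrix(0, 0, k_eff)))
  }
  mr <- ((meas_idx - 1L) %% n + 1L) * aspect[1]
  mc <- ((meas_idx - 1L) %/% n + 1L) * aspect[2]
  ur <- ((unmeas_idx - 1L) %% n + 1L) * aspect[1]
  uc <- ((unmeas_idx - 1L) %/% n + 1L) * aspect[2]
  # squared Euclidean distances, unmeasured x measured
  d2 <- outer(ur^2, rep(1, length(mr))) + outer(rep(1, length(ur)), mr^2) -
    2 * outer(ur, mr) +
    outer(uc^2, rep(1, length(mc))) + outer(rep(1, length(uc)), mc^2) -
    2 * outer(uc, mc)
  if (k_eff == length(meas_idx)) {
    nn <- matrix(rep(seq_along(meas_idx), each = length(unmeas_idx)),
                 nrow = length(unmeas_idx))
    d2k <- d2
    d2min <- apply(d2, 1, min)
  } else {
    # k passes of vectorised row-argmin (deterministic first-index ties)
    nn <- matrix(0L, nrow(d2), k_eff)
    d2k <- matrix(0, nrow(d2), k_eff)
    rows <- seq_len(nrow(d2))
    for (j in seq_len(k_eff)) {
      jm <- max.col(-d2, ties.method = "first")
      nn[, j] <- jm
      d2k[, j] <- d2[cbind(rows, jm)]
      d2[cbind(rows, jm)] <- Inf
    }
    d2min <- d2k[, 1]
  }
  w <- 1 / (pmax(d2k, 0) + eps)
  list(meas_idx = meas_idx, unmeas_idx = unmeas_idx, nn = nn, w = w,
       d2min = pmax(d2min, 0))
}

idw_fill <- function(channel_img, nbr) {
  if (length(nbr$unmeas_idx) == 0) return(channel_img)
  vals <- channel_img[nbr$meas_idx]
  vmat <- matrix(vals[as.vector(nbr$nn)], nrow = nrow(nbr$nn))
  est <- rowSums(nbr$w * vmat) / rowSums(nbr$w)
  channel_img[nbr$unmeas_idx] <- est
  channel_img
}

#' Reconstruct one channel from sparse measurements
#'
#' Measured pixels keep their measured values verbatim; every unmeasured
#' pixel is estimated by an inverse-distance-weighted mean of its `k`
#' nearest measured neighbours (weight `1 / (dist^2 + eps)`, Euclidean
#' distance in pixel units).
#'
#' @param state a `measurement_state` with at least one measured location.
#' @param channel channel index in `1:d`.
#' @param k number of nearest measured neighbours (all measured pixels when
#'   fewer than `k` exist).
#' @param eps additive guard in the weight denominator.
#' @param aspect length-2 multiplier on (row, col) pixel spacing for
#'   anisotropic scan grids (e.g. scan-rate vs line-pitch spacing).
#' @return `N x M` numeric matrix.
#' @export
reconstruct_channel <- function(state, channel, k = 10L, eps = 1e-12,
                                aspect = c(1, 1)) {
  stopifnot(inherits(state, "measurement_state"))
  d <- length(state$channel_labels)
  if (!is_count(channel) || channel < 1 || channel > d) abort("bad channel index")
  nbr <- idw_neighbours(state, k = k, eps = eps, aspect = aspect)
  img <- matrix(state$values[, , channel], state$shape[1], state$shape[2])
  img[!state$measured] <- 0
  idw_fill(img, nbr)
}

#' Reconstruct all channels from sparse measurements
#'
#' Channel-wise [reconstruct_channel()] sharing one neighbour search across
#' channels (the measured-location geometry is channel-independent).
#'
#' @inheritParams reconstruct_channel
#' @return A `reconstruction`: a [channel_stack()]-like object with fields
#'   `data` (N x M x d), `channel_labels` and `source_state`.
#' @export
reconstruct_all <- function(state, k = 10L, eps = 1e-12, aspect = c(1, 1),
                            nbr = NULL) {
  stopifnot(inherits(state, "measurement_state"))
  if (is.null(nbr)) nbr <- idw_neighbours(state, k = k, eps = eps, aspect = aspect)
  d <- length(state$channel_labels)
  out <- array(0, dim = c(state$shape, d))
  for (c in seq_len(d)) {
    img <- matrix(state$values[, , c], state$shape[1], state$shape[2])
    img[!state$measured] <- 0
    out[, , c] <- idw_fill(img, nbr)
  }
  structure(
    list(data = out, channel_labels = state$channel_labels, source_state = state),
    class = c("reconstruction", "channel_stack")
  )
}
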