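#' Mean squared error between two images
#'
#' @param image_a,image_b equally shaped numeric matrices.
#' @return mean over all pixels of the squared differences.
#' @export
mse <- function(image_a, image_b) {
  image_a <- as.matrix(image_a); image_b <- as.matrix(image_b)
  if (!identical(dim(image_a), dim(image_b))) abort("image shapes differ")
  mean((image_a - image_b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(max_i^2 / mse)`. A perfect reconstruction (zero MSE) returns
#' `Inf`, the explicit perfect-reconstruction sentinel, rather than a
#' floating-point overflow.
#'
#' @inheritParams mse
#' @param max_i maximum possible pixel value. Ion images have no fixed bit
#'   depth, so the convention here is the maximum of the ground-truth
#'   channel; pass 255 etc. for integer-typed imagery.
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(image_a, image_b, max_i) {
  if (!is.numeric(max_i) || length(max_i) != 1 || max_i <= 0) {
    abort("`max_i` must be a positive scalar")
  }
  e <- mse(image_a, image_b)
  if (e == 0) return(Inf)
  10 * log10(max_i^2 / e)
}

#' Per-channel and average PSNR of a reconstruction
#'
#' PSNR is computed per channel against the ground truth, with `max_i` the
#' channel's ground-truth maximum (overridable), then averaged arithmetically.
#'
#' @param truth a [channel_stack()] ground truth.
#' @param recon a reconstruction (`channel_stack`-like, same shape).
#' @param max_i optional vector of per-channel maxima.
#' @return tibble with `channel`, `psnr`, plus one `"mean"` row.
#' @export
psnr_stack <- function(truth, recon, max_i = NULL) {
  d <- n_channels(truth)
  if (is.null(max_i)) {
    max_i <- vapply(seq_len(d), function(c) max(truth$data[, , c]), numeric(1))
  }
  vals <- vapply(seq_len(d), function(c) {
    psnr(truth$data[, , c], recon$data[, , c], max_i[c])
  }, numeric(1))
  dplyr::bind_rows(
    tibble(channel = truth$channel_labels, psnr = vals),
    tibble(channel = "mean", psnr = mean(vals))
  )
}

#' Cosine similarity of two maps
#'
#' Flattened dot product over the product of norms; used to compare
#' predicted ERD with ground-truth RD maps.
#'
#' @param map_a,map_b equally shaped numeric matrices, each with at least
#'   one nonzero element.
#' @return similarity in `[0, 1]` for nonnegative maps.
#' @export
cosine_similarity <- function(map_a, map_b) {
  a <- as.vector(as.matrix(map_a)); b <- as.vector(as.matrix(map_b))
  if (length(a) != length(b)) abort("map shapes differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for an all-zero map")
  sum(a * b) / (na * nb)
}

#' Scan geometry of a raster acquisition
#'
#' @param height_mm sample extent along the line-stepping axis.
#' @param width_mm sample extent along the scan axis.
#' @param scan_rate_um_s stage scan rate along a line.
#' @param line_pitch_um step between adjacent scheduled lines.
#' @return a `scan_geometry`.
#' @export
scan_geometry <- function(height_mm, width_mm, scan_rate_um_s, line_pitch_um) {
  vals <- c(height_mm, width_mm, scan_rate_um_s, line_pitch_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry fields must be strictly positive")
  }
  structure(
    list(height_mm = height_mm, width_mm = width_mm,
         scan_rate_um_s = scan_rate_um_s, line_pitch_um = line_pitch_um),
    class = "scan_geometry"
  )
}

#' Per-line timing model
#'
#' @param per_line_prep_s seconds of scan preparation per line (instrument
#'   ready + probe landing).
#' @param per_line_compute_s optional seconds of per-line computation added
#'   by the dynamic-sampling step.
#' @param measured_line_time_total_min optional measured total line time, for
#'   experimental accounting.
#' @return a `timing_model`.
#' @export
timing_model <- function(per_line_prep_s, per_line_compute_s = NULL,
                         measured_line_time_total_min = NULL) {
  if (per_line_prep_s < 0 ||
      (!is.null(per_line_compute_s) && per_line_compute_s < 0) ||
      (!is.null(measured_line_time_total_min) && measured_line_time_total_min < 0)) {
    abort("timing fields must be nonnegative")
  }
  structure(
    list(per_line_prep_s = per_line_prep_s,
         per_line_compute_s = per_line_compute_s,
         measured_line_time_total_min = measured_line_time_total_min),
    class = "timing_model"
  )
}

#' Number of scheduled scan lines
#'
#' Lines at positions `0, pitch, 2*pitch, ...` up to the sample height, both
#' edges included: `floor(height / pitch) + 1`.
#'
#' @param geometry a [scan_geometry()].
#' @return integer line count.
#' @export
scheduled_line_count <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  as.integer(floor(geometry$height_mm * 1000 / geometry$line_pitch_um + 1e-9)) + 1L
}

#' Acquisition-throughput estimate
#'
#' Full (non-sparse) imaging time is `lines * (width / scan_rate + prep)`;
#' when the sparse-run component times are supplied, the sparse total is
#' their sum and the fold improvement is `full / sparse`.
#'
#' @param geometry a [scan_geometry()].
#' @param timing a [timing_model()].
#' @param sparse_times optional list with `ms_acq_min`, `prep_min`,
#'   `compute_min` — the measured components of a sparse run.
#' @return tibble with `scheduled_lines`, `full_time_min` and, when sparse
#'   components are given, `sparse_time_min` and `fold_improvement`
#'   (unrounded; the print convention is nearest minute / one decimal).
#' @export
estimate_throughput <- function(geometry, timing, sparse_times = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(timing, "timing_model"))
  lines <- scheduled_line_count(geometry)
  line_scan_s <- geometry$width_mm * 1000 / geometry$scan_rate_um_s
  full_min <- lines * (line_scan_s + timing$per_line_prep_s) / 60
  out <- tibble(scheduled_lines = lines, full_time_min = full_min)
  if (!is.null(sparse_times)) {
    sparse_min <- sum(unlist(sparse_times))
    if (sparse_min <= 0) abort("sparse time must be positive")
    out$sparse_time_min <- sparse_min
    out$fold_improvement <- full_min / sparse_min
  }
  out
}
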