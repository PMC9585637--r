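#' Closed-loop dynamic sparse-sampling simulation
#'
#' Digitally resamples a fully measured stack: initialises per mode (1%
#' random pixels for pointwise; full lines at 25/50/70% of the height for
#' linewise), then iterates predict -> select -> measure -> reconstruct
#' until the stopping rule fires. When `model` is `NULL` the run is
#' oracle-guided: the channel-mean of max-normalised ground-truth RD labels
#' stands in for the ERD, decoupling policy behaviour from model quality.
#'
#' Fidelity snapshots (per-channel and mean PSNR against the ground truth;
#' ERD-vs-RD cosine similarity when a model is used) are recorded at every
#' 1% density increment in pointwise mode and at every iteration in linewise
#' mode.
#'
#' @param truth a [channel_stack()] ground truth.
#' @param mode `"pointwise"` or `"linewise"`.
#' @param model a trained [build_erd_model()]/[train_erd_model()] model, or
#'   `NULL` for the oracle.
#' @param criteria stopping rule, see [check_stop()].
#' @param seed integer; the only randomness is the pointwise initialisation.
#' @param schedule optional [line_schedule()] (linewise); defaults to all
#'   rows with revisits allowed, so a simulated run can always reach its
#'   target density.
#' @param sigma_cap passed to [rd_label()].
#' @param k IDW neighbour count for reconstruction.
#' @param acquire optional transport function `(locations, iteration) ->
#'   n x d value matrix`; defaults to reading `truth` directly. Used by
#'   [mock_acquisition()].
#' @return A `dlads_trace`: list with `metrics` (tibble), `state`,
#'   `reconstruction`, `mode`, `seed`, `config`.
#' @export
run_dynamic <- function(truth, mode = c("pointwise", "linewise"), model = NULL,
                        criteria = list(max_density = 0.4), seed = 1L,
                        schedule = NULL, sigma_cap = 8, k = 10L,
                        acquire = NULL) {
  stopifnot(inherits(truth, "channel_stack"))
  mode <- match.arg(mode)
  shape <- dim(truth$data)[1:2]
  d <- n_channels(truth)
  if (is.null(criteria$max_density) && is.null(criteria$max_iterations)) {
    abort("`criteria` needs `max_density` and/or `max_iterations`")
  }
  if (is.null(acquire)) {
    nm <- prod(shape)
    truth_mat <- matrix(truth$data, nm, d)
    acquire <- function(loc, iter) {
      truth_mat[px_index(loc$row, loc$col, shape[1]), , drop = FALSE]
    }
  }
  state <- new_measurement_state(shape, truth$channel_labels)
  if (mode == "pointwise") {
    init <- init_pointwise(shape, seed = child_seed(seed, 1L))
  } else {
    if (is.null(schedule)) {
      schedule <- line_schedule(n_rows = shape[1], visited_once_only = FALSE)
    }
    init <- init_linewise(schedule, shape[2])
    for (r in unique(init$row)) schedule <- mark_visited(schedule, r)
  }
  it <- 0L
  state <- measure(state, init, acquire(init, it), iteration = it)

  # one distance map per iteration, shared by all channels' RD labels
  state_dmap <- function(state, nbr) {
    dmap <- matrix(0, shape[1], shape[2])
    dmap[nbr$unmeas_idx] <- sqrt(nbr$d2min)
    dmap
  }
  priority_for <- function(state, recon, dmap) {
    maps <- lapply(seq_len(d), function(c) {
      if (is.null(model)) {
        rd_label(truth$data[, , c], state, recon = recon$data[, , c],
                 sigma_cap = sigma_cap, normalize = TRUE, dmap = dmap)
      } else {
        predict_erd(model, state, c, recon = recon$data[, , c])
      }
    })
    mean_erd(maps)
  }
  oracle_mean <- function(state, recon, dmap) {
    mean_erd(lapply(seq_len(d), function(c) {
      rd_label(truth$data[, , c], state, recon = recon$data[, , c],
               sigma_cap = sigma_cap, normalize = TRUE, dmap = dmap)
    }))
  }

  metrics <- list()
  snap <- function(iteration, state, recon, priority, dmap) {
    ps <- psnr_stack(truth, recon)
    cs <- NA_real_
    if (!is.null(model) && !is.null(priority) && any(priority > 0)) {
      rdm <- oracle_mean(state, recon, dmap)
      if (any(rdm > 0)) cs <- cosine_similarity(priority, rdm)
    }
    tibble(
      iteration = iteration,
      n_measured = sum(state$measured),
      density = sampling_density(state),
      psnr_mean = ps$psnr[ps$channel == "mean"],
      erd_rd_cosine = cs,
      psnr_channels = list(ps[ps$channel != "mean", ])
    )
  }

  last_pct <- -1L
  completed <- FALSE
  repeat {
    nbr <- idw_neighbours(state, k = k)
    recon <- reconstruct_all(state, k = k, nbr = nbr)
    dmap <- state_dmap(state, nbr)
    priority <- NULL
    dens_pct <- floor(sampling_density(state) * 100 + 1e-9)
    do_snap <- mode == "linewise" || dens_pct > last_pct
    stop_now <- check_stop(state, criteria, iterations = it)
    if (do_snap || stop_now) {
      if (!is.null(model) && !stop_now) priority <- priority_for(state, recon, dmap)
      metrics[[length(metrics) + 1L]] <- snap(it, state, recon, priority, dmap)
      last_pct <- dens_pct
    }
    if (stop_now) break
    if (is.null(priority)) priority <- priority_for(state, recon, dmap)
    if (mode == "pointwise") {
      sel <- select_pointwise(priority, state)
      if (is.null(sel)) { completed <- TRUE; break }
    } else {
      seg <- select_linewise_segment(priority, state, schedule)
      if (is.null(seg)) { completed <- TRUE; break }
      schedule <- mark_visited(schedule, seg$row)
      sel <- seg$pixels
    }
    it <- it + 1L
    state <- measure(state, sel, acquire(sel, it), iteration = it)
  }
  if (completed) {
    recon <- reconstruct_all(state, k = k)
    metrics[[length(metrics) + 1L]] <- snap(it, state, recon, NULL, NULL)
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), state = state,
         reconstruction = recon, mode = mode, seed = as.integer(seed),
         completed = completed,
         config = list(criteria = criteria, sigma_cap = sigma_cap, k = k,
                       oracle = is.null(model))),
    class = "dlads_trace"
  )
}

#' Non-adaptive baseline sampling runs
#'
#' `"random"` draws one random mask at the target density; `"uniform_lines"`
#' measures every `ceiling(1 / density)`-th scheduled line in full. One
#' reconstruction and evaluation is performed.
#'
#' @inheritParams run_dynamic
#' @param policy `"random"` or `"uniform_lines"`.
#' @param density target sampling density in (0, 1].
#' @return A `dlads_trace` with a single metrics row.
#' @export
run_baseline <- function(truth, policy = c("random", "uniform_lines"),
                         density, seed = 1L, schedule = NULL, k = 10L) {
  stopifnot(inherits(truth, "channel_stack"))
  policy <- match.arg(policy)
  if (!is.numeric(density) || density <= 0 || density > 1) {
    abort("`density` must lie in (0, 1]")
  }
  shape <- dim(truth$data)[1:2]
  if (policy == "random") {
    loc <- random_mask(shape, density, seed = seed)
  } else {
    if (is.null(schedule)) schedule <- line_schedule(n_rows = shape[1])
    step <- ceiling(1 / density)
    rows <- schedule$line_rows[seq(1, length(schedule$line_rows), by = step)]
    loc <- tibble(row = rep(rows, each = shape[2]),
                  col = rep(seq_len(shape[2]), length(rows)))
  }
  state <- new_measurement_state(shape, truth$channel_labels)
  state <- measure(state, loc, truth, iteration = 0L)
  recon <- reconstruct_all(state, k = k)
  ps <- psnr_stack(truth, recon)
  metrics <- tibble(
    iteration = 0L, n_measured = sum(state$measured),
    density = sampling_density(state),
    psnr_mean = ps$psnr[ps$channel == "mean"],
    erd_rd_cosine = NA_real_,
    psnr_channels = list(ps[ps$channel != "mean", ])
  )
  structure(
    list(metrics = metrics, state = state, reconstruction = recon,
         mode = paste0("baseline_", policy), seed = as.integer(seed),
         completed = FALSE, config = list(density = density, k = k)),
    class = "dlads_trace"
  )
}

#' @export
print.dlads_trace <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("<dlads_trace> mode %s, %d snapshot(s), final density %.1f%%, mean PSNR %.2f dB\n",
              x$mode, nrow(x$metrics), 100 * last$density, last$psnr_mean))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dlads_trace <- function(x, ...) {
  dplyr::select(x$metrics, -"psnr_channels")
}

#' Per-channel PSNR snapshots of a trace
#' @param x a `dlads_trace`.
#' @param ... unused.
#' @return long tibble (`iteration`, `density`, `channel`, `psnr`).
#' @export
trace_channel_psnr <- function(x, ...) {
  stopifnot(inherits(x, "dlads_trace"))
  tidyr::unnest(
    dplyr::select(x$metrics, "iteration", "density", "psnr_channels"),
    "psnr_channels"
  )
}

#' @exportS3Method generics::glance
glance.dlads_trace <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble(
    mode = x$mode, seed = x$seed, iterations = last$iteration,
    final_density = last$density, final_psnr_mean = last$psnr_mean,
    completed = x$completed
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.dlads_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = 100 * .data$density, y = .data$psnr_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "sampling density (%)", y = "mean PSNR (dB)",
                  title = sprintf("%s sampling", object$mode)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.channel_stack <- function(object, ...) {
  dm <- dim(object$data)
  df <- tidyr::expand_grid(channel = object$channel_labels,
                           col = seq_len(dm[2]), row = seq_len(dm[1]))
  df$intensity <- as.vector(object$data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
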