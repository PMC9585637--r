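#' File-based mock acquisition run
#'
#' Runs the same decision loop as [run_dynamic()], but every selected set of
#' locations is handed to the "instrument" through a polling file exchange,
#' emulating the handshake between the sampling program and the acquisition /
#' stage-control software: for iteration `i` a request file
#' `request_%04d.txt` is written to `exchange_dir`, the loop then polls until
#' a responder has produced `data_%04d.csv` with the measured per-channel
#' intensities, and only then proceeds. With the bundled responder (which
#' reads the ground truth) the resulting trace is identical to
#' [run_dynamic()] under the same seed.
#'
#' Exchange formats: the request is line-oriented text (a header
#' `iteration <i> mode <mode> n <count>` followed by one `row col` pair per
#' pixel); the response is a CSV with columns `row`, `col` and one column per
#' channel, written with 17 significant digits so values round-trip exactly.
#'
#' @inheritParams run_dynamic
#' @param exchange_dir writable directory for the request/data files.
#' @param responder function `(exchange_dir, truth)` servicing pending
#'   requests, called between polls; defaults to [mock_responder()]. Pass
#'   `NULL` when an external process answers the requests.
#' @param poll_interval seconds between polls.
#' @param timeout seconds to wait for a response before failing with the
#'   last completed iteration.
#' @return A `dlads_trace` with an extra `transport` tibble logging the
#'   request/data files and their completion times.
#' @export
mock_acquisition <- function(truth, mode = c("pointwise", "linewise"),
                             model = NULL, criteria = list(max_density = 0.4),
                             exchange_dir, seed = 1L,
                             responder = mock_responder,
                             poll_interval = 0.01, timeout = 5, ...) {
  stopifnot(inherits(truth, "channel_stack"))
  mode <- match.arg(mode)
  if (!dir.exists(exchange_dir)) dir.create(exchange_dir, recursive = TRUE)
  if (file.access(exchange_dir, 2) != 0) abort("`exchange_dir` is not writable")
  d <- n_channels(truth)
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  acquire <- function(loc, iter) {
    req <- file.path(exchange_dir, sprintf("request_%04d.txt", iter))
    datafile <- file.path(exchange_dir, sprintf("data_%04d.csv", iter))
    writeLines(
      c(sprintf("iteration %d mode %s n %d", iter, mode, nrow(loc)),
        sprintf("%d %d", loc$row, loc$col)),
      req
    )
    t_req <- Sys.time()
    repeat {
      if (!is.null(responder)) responder(exchange_dir, truth)
      if (file.exists(datafile)) break
      if (as.numeric(difftime(Sys.time(), t_req, units = "secs")) > timeout) {
        abort(sprintf(
          "acquisition timeout waiting for %s (last completed iteration %d)",
          basename(datafile), iter - 1L
        ))
      }
      Sys.sleep(poll_interval)
    }
    dat <- read.csv(datafile)
    ord <- match(paste(loc$row, loc$col), paste(dat$row, dat$col))
    if (any(is.na(ord))) abort(sprintf("response %s is missing locations", basename(datafile)))
    log_env$rows[[length(log_env$rows) + 1L]] <- tibble(
      iteration = iter, request_file = basename(req),
      data_file = basename(datafile), request_time = t_req,
      data_time = file.mtime(datafile)
    )
    as.matrix(dat[ord, 2 + seq_len(d), drop = FALSE])
  }
  trace <- run_dynamic(truth, mode = mode, model = model, criteria = criteria,
                       seed = seed, acquire = acquire, ...)
  trace$transport <- dplyr::bind_rows(log_env$rows)
  trace
}

#' Bundled mock responder
#'
#' Emulates the instrument side of the file exchange: finds request files in
#' `exchange_dir` that have no corresponding data file, looks the requested
#' pixel intensities up in the ground-truth stack and writes the per-channel
#' CSV response.
#'
#' @param exchange_dir the exchange directory.
#' @param truth the [channel_stack()] the "instrument" measures from.
#' @return (invisibly) the number of requests serviced.
#' @export
mock_responder <- function(exchange_dir, truth) {
  stopifnot(inherits(truth, "channel_stack"))
  reqs <- list.files(exchange_dir, pattern = "^request_[0-9]+\\.txt$",
                     full.names = TRUE)
  n_done <- 0L
  shape <- dim(truth$data)[1:2]
  d <- n_channels(truth)
  nm <- prod(shape)
  truth_mat <- matrix(truth$data, nm, d)
  for (req in reqs) {
    datafile <- file.path(exchange_dir,
                          sub("^request_([0-9]+)\\.txt$", "data_\\1.csv", basename(req)))
    if (file.exists(datafile)) next
    lines <- readLines(req)
    px <- do.call(rbind, lapply(lines[-1], function(s) as.integer(strsplit(s, " ")[[1]])))
    vals <- truth_mat[px_index(px[, 1], px[, 2], shape[1]), , drop = FALSE]
    df <- data.frame(row = px[, 1], col = px[, 2])
    for (c in seq_len(d)) {
      df[[truth$channel_labels[c]]] <- formatC(vals[, c], digits = 17, format = "g")
    }
    tmp <- paste0(datafile, ".tmp")
    write.csv(df, tmp, row.names = FALSE, quote = FALSE)
    file.rename(tmp, datafile)  # atomic publish, so pollers never see partial files
    n_done <- n_done + 1L
  }
  invisible(n_done)
}

#' Run a responder loop (for an external responder process)
#'
#' Polls `exchange_dir` and services requests with [mock_responder()] until
#' `stop_file` appears or `max_seconds` elapse.
#'
#' @inheritParams mock_responder
#' @param stop_file path whose existence ends the loop.
#' @param poll_interval seconds between polls.
#' @param max_seconds hard runtime cap.
#' @export
mock_responder_loop <- function(exchange_dir, truth,
                                stop_file = file.path(exchange_dir, "STOP"),
                                poll_interval = 0.05, max_seconds = 600) {
  t0 <- Sys.time()
  while (!file.exists(stop_file) &&
         as.numeric(difftime(Sys.time(), t0, units = "secs")) < max_seconds) {
    mock_responder(exchange_dir, truth)
    Sys.sleep(poll_interval)
  }
  invisible(NULL)
}
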