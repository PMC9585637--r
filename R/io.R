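#' Write a channel stack to a portable directory container
#'
#' One directory = one stack: a plain CSV matrix per channel
#' (`channel_001.csv`, ...) plus a `manifest.json` with the labels, shape and
#' units — trivially diffable and language-neutral.
#'
#' @param stack a [channel_stack()].
#' @param dir output directory (created if needed).
#' @param units free-text intensity units recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_channel_stack <- function(stack, dir, units = "ion counts (arbitrary)") {
  stopifnot(inherits(stack, "channel_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- n_channels(stack)
  files <- sprintf("channel_%03d.csv", seq_len(d))
  for (c in seq_len(d)) {
    write.table(stack$data[, , c], file.path(dir, files[c]),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    channel_labels = stack$channel_labels,
    shape = dim(stack$data)[1:2],
    n_channels = d,
    channel_files = files,
    units = units
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a channel stack from its directory container
#'
#' @param dir directory written by [write_channel_stack()].
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  d <- mf$n_channels
  shape <- as.integer(mf$shape)
  data <- array(0, dim = c(shape, d))
  for (c in seq_len(d)) {
    m <- as.matrix(read.csv(file.path(dir, mf$channel_files[c]), header = FALSE))
    data[, , c] <- m
  }
  channel_stack(data, mf$channel_labels)
}

#' Write / read a boolean measurement mask
#'
#' Portable 0/1 CSV matrix.
#'
#' @param mask logical matrix.
#' @param path CSV path.
#' @return `path` invisibly / the logical matrix.
#' @export
write_mask <- function(mask, path) {
  write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)), path,
              sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE)) == 1
  dimnames(m) <- NULL
  m
}

#' Write the measurement log of a state
#'
#' Line-oriented TSV: iteration, row, col and the per-channel measured value.
#'
#' @param state a `measurement_state`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_log <- function(state, path) {
  stopifnot(inherits(state, "measurement_state"))
  ord <- state$order
  d <- length(state$channel_labels)
  nm <- prod(state$shape)
  vmat <- matrix(state$values, nm, d)
  vals <- vmat[px_index(ord$row, ord$col, state$shape[1]), , drop = FALSE]
  colnames(vals) <- state$channel_labels
  df <- cbind(as.data.frame(ord), as.data.frame(vals))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export each channel of a stack as CSV for inspection
#'
#' @param stack a [channel_stack()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
export_channels_csv <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", stack$channel_labels), ".csv"))
  for (c in seq_len(n_channels(stack))) {
    write.table(stack$data[, , c], paths[c], sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Snapshot a run configuration
#'
#' Writes the resolved configuration and the seed set actually used as JSON
#' into the run directory, so a run is reproducible from its outputs alone.
#'
#' @param config named list.
#' @param dir run output directory.
#' @return path of the snapshot, invisibly.
#' @export
write_run_config <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "run_config.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Save / load an ERD model checkpoint
#'
#' The weights go into the R serialisation format (`erd_model.rds`) and the
#' architecture/optimiser configuration plus training history into
#' plain-text sidecars (`config.json`, `history.csv`) so a checkpoint is
#' inspectable without loading it.
#'
#' @param model an `erd_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` invisibly / the restored `erd_model`.
#' @export
save_erd_model <- function(model, dir) {
  stopifnot(inherits(model, "erd_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model[c("weights", "trained", "n_params")],
          file.path(dir, "erd_model.rds"))
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_erd_model
#' @export
load_erd_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(erd_config, cfg[setdiff(names(cfg), "in_channels")])
  model <- build_erd_model(config)
  saved <- readRDS(file.path(dir, "erd_model.rds"))
  model$weights <- saved$weights
  model$trained <- saved$trained
  model$n_params <- saved$n_params
  hist <- file.path(dir, "history.csv")
  if (file.exists(hist)) model$history <- tibble::as_tibble(read.csv(hist))
  model
}

#' Save / load a serialised training set
#'
#' One subdirectory per sample holding the input triple and the RD target as
#' CSV matrices, plus a top-level `manifest.csv` (stack id, channel, density,
#' seed).
#'
#' @param samples list from [build_training_set()].
#' @param dir output directory.
#' @return `dir` invisibly / the restored sample list.
#' @export
write_training_set <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metas <- list()
  for (i in seq_along(samples)) {
    sd <- file.path(dir, sprintf("sample_%04d", i))
    dir.create(sd, showWarnings = FALSE)
    s <- samples[[i]]
    for (nm in names(s$input)) {
      write.table(s$input[[nm]], file.path(sd, paste0(nm, ".csv")),
                  sep = ",", row.names = FALSE, col.names = FALSE)
    }
    write.table(unclass(s$target), file.path(sd, "target.csv"),
                sep = ",", row.names = FALSE, col.names = FALSE)
    metas[[i]] <- s$meta
  }
  write.csv(dplyr::bind_rows(metas), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    sd <- file.path(dir, sprintf("sample_%04d", i))
    get <- function(nm) unname(as.matrix(read.csv(file.path(sd, paste0(nm, ".csv")),
                                                  header = FALSE)))
    list(input = list(recon = get("recon"), values = get("values"),
                      mask = get("mask")),
         target = get("target"),
         meta = tibble::as_tibble(manifest[i, ]))
  })
}
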