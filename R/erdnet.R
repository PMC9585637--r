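#' Configuration of the ERD predictor network
#'
#' The estimated-reduction-in-distortion (ERD) predictor is a compact
#' symmetric encoder--decoder with skip connections: `depth` resolution
#' levels, one 3x3 convolution + LeakyReLU per level, 2x2 average pooling,
#' nearest-neighbour upsampling, and a linear 1x1 head. Its input contract is
#' three `N x M` arrays — the reconstruction, the measured values (zero where
#' unmeasured) and the binary measured-location indicator — and its output is
#' one `N x M` map, clamped at zero. Weights are optimised with Nadam under a
#' mean-absolute-error loss.
#'
#' @param base_width channels at the finest resolution level; deeper levels
#'   double it.
#' @param depth number of resolution levels (>= 1). Inputs are zero-padded
#'   internally to a multiple of `2^(depth-1)`.
#' @param lrelu_alpha LeakyReLU negative slope.
#' @param learning_rate,beta1,beta2,epsilon Nadam hyperparameters.
#' @param seed seed for the weight initialisation.
#' @param min_image_size smallest image edge the configuration is intended
#'   for; must be >= `2^(depth-1)`.
#' @return An `erd_config` list.
#' @export
erd_config <- function(base_width = 16L, depth = 3L, lrelu_alpha = 0.1,
                       learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, seed = 1L, min_image_size = 16L) {
  if (!is_count(depth) || depth < 1) abort("`depth` must be a positive integer")
  if (!is_count(base_width) || base_width < 1) abort("`base_width` must be >= 1")
  if (min_image_size < 2^(depth - 1)) {
    abort("`depth` incompatible with `min_image_size`: need min_image_size >= 2^(depth-1)")
  }
  structure(
    list(base_width = as.integer(base_width), depth = as.integer(depth),
         in_channels = 3L, lrelu_alpha = lrelu_alpha,
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, seed = as.integer(seed),
         min_image_size = as.integer(min_image_size)),
    class = "erd_config"
  )
}

#' Build an (untrained) ERD model
#'
#' Initialises the network weights (He-scaled Gaussians, deterministic given
#' `config$seed`) and reports the parameter count.
#'
#' @param config an [erd_config()].
#' @return An `erd_model` with fields `config`, `weights`, `trained`,
#'   `history` (per-epoch train/validation MAE) and `n_params`.
#' @export
build_erd_model <- function(config = erd_config()) {
  if (!inherits(config, "erd_config")) abort("`config` must be an erd_config()")
  weights <- nn_init_weights(config)
  structure(
    list(config = config, weights = weights, trained = FALSE,
         history = tibble(epoch = integer(), train_mae = numeric(),
                          val_mae = numeric()),
         n_params = sum(vapply(weights, length, integer(1))),
         geom_cache = new.env(parent = emptyenv())),
    class = "erd_model"
  )
}

#' @export
print.erd_model <- function(x, ...) {
  cat(sprintf("<erd_model> depth %d, base width %d, %d parameters, %s\n",
              x$config$depth, x$config$base_width, x$n_params,
              if (x$trained) "trained" else "untrained"))
  if (nrow(x$history)) {
    cat(sprintf("best validation MAE %.5g after %d epoch(s)\n",
                min(x$history$val_mae), nrow(x$history)))
  }
  invisible(x)
}

model_geometry <- function(model, hp, wp) {
  key <- paste0(hp, "x", wp)
  g <- model$geom_cache[[key]]
  if (is.null(g)) {
    g <- nn_geometry(hp, wp, model$config$depth)
    assign(key, g, envir = model$geom_cache)
  }
  g
}

# stack the three input planes into an (hp*wp) x 3 matrix at padded dims
erd_input_matrix <- function(input, hp, wp) {
  cbind(as.vector(nn_pad(input$recon, hp, wp)),
        as.vector(nn_pad(input$values, hp, wp)),
        as.vector(nn_pad(input$mask, hp, wp)))
}

erd_forward_raw <- function(model, input, cache = FALSE) {
  n <- nrow(input$recon); m <- ncol(input$recon)
  pd <- nn_padded_dims(n, m, model$config$depth)
  geom <- model_geometry(model, pd[1], pd[2])
  X <- erd_input_matrix(input, pd[1], pd[2])
  fw <- nn_forward(model$weights, model$config, X, geom, cache = cache)
  out <- matrix(fw$out, pd[1], pd[2])[seq_len(n), seq_len(m), drop = FALSE]
  list(out = out, fw = fw, geom = geom, pd = pd, n = n, m = m)
}

#' Train the ERD model
#'
#' Stochastic (per-sample) Nadam optimisation of the mean-absolute-error
#' loss between the predicted and ground-truth RD maps. After each epoch the
#' validation MAE is evaluated; the weights achieving the minimum validation
#' MAE are returned, and training stops early once the validation loss has
#' failed to improve for more than `patience` consecutive epochs
#' (`patience = 0` therefore runs exactly one epoch).
#'
#' @param model an [build_erd_model()] output.
#' @param train_pairs,val_pairs non-empty sample lists from
#'   [build_training_set()].
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs.
#' @param seed seed controlling the per-epoch sample shuffling.
#' @param verbose print per-epoch losses.
#' @return The trained `erd_model` (best-validation weights, `trained = TRUE`,
#'   `history` filled in).
#' @export
train_erd_model <- function(model, train_pairs, val_pairs, epochs = 12L,
                            patience = 2L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "erd_model"))
  if (length(train_pairs) == 0 || length(val_pairs) == 0) {
    abort("training and validation sets must be non-empty")
  }
  cfg <- model$config
  weights <- model$weights
  opt <- nadam_init(weights)
  best <- list(val = Inf, weights = weights)
  history <- list()
  no_improve <- 0L
  for (epoch in seq_len(max(1L, epochs))) {
    ord <- withr::with_seed(child_seed(seed, epoch), sample(length(train_pairs)))
    train_losses <- numeric(length(ord))
    for (j in seq_along(ord)) {
      s <- train_pairs[[ord[j]]]
      n <- nrow(s$target); m <- ncol(s$target)
      pd <- nn_padded_dims(n, m, cfg$depth)
      geom <- model_geometry(model, pd[1], pd[2])
      X <- erd_input_matrix(s$input, pd[1], pd[2])
      fw <- nn_forward(weights, cfg, X, geom, cache = TRUE)
      pred <- matrix(fw$out, pd[1], pd[2])
      tgt <- nn_pad(s$target, pd[1], pd[2])
      resid <- pred - tgt
      inside <- matrix(FALSE, pd[1], pd[2])
      inside[seq_len(n), seq_len(m)] <- TRUE
      loss <- mean(abs(resid[inside]))
      if (!is.finite(loss)) {
        abort(sprintf("non-finite training loss at epoch %d (sample %d)", epoch, j))
      }
      train_losses[j] <- loss
      dOut <- matrix(0, pd[1] * pd[2], 1)
      dOut[as.vector(inside), 1] <- sign(as.vector(resid)[as.vector(inside)]) / sum(inside)
      grads <- nn_backward(weights, cfg, geom, fw$cache, dOut)
      upd <- nadam_step(weights, grads, opt, cfg$learning_rate, cfg$beta1,
                        cfg$beta2, cfg$epsilon)
      weights <- upd$weights
      opt <- upd$opt
    }
    model$weights <- weights
    val_mae <- mean(vapply(val_pairs, function(s) {
      pred <- erd_forward_raw(model, s$input)$out
      mean(abs(pred - s$target))
    }, numeric(1)))
    if (!is.finite(val_mae)) abort(sprintf("non-finite validation loss at epoch %d", epoch))
    history[[epoch]] <- tibble(epoch = epoch, train_mae = mean(train_losses),
                               val_mae = val_mae)
    if (verbose) {
      message(sprintf("epoch %d: train MAE %.5g, val MAE %.5g",
                      epoch, mean(train_losses), val_mae))
    }
    if (val_mae < best$val) {
      best <- list(val = val_mae, weights = weights)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    if (no_improve >= patience) break
  }
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model
}

#' Validation MAE of a model on a sample set
#'
#' @param model an `erd_model`.
#' @param pairs sample list from [build_training_set()].
#' @return mean absolute error between predictions and RD targets.
#' @export
erd_validation_mae <- function(model, pairs) {
  mean(vapply(pairs, function(s) {
    mean(abs(erd_forward_raw(model, s$input)$out - s$target))
  }, numeric(1)))
}

#' Predict the ERD map for one channel of a measurement state
#'
#' Assembles the three model inputs from the state (reconstruction, measured
#' values with unmeasured positions zero-filled, binary indicator), scales
#' the two intensity planes by the channel's maximum measured intensity (the
#' same intensity-scale normalisation used in training), runs the network,
#' clamps negatives to zero and zeroes measured locations. The result
#' depends only on the measured mask and values, not on acquisition history.
#'
#' @param model an `erd_model` (a warning is raised if untrained).
#' @param state a `measurement_state` with >= 1 measured location.
#' @param channel channel index.
#' @param recon optional precomputed `N x M` reconstruction of the channel.
#' @return `N x M` nonnegative ERD matrix, attribute `channel_scope` set to
#'   the channel label.
#' @export
predict_erd <- function(model, state, channel, recon = NULL) {
  stopifnot(inherits(model, "erd_model"), inherits(state, "measurement_state"))
  if (!model$trained) warn("predicting with an untrained ERD model")
  if (!any(state$measured)) abort("need at least one measured location")
  if (is.null(recon)) recon <- reconstruct_channel(state, channel)
  vals <- state$values[, , channel]
  vals[!state$measured] <- 0
  mx <- max(vals)
  if (mx > 0) {
    vals <- vals / mx
    recon <- recon / mx
  }
  input <- list(recon = recon, values = vals, mask = state_mask_numeric(state))
  out <- erd_forward_raw(model, input)$out
  out[out < 0] <- 0
  out[state$measured] <- 0
  attr(out, "channel_scope") <- state$channel_labels[channel]
  out
}

#' Average ERD maps across channels
#'
#' Element-wise arithmetic mean of per-channel ERD maps; this channel mean is
#' the priority map used to choose sampling locations when several m/z
#' channels are monitored.
#'
#' @param maps non-empty list of equally shaped ERD matrices.
#' @return matrix of the same shape, attribute `channel_scope = "mean"`.
#' @export
mean_erd <- function(maps) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) == 0) abort("need at least one ERD map")
  dm <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), dm)) abort("ERD maps must share one shape")
  }
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  attr(out, "channel_scope") <- if (length(maps) == 1)
    attr(maps[[1]], "channel_scope") else "mean"
  out
}

#' @exportS3Method generics::tidy
tidy.erd_model <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.erd_model <- function(x, ...) {
  tibble(
    n_params = x$n_params,
    depth = x$config$depth,
    base_width = x$config$base_width,
    trained = x$trained,
    epochs_run = nrow(x$history),
    best_val_mae = if (nrow(x$history)) min(x$history$val_mae) else NA_real_
  )
}
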