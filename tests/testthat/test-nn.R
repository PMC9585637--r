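test_that("analytic network gradients match finite differences", {
  set.seed(7)
  cfg <- erd_config(base_width = 2L, depth = 3L, seed = 42L, min_image_size = 4L)
  model <- build_erd_model(cfg)
  h <- 8L; w <- 8L
  input <- list(recon = matrix(runif(h * w), h, w),
                values = matrix(runif(h * w), h, w),
                mask = matrix(rbinom(h * w, 1, 0.3), h, w))
  target <- matrix(runif(h * w), h, w)
  geom <- dlads:::nn_geometry(h, w, cfg$depth)
  X <- dlads:::erd_input_matrix(input, h, w)
  wts <- model$weights
  loss_fn <- function(wts) {
    out <- dlads:::nn_forward(wts, cfg, X, geom)$out
    mean(abs(out - as.vector(target)))
  }
  fw <- dlads:::nn_forward(wts, cfg, X, geom, cache = TRUE)
  resid <- as.vector(fw$out) - as.vector(target)
  grads <- dlads:::nn_backward(wts, cfg, geom, fw$cache,
                               matrix(sign(resid) / length(resid), ncol = 1))
  for (nm in names(wts)) {
    for (i in head(seq_along(wts[[nm]]), 3)) {
      e <- 1e-6
      wp <- wts; wp[[nm]][i] <- wp[[nm]][i] + e
      wm <- wts; wm[[nm]][i] <- wm[[nm]][i] - e
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * e)
      expect_lt(abs(num - grads[[nm]][i]),
                1e-5 * max(1, abs(num)))
    }
  }
})

test_that("the first Nadam step matches its closed form", {
  lr <- 0.01; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  w0 <- 0.5; g <- 0.2
  opt <- dlads:::nadam_init(list(w = w0))
  upd <- dlads:::nadam_step(list(w = w0), list(w = g), opt, lr, b1, b2, eps)
  # t = 1: m = (1-b1) g, v = (1-b2) g^2
  # m_hat = b1 (1-b1) g / (1-b1^2) + g  = g (b1/(1+b1) + 1); v_hat = g^2
  mhat <- g * (b1 / (1 + b1) + 1)
  expect_equal(upd$weights$w, w0 - lr * mhat / (abs(g) + eps), tolerance = 1e-12)
})

test_that("model honours the input/output shape contract", {
  model <- build_erd_model(erd_config(base_width = 4L, seed = 3L))
  mk <- function(n, m) list(recon = matrix(runif(n * m), n, m),
                            values = matrix(0, n, m),
                            mask = matrix(0, n, m))
  out <- dlads:::erd_forward_raw(model, mk(16, 16))$out
  expect_equal(dim(out), c(16L, 16L))
  # non-multiple-of-4 shapes are padded internally and cropped back
  out2 <- dlads:::erd_forward_raw(model, mk(10, 13))$out
  expect_equal(dim(out2), c(10L, 13L))
  expect_true(all(is.finite(out2)))
  # all-zero input triple stays finite
  z <- list(recon = matrix(0, 8, 8), values = matrix(0, 8, 8),
            mask = matrix(0, 8, 8))
  expect_true(all(is.finite(dlads:::erd_forward_raw(model, z)$out)))
})

test_that("weight initialisation is seeded and depth is validated", {
  a <- build_erd_model(erd_config(base_width = 4L, seed = 5L))
  b <- build_erd_model(erd_config(base_width = 4L, seed = 5L))
  expect_identical(a$weights, b$weights)
  c <- build_erd_model(erd_config(base_width = 4L, seed = 6L))
  expect_false(identical(a$weights, c$weights))
  expect_gt(a$n_params, 0)
  expect_error(erd_config(depth = 6L, min_image_size = 16L), "incompatible")
})

test_that("patience zero trains for exactly one epoch", {
  pairs <- build_training_set(list(tiny_phantom(c(8, 8), 1, seed = 1)),
                              densities = c(0.1, 0.2), seed = 2)
  model <- build_erd_model(erd_config(base_width = 2L, seed = 1L))
  fit <- train_erd_model(model, pairs, pairs, epochs = 10, patience = 0, seed = 1)
  expect_equal(nrow(fit$history), 1L)
  expect_true(fit$trained)
})

test_that("training reduces the loss on a small overfit problem", {
  pairs <- build_training_set(list(tiny_phantom(c(16, 16), 2, seed = 8)),
                              densities = seq(0.05, 0.25, by = 0.05), seed = 3)
  model <- build_erd_model(erd_config(base_width = 4L, seed = 2L))
  fit <- train_erd_model(model, pairs, pairs, epochs = 15, patience = 15, seed = 4)
  expect_lt(tail(fit$history$train_mae, 1), fit$history$train_mae[1])
  expect_lt(min(fit$history$val_mae), erd_validation_mae(model, pairs))
})

test_that("training is reproducible for a fixed seed", {
  pairs <- build_training_set(list(tiny_phantom(c(8, 8), 1, seed = 9)),
                              densities = c(0.1, 0.3), seed = 5)
  model <- build_erd_model(erd_config(base_width = 2L, seed = 7L))
  f1 <- train_erd_model(model, pairs, pairs, epochs = 3, patience = 3, seed = 6)
  f2 <- train_erd_model(model, pairs, pairs, epochs = 3, patience = 3, seed = 6)
  expect_equal(f1$history, f2$history)
  expect_equal(f1$weights, f2$weights)
})
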