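# Minimal convolutional encoder-decoder engine used by the ERD model.
#
# Feature maps are stored as (h*w) x channels matrices in column-major pixel
# order; 3x3 convolutions are evaluated as im2col gathers followed by one
# BLAS matrix product per layer. All gradients are exact and are checked
# against central finite differences in the test suite.

# Per-resolution geometry: 3x3 neighbour indices (out-of-bounds mapped to a
# zero sink row hw+1) and 2x2 pooling child indices.
nn_geom_level <- function(h, w) {
  hw <- h * w
  rr <- rep(seq_len(h), w)
  cc <- rep(seq_len(w), each = h)
  idx <- matrix(NA_integer_, hw, 9L)
  k <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      k <- k + 1L
      r2 <- rr + dr
      c2 <- cc + dc
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      idx[, k] <- ifelse(ok, (c2 - 1L) * h + r2, hw + 1L)
    }
  }
  children <- NULL
  if (h %% 2 == 0 && w %% 2 == 0) {
    h2 <- h %/% 2L; w2 <- w %/% 2L
    rc <- rep(seq_len(h2), w2)
    cc2 <- rep(seq_len(w2), each = h2)
    children <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
      (2L * cc2 - 2L + o[2]) * h + (2L * rc - 1L + o[1])
    })
  }
  list(h = h, w = w, hw = hw, conv = idx, children = children)
}

nn_geometry <- function(h, w, depth) {
  levels <- vector("list", depth)
  for (l in seq_len(depth)) {
    levels[[l]] <- nn_geom_level(h, w)
    if (l < depth) {
      if (h %% 2 != 0 || w %% 2 != 0) {
        abort("internal: image size must be a multiple of 2^(depth-1)")
      }
      h <- h %/% 2L
      w <- w %/% 2L
    }
  }
  levels
}

conv3_fwd <- function(X, W, b, idx) {
  hw <- nrow(X)
  cin <- ncol(X)
  X1 <- rbind(X, 0)
  Xcol <- matrix(0, hw, 9L * cin)
  for (k in 1:9) Xcol[, ((k - 1L) * cin + 1L):(k * cin)] <- X1[idx[, k], , drop = FALSE]
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = hw)
  list(Y = Y, Xcol = Xcol)
}

conv3_bwd <- function(dY, Xcol, W, idx, cin, hw) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  dX1 <- matrix(0, hw + 1L, cin)
  for (k in 1:9) {
    tgt <- idx[, k]
    inb <- tgt <= hw
    blk <- dXcol[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    dX1[tgt[inb], ] <- dX1[tgt[inb], , drop = FALSE] + blk[inb, , drop = FALSE]
  }
  list(dX = dX1[seq_len(hw), , drop = FALSE], dW = dW, db = db)
}

lrelu_fwd <- function(X, alpha) {
  pos <- X > 0
  list(Y = X * ifelse(pos, 1, alpha), pos = pos)
}

pool_fwd <- function(X, children) {
  (X[children[[1]], , drop = FALSE] + X[children[[2]], , drop = FALSE] +
     X[children[[3]], , drop = FALSE] + X[children[[4]], , drop = FALSE]) / 4
}

pool_bwd <- function(dY, children, hw_fine) {
  dX <- matrix(0, hw_fine, ncol(dY))
  for (g in 1:4) dX[children[[g]], ] <- dY / 4
  dX
}

upsample_fwd <- function(X, children, hw_fine) {
  Y <- matrix(0, hw_fine, ncol(X))
  for (g in 1:4) Y[children[[g]], ] <- X
  Y
}

upsample_bwd <- function(dY, children) {
  dY[children[[1]], , drop = FALSE] + dY[children[[2]], , drop = FALSE] +
    dY[children[[3]], , drop = FALSE] + dY[children[[4]], , drop = FALSE]
}

nn_widths <- function(config) config$base_width * 2L^(seq_len(config$depth) - 1L)

# He-initialised flat weight list
nn_init_weights <- function(config) {
  widths <- nn_widths(config)
  depth <- config$depth
  p <- list()
  withr::with_seed(config$seed, {
    cin <- config$in_channels
    for (l in seq_len(depth)) {
      cout <- widths[l]
      p[[paste0("enc", l, ".W")]] <- matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                                            9 * cin, cout)
      p[[paste0("enc", l, ".b")]] <- rep(0, cout)
      cin <- cout
    }
    for (l in rev(seq_len(depth - 1L))) {
      cin_d <- widths[l + 1L] + widths[l]
      cout <- widths[l]
      p[[paste0("dec", l, ".W")]] <- matrix(rnorm(9 * cin_d * cout, 0, sqrt(2 / (9 * cin_d))),
                                            9 * cin_d, cout)
      p[[paste0("dec", l, ".b")]] <- rep(0, cout)
    }
    p[["head.W"]] <- matrix(rnorm(widths[1], 0, sqrt(2 / widths[1])), widths[1], 1)
    p[["head.b"]] <- 0
  })
  p
}

# Forward pass on an (h*w) x in_channels matrix at padded dims (h, w) both
# multiples of 2^(depth-1). Returns the linear output column and, optionally,
# the activation cache needed for the backward pass.
nn_forward <- function(weights, config, X, geom, cache = FALSE) {
  depth <- config$depth
  alpha <- config$lrelu_alpha
  E <- vector("list", depth)
  cc <- if (cache) list(conv = vector("list", 2L * depth), E = NULL) else NULL
  A <- X
  for (l in seq_len(depth)) {
    cv <- conv3_fwd(A, weights[[paste0("enc", l, ".W")]],
                    weights[[paste0("enc", l, ".b")]], geom[[l]]$conv)
    lr <- lrelu_fwd(cv$Y, alpha)
    E[[l]] <- lr$Y
    if (cache) cc$conv[[l]] <- list(Xcol = cv$Xcol, pos = lr$pos)
    A <- lr$Y
    if (l < depth) A <- pool_fwd(A, geom[[l]]$children)
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- upsample_fwd(A, geom[[l]]$children, geom[[l]]$hw)
    Ad <- cbind(up, E[[l]])
    cv <- conv3_fwd(Ad, weights[[paste0("dec", l, ".W")]],
                    weights[[paste0("dec", l, ".b")]], geom[[l]]$conv)
    lr <- lrelu_fwd(cv$Y, alpha)
    if (cache) cc$conv[[depth + l]] <- list(Xcol = cv$Xcol, pos = lr$pos,
                                            up_ncol = ncol(up))
    A <- lr$Y
  }
  out <- A %*% weights[["head.W"]] + rep(weights[["head.b"]], each = nrow(A))
  if (cache) cc$A_head <- A
  list(out = out, cache = cc)
}

nn_backward <- function(weights, config, geom, cache, dOut) {
  depth <- config$depth
  alpha <- config$lrelu_alpha
  grads <- list()
  grads[["head.W"]] <- crossprod(cache$A_head, dOut)
  grads[["head.b"]] <- sum(dOut)
  dA <- dOut %*% t(weights[["head.W"]])
  dE <- vector("list", depth)  # gradients flowing into skip activations
  for (l in seq_len(depth - 1L)) {
    nm <- paste0("dec", l, ".W")
    cv <- cache$conv[[depth + l]]
    dPre <- dA * ifelse(cv$pos, 1, alpha)
    bw <- conv3_bwd(dPre, cv$Xcol, weights[[nm]], geom[[l]]$conv,
                    cin = ncol(cv$Xcol) / 9L, hw = geom[[l]]$hw)
    grads[[nm]] <- bw$dW
    grads[[paste0("dec", l, ".b")]] <- bw$db
    nu <- cv$up_ncol
    dUp <- bw$dX[, seq_len(nu), drop = FALSE]
    dE[[l]] <- bw$dX[, (nu + 1L):ncol(bw$dX), drop = FALSE]
    dA <- upsample_bwd(dUp, geom[[l]]$children)  # into the level-(l+1) activation
  }
  # encoder backward, deepest level first; dA currently holds the gradient
  # reaching the bottleneck activation E[[depth]] (via the first upsample)
  dAct <- dA
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      # gradient into E[[l]]: skip connection + pooled path from level l+1
      dAct <- dE[[l]] + pool_bwd(dAct, geom[[l]]$children, geom[[l]]$hw)
    }
    nm <- paste0("enc", l, ".W")
    cv <- cache$conv[[l]]
    dPre <- dAct * ifelse(cv$pos, 1, alpha)
    bw <- conv3_bwd(dPre, cv$Xcol, weights[[nm]], geom[[l]]$conv,
                    cin = ncol(cv$Xcol) / 9L, hw = geom[[l]]$hw)
    grads[[nm]] <- bw$dW
    grads[[paste0("enc", l, ".b")]] <- bw$db
    dAct <- bw$dX
  }
  grads
}

nadam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

# Nadam update (Dozat 2016, constant momentum schedule): Adam moments with a
# Nesterov-style lookahead in the first-moment estimate.
nadam_step <- function(weights, grads, opt, lr, beta1, beta2, epsilon) {
  opt$t <- opt$t + 1L
  t <- opt$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- beta1 * opt$m[[nm]] / (1 - beta1^(t + 1)) + (1 - beta1) * g / (1 - beta1^t)
    vhat <- opt$v[[nm]] / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + epsilon)
  }
  list(weights = weights, opt = opt)
}

# pad an N x M matrix with zeros (bottom/right) to target dims
nn_pad <- function(mat, hp, wp) {
  if (nrow(mat) == hp && ncol(mat) == wp) return(mat)
  out <- matrix(0, hp, wp)
  out[seq_len(nrow(mat)), seq_len(ncol(mat))] <- mat
  out
}

nn_padded_dims <- function(n, m, depth) {
  s <- 2L^(depth - 1L)
  c(as.integer(ceiling(n / s) * s), as.integer(ceiling(m / s) * s))
}
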