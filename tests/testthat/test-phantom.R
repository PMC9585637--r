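test_that("noiseless phantom equals its region template", {
  w <- matrix(c(0, 0, 0, 1), 1, 4)
  spec <- phantom_spec(shape = c(16, 16), n_channels = 1, noise_cv = 0,
                       channel_region_weights = w)
  ph <- generate_phantom(spec)
  # independent template: core = innermost ellipse of the default layout
  n <- 16; m <- 16
  y <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  x <- (seq_len(m) - (m + 1) / 2) / (m / 2)
  core <- outer(y^2, x^2, `+`) <= (0.15 * 2)^2
  expect_equal(ph$data[, , 1], matrix(as.numeric(core), n, m))
  expect_setequal(unique(as.vector(ph$data)), c(0, 1))
})

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(shape = c(24, 24), n_channels = 3, noise_cv = 0.15, seed = 9)
  expect_identical(generate_phantom(spec), generate_phantom(spec))
  spec2 <- phantom_spec(shape = c(24, 24), n_channels = 3, noise_cv = 0.15, seed = 10)
  expect_false(identical(generate_phantom(spec)$data, generate_phantom(spec2)$data))
})

test_that("per-region channel means match configured weights within 3 s.e.", {
  spec <- phantom_spec(shape = c(64, 64), n_channels = 6, noise_cv = 0.1, seed = 0)
  ph <- generate_phantom(spec)
  reg <- phantom_regions(spec)
  for (c in seq_len(6)) {
    for (r in 0:3) {
      px <- ph$data[, , c][reg == r]
      se <- sd(px) / sqrt(length(px))
      expect_lt(abs(mean(px) - spec$channel_region_weights[c, r + 1]),
                3 * se + 0.01)
    }
  }
})

test_that("off-tissue background mean is lower than every tissue region", {
  spec <- phantom_spec(shape = c(48, 48), n_channels = 4, noise_cv = 0.2, seed = 2)
  ph <- generate_phantom(spec)
  reg <- phantom_regions(spec)
  for (c in seq_len(4)) {
    bg <- mean(ph$data[, , c][reg == 0])
    for (r in 1:3) expect_lt(bg, mean(ph$data[, , c][reg == r]))
  }
})

test_that("region-mean ordering matches weight ordering for most seeds", {
  hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    spec <- phantom_spec(shape = c(32, 32), n_channels = 3, noise_cv = 0.2, seed = s)
    ph <- generate_phantom(spec)
    reg <- phantom_regions(spec)
    ok <- TRUE
    for (c in seq_len(3)) {
      means <- vapply(0:3, function(r) mean(ph$data[, , c][reg == r]), numeric(1))
      w <- spec$channel_region_weights[c, ]
      # concordance over every pair of regions with distinct weights
      for (i in 1:3) {
        for (j in (i + 1):4) {
          if (w[i] != w[j]) ok <- ok && (sign(means[i] - means[j]) == sign(w[i] - w[j]))
        }
      }
    }
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("every channel must have a nonzero tissue enhancement", {
  w <- matrix(c(0.5, 0, 0, 0), 1, 4)  # background only
  expect_error(phantom_spec(n_channels = 1, channel_region_weights = w),
               "nonzero enhancement")
  expect_error(phantom_spec(noise_cv = -0.1), "noise_cv")
})

test_that("random_mask draws the exact pixel count", {
  expect_equal(nrow(random_mask(c(10, 10), 1.0)), 100)
  expect_equal(nrow(random_mask(c(10, 10), 0.01)), 1)   # 1% rule keeps >= 1 pixel
  expect_equal(nrow(random_mask(c(5, 5), 0.01)), 1)     # floor of one
  for (f in c(0.05, 0.125, 0.33, 0.5)) {
    got <- nrow(random_mask(c(20, 20), f, seed = 3))
    expect_equal(got, max(1, floor(f * 400 + 0.5)))
  }
  m <- random_mask(c(12, 7), 0.4, seed = 5)
  expect_false(anyDuplicated(paste(m$row, m$col)) > 0)
  expect_identical(random_mask(c(12, 7), 0.4, seed = 5), m)
  expect_error(random_mask(c(10, 10), 0), "fraction")
  expect_error(random_mask(c(10, 10), 1.2), "fraction")
})

test_that("random_mask per-pixel inclusion frequency is uniform", {
  counts <- matrix(0, 20, 20)
  n_seeds <- 1000L
  for (s in seq_len(n_seeds)) {
    m <- random_mask(c(20, 20), 0.25, seed = s)
    counts[cbind(m$row, m$col)] <- counts[cbind(m$row, m$col)] + 1
  }
  freq <- counts / n_seeds
  # binomial sd at p = 0.25, n = 1000 is ~0.0137; allow ~4.4 sd for the max
  # over 400 pixels
  expect_lt(max(abs(freq - 0.25)), 0.06)
})

test_that("channel stack validates its invariants", {
  expect_error(channel_stack(array(-1, c(4, 4, 1))), "finite")
  expect_error(channel_stack(array(1, c(1, 4, 1))), "N >= 2")
  expect_error(channel_stack(array(1, c(4, 4, 2)), c("a", "a")), "unique")
  st <- channel_stack(matrix(1, 4, 5))
  expect_equal(dim(st), c(4L, 5L, 1L))
  expect_equal(n_channels(st), 1L)
})
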