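# Analytic parameter count for the configured layout, derived layer by
# layer independently of the builder's bookkeeping.
analytic_param_count <- function(cfg) {
  K <- cfg$kernel; f <- cfg$filters; L <- cfg$levels
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  block <- function(c) 2 * (2 * c) + 2 * conv(K, c, c)  # two BN + two convs
  total <- conv(K, 1, f[1])                             # stem
  for (l in seq_len(L)) {
    total <- total + cfg$blocks[l] * block(f[l])
    if (l < L) total <- total + conv(K, f[l], f[l + 1])
  }
  for (l in seq_len(L - 1)) {
    total <- total + conv(1, f[l + 1], f[l]) + block(f[l])
  }
  total + conv(1, f[1], 1)
}

test_that("parameter count matches the analytic layout formula", {
  expect_equal(n_parameters(build_model(network_config(), seed = 1)),
               analytic_param_count(network_config()))
  small <- network_config(init_filters = 4, levels = 3, blocks = c(1, 2, 2))
  expect_equal(n_parameters(build_model(small, seed = 1)),
               analytic_param_count(small))
  # filters double per level
  expect_identical(network_config()$filters, c(32L, 64L, 128L, 256L))
})

test_that("output shape equals input shape at tiling sizes", {
  cfg <- network_config(init_filters = 4, levels = 3, blocks = c(1, 1, 1))
  m <- build_model(cfg, seed = 2)
  for (size in c(224L, 448L)) {
    p <- predict(m, matrix(0.5, size, size))
    expect_identical(dim(p), c(size, size))
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(predict(m, matrix(0.5, 90, 90)), "pad")
})

test_that("the default architecture maps 224 x 224 to 224 x 224", {
  m <- build_model(network_config(), seed = 1)
  p <- predict(m, matrix(0.4, 224, 224))
  expect_identical(dim(p), c(224L, 224L))
})

test_that("inference is deterministic and zero weights give 0.5", {
  cfg <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1))
  m <- build_model(cfg, seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(predict(m, x), predict(m, x))
  # same seed, same initialization
  expect_identical(build_model(cfg, seed = 3)$params, m$params)
  mz <- m
  mz$params <- lapply(mz$params, function(a) a * 0)
  expect_true(all(predict(mz, x) == 0.5))
})

test_that("predictions are shift-consistent away from the borders", {
  cfg <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1))
  m <- build_model(cfg, seed = 4)
  set.seed(9)
  x <- matrix(runif(64 * 64), 64, 64)
  shift <- 2  # one full downsampling period
  xs <- matrix(0.5, 64, 64)
  xs[(shift + 1):64, ] <- x[1:(64 - shift), ]
  p <- predict(m, x); ps <- predict(m, xs)
  core <- 21:44
  expect_lt(max(abs(ps[core + shift, core] - p[core, core])), 1e-8)
})

test_that("the residual skip connections are live", {
  cfg <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1))
  ablated <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1),
                            residual = FALSE)
  m <- build_model(cfg, seed = 5)
  ma <- build_model(ablated, seed = 5)
  expect_identical(m$params, ma$params)  # identical initialization ...
  x <- matrix(runif(32 * 32), 32, 32)
  expect_gt(max(abs(predict(m, x) - predict(ma, x))), 1e-6)  # ... different map
})

test_that("backpropagation matches finite differences through the network", {
  cfg <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1))
  m <- build_model(cfg, seed = 3)
  set.seed(7)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  lc <- loss_config()
  fwd <- cherenkovseg:::net_forward(m, x, train = TRUE)
  dlog <- seg_loss_grad(fwd$prob, y, lc) * fwd$prob * (1 - fwd$prob)
  G <- cherenkovseg:::net_backward(m, fwd, dlog)
  loss_of <- function(model) {
    seg_loss(cherenkovseg:::net_forward(model, x, train = TRUE)$prob, y, lc)
  }
  set.seed(11)
  h <- 1e-5
  for (nm in sample(names(G), 10)) {
    i <- sample(length(m$params[[nm]]), 1)
    m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + h
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - h
    fd <- (loss_of(m1) - loss_of(m2)) / (2 * h)
    expect_lt(abs(fd - G[[nm]][i]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("binarize applies a strict threshold", {
  expect_identical(binarize(matrix(0.5, 3, 3), 0.5), matrix(0L, 3, 3))
  m <- random_mask(6, 6)
  expect_identical(binarize(m + 0, 0.5), m)
  set.seed(19)
  p <- matrix(runif(64), 8, 8)
  manual <- matrix(0L, 8, 8)
  for (i in 1:8) for (j in 1:8) if (p[i, j] > 0.3) manual[i, j] <- 1L
  expect_identical(binarize(p, 0.3), manual)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- network_config(init_filters = 4, levels = 2, blocks = c(1, 1))
  m <- build_model(cfg, seed = 6)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict(m, x), predict(m2, x))
  expect_identical(m2$config$blocks, cfg$blocks)
})
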