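# Residual encoder-decoder segmentation network.
#
# Pre-activation residual blocks (batch norm -> ReLU -> 3x3 conv, twice, plus
# an additive identity skip), strided-convolution downsampling between
# encoder levels, and a decoder symmetric to the encoder but with a single
# block per level: 1x1 channel reduction, x2 nearest-neighbor upsampling,
# additive skip from the matching encoder level, one residual block. A
# single-channel 1x1 head with a sigmoid yields the per-pixel vessel
# probability. Forward and backward passes are explicit; convolutions run
# through Rcpp im2col/GEMM kernels.

#' Architecture of the residual encoder-decoder network
#'
#' The default layout is the canonical configuration of this backbone
#' family: 32 initial filters doubling per level over 4 spatial levels, with
#' `c(1, 2, 2, 4)` residual blocks per encoder level and one per decoder
#' level.
#'
#' @param init_filters Filters at the first level (doubled at each deeper
#'   level).
#' @param levels Number of spatial levels (>= 2); each level below the first
#'   halves the resolution.
#' @param blocks Integer vector of residual blocks per encoder level
#'   (length `levels`).
#' @param kernel Odd convolution kernel size.
#' @param residual Keep the additive identity skip inside each block. The
#'   `FALSE` setting is an ablation switch that degrades the blocks to plain
#'   pre-activation stacks.
#' @param bn_eps,bn_momentum Batch-normalization variance floor and
#'   running-statistics update rate.
#' @return A `network_config` object.
#' @export
network_config <- function(init_filters = 32, levels = 4,
                           blocks = c(1, 2, 2, 4), kernel = 3,
                           residual = TRUE, bn_eps = 1e-5,
                           bn_momentum = 0.1) {
  if (levels < 2) abort("`levels` must be >= 2")
  if (kernel %% 2 != 1) abort("`kernel` must be odd")
  if (length(blocks) != levels) {
    abort("`blocks` must provide one block count per level")
  }
  if (any(blocks < 1)) abort("block counts must be >= 1")
  if (init_filters < 1) abort("`init_filters` must be >= 1")
  structure(list(
    init_filters = as.integer(init_filters), levels = as.integer(levels),
    blocks = as.integer(blocks), kernel = as.integer(kernel),
    filters = as.integer(init_filters * 2^(seq_len(levels) - 1)),
    residual = isTRUE(residual), bn_eps = bn_eps, bn_momentum = bn_momentum
  ), class = "network_config")
}

conv_param_names <- function(cfg) {
  L <- cfg$levels; nm <- character()
  add_block <- function(prefix) {
    c(paste0(prefix, c(".bn1.gamma", ".bn1.beta", ".conv1.w", ".conv1.b",
                       ".bn2.gamma", ".bn2.beta", ".conv2.w", ".conv2.b")))
  }
  nm <- c(nm, "stem.w", "stem.b")
  for (l in seq_len(L)) {
    for (b in seq_len(cfg$blocks[l])) {
      nm <- c(nm, add_block(sprintf("enc%d.b%d", l, b)))
    }
    if (l < L) nm <- c(nm, sprintf("down%d.w", l), sprintf("down%d.b", l))
  }
  for (l in rev(seq_len(L - 1))) {
    nm <- c(nm, sprintf("dec%d.proj.w", l), sprintf("dec%d.proj.b", l),
            add_block(sprintf("dec%d", l)))
  }
  c(nm, "head.w", "head.b")
}

#' Build a segmentation model with freshly initialized parameters
#'
#' Convolution weights use He-normal initialization (`sd = sqrt(2 / fan_in)`),
#' biases start at zero, batch-norm scales at one; initialization is
#' deterministic per seed.
#'
#' @param config A [network_config()].
#' @param seed RNG seed for the initialization.
#' @return A `seg_model` object holding the parameter collection, the
#'   running normalization statistics, the config, and training provenance.
#' @export
build_model <- function(config = network_config(), seed = 1) {
  if (!inherits(config, "network_config")) {
    abort("`config` must be a network_config")
  }
  K <- config$kernel; f <- config$filters; L <- config$levels
  params <- list(); running <- list()
  with_local_seed(seed, {
    he_conv <- function(k, cin, cout) {
      array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
            dim = c(k, k, cin, cout))
    }
    add_conv <- function(name, k, cin, cout) {
      params[[paste0(name, ".w")]] <<- he_conv(k, cin, cout)
      params[[paste0(name, ".b")]] <<- numeric(cout)
    }
    add_bn <- function(name, c) {
      params[[paste0(name, ".gamma")]] <<- rep(1, c)
      params[[paste0(name, ".beta")]] <<- numeric(c)
      running[[paste0(name, ".mean")]] <<- numeric(c)
      running[[paste0(name, ".var")]] <<- rep(1, c)
    }
    add_block <- function(prefix, c) {
      add_bn(paste0(prefix, ".bn1"), c)
      add_conv(paste0(prefix, ".conv1"), K, c, c)
      add_bn(paste0(prefix, ".bn2"), c)
      add_conv(paste0(prefix, ".conv2"), K, c, c)
    }
    add_conv("stem", K, 1L, f[1])
    for (l in seq_len(L)) {
      for (b in seq_len(config$blocks[l])) {
        add_block(sprintf("enc%d.b%d", l, b), f[l])
      }
      if (l < L) add_conv(sprintf("down%d", l), K, f[l], f[l + 1])
    }
    for (l in rev(seq_len(L - 1))) {
      add_conv(sprintf("dec%d.proj", l), 1L, f[l + 1], f[l])
      add_block(sprintf("dec%d", l), f[l])
    }
    add_conv("head", 1L, f[1], 1L)
  })
  structure(list(params = params, running = running, config = config,
                 provenance = list(stage = "init", epoch = NA_integer_,
                                   val_loss = NA_real_, seed = seed)),
            class = "seg_model")
}

#' Number of trainable parameters of a model
#'
#' @param model A `seg_model`.
#' @return Integer count of weights, biases and normalization scales/offsets.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seg_model: %d levels, %s blocks, %d->%d filters, %s parameters [%s]>\n",
    cfg$levels, paste(cfg$blocks, collapse = "/"), cfg$filters[1],
    cfg$filters[cfg$levels], format(n_parameters(x), big.mark = ","),
    x$provenance$stage))
  invisible(x)
}

# ---- forward / backward ------------------------------------------------

net_forward <- function(model, x, train = FALSE) {
  P <- model$params; Rn <- model$running; cfg <- model$config
  L <- cfg$levels
  cache <- new.env(parent = emptyenv())
  newR <- Rn

  conv_f <- function(name, x, stride = 1L) {
    w <- P[[paste0(name, ".w")]]
    K <- dim(w)[1]; pad <- (K - 1L) %/% 2L
    y <- cpp_conv2d_forward(x, w, P[[paste0(name, ".b")]], stride, pad)
    if (train) cache[[name]] <- list(x = x, stride = stride, pad = pad)
    y
  }
  bn_f <- function(name, x) {
    g <- P[[paste0(name, ".gamma")]]; be <- P[[paste0(name, ".beta")]]
    if (train) {
      st <- cpp_bn_stats(x)
      mu <- st$mu; v <- st$var
      m <- cfg$bn_momentum
      newR[[paste0(name, ".mean")]] <<-
        (1 - m) * Rn[[paste0(name, ".mean")]] + m * mu
      newR[[paste0(name, ".var")]] <<-
        (1 - m) * Rn[[paste0(name, ".var")]] + m * v
    } else {
      mu <- Rn[[paste0(name, ".mean")]]; v <- Rn[[paste0(name, ".var")]]
    }
    out <- cpp_bn_forward(x, mu, v, g, be, cfg$bn_eps)
    if (train) cache[[name]] <- list(xhat = out$xhat, inv = out$inv)
    out$y
  }
  relu_f <- function(name, x) {
    pos <- x > 0
    if (train) cache[[name]] <- pos
    x * pos
  }
  block_f <- function(prefix, x) {
    h <- bn_f(paste0(prefix, ".bn1"), x)
    h <- relu_f(paste0(prefix, ".relu1"), h)
    h <- conv_f(paste0(prefix, ".conv1"), h)
    h <- bn_f(paste0(prefix, ".bn2"), h)
    h <- relu_f(paste0(prefix, ".relu2"), h)
    h <- conv_f(paste0(prefix, ".conv2"), h)
    if (cfg$residual) x + h else h
  }

  h <- conv_f("stem", x)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    for (b in seq_len(cfg$blocks[l])) h <- block_f(sprintf("enc%d.b%d", l, b), h)
    skips[[l]] <- h
    if (l < L) h <- conv_f(sprintf("down%d", l), h, stride = 2L)
  }
  for (l in rev(seq_len(L - 1))) {
    h <- conv_f(sprintf("dec%d.proj", l), h)
    h <- upsample2(h)
    h <- h + skips[[l]]
    h <- block_f(sprintf("dec%d", l), h)
  }
  logits <- conv_f("head", h)
  prob <- sigmoid(logits)
  list(prob = prob, logits = logits, cache = cache, running = newR)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

downsample2_sum <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(1, d[2], by = 2)
  dy[o1, o2, , , drop = FALSE] + dy[o1 + 1, o2, , , drop = FALSE] +
    dy[o1, o2 + 1, , , drop = FALSE] + dy[o1 + 1, o2 + 1, , , drop = FALSE]
}

# dlogits: gradient of the scalar loss w.r.t. the pre-sigmoid output.
# Returns the gradient list over trainable parameters.
net_backward <- function(model, fwd, dlogits) {
  P <- model$params; cfg <- model$config; L <- cfg$levels
  cache <- fwd$cache
  G <- list()

  conv_b <- function(name, dy) {
    cc <- cache[[name]]
    r <- cpp_conv2d_backward(cc$x, P[[paste0(name, ".w")]], dy,
                             cc$stride, cc$pad)
    G[[paste0(name, ".w")]] <<- r$dw
    G[[paste0(name, ".b")]] <<- r$db
    r$dx
  }
  bn_b <- function(name, dy) {
    cc <- cache[[name]]
    r <- cpp_bn_backward(dy, cc$xhat, cc$inv, P[[paste0(name, ".gamma")]])
    G[[paste0(name, ".gamma")]] <<- r$dgamma
    G[[paste0(name, ".beta")]] <<- r$dbeta
    r$dx
  }
  relu_b <- function(name, dy) dy * cache[[name]]
  block_b <- function(prefix, dy) {
    dh <- conv_b(paste0(prefix, ".conv2"), dy)
    dh <- relu_b(paste0(prefix, ".relu2"), dh)
    dh <- bn_b(paste0(prefix, ".bn2"), dh)
    dh <- conv_b(paste0(prefix, ".conv1"), dh)
    dh <- relu_b(paste0(prefix, ".relu1"), dh)
    dh <- bn_b(paste0(prefix, ".bn1"), dh)
    if (cfg$residual) dy + dh else dh
  }

  dh <- conv_b("head", dlogits)
  dskips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    ds <- block_b(sprintf("dec%d", l), dh)
    dskips[[l]] <- ds
    dh <- conv_b(sprintf("dec%d.proj", l), downsample2_sum(ds))
  }
  d <- dh  # gradient w.r.t. the deepest encoder output
  for (l in rev(seq_len(L))) {
    for (b in rev(seq_len(cfg$blocks[l]))) {
      d <- block_b(sprintf("enc%d.b%d", l, b), d)
    }
    if (l > 1) {
      d <- conv_b(sprintf("down%d", l - 1), d)
      d <- d + dskips[[l - 1]]
    }
  }
  conv_b("stem", d)
  G
}

# ---- inference ---------------------------------------------------------

#' Predict a vessel probability map
#'
#' Runs the network in inference mode (normalization uses the running
#' statistics, so repeated calls are deterministic). Spatial dimensions must
#' be divisible by `2^(levels - 1)`.
#'
#' @param object A `seg_model`.
#' @param image A numeric matrix in `[0, 1]`, a list of such matrices, or an
#'   `(H, W, 1, N)` array.
#' @param ... Unused.
#' @return A probability map in `(0, 1)` matching the input form (matrix in,
#'   matrix out).
#' @export
predict.seg_model <- function(object, image, ...) {
  single <- is.matrix(image)
  listed <- is.list(image)
  x <- as_batch4(image, "image")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("`image` values must be finite and lie in [0, 1]")
  }
  div <- 2^(object$config$levels - 1)
  d <- dim(x)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    abort(sprintf(
      "image dimensions (%d x %d) must be divisible by %d; pad the input",
      d[1], d[2], div))
  }
  prob <- net_forward(object, x, train = FALSE)$prob
  if (single) return(prob[, , 1, 1])
  if (listed) return(purrr::map(seq_len(d[4]), function(i) prob[, , 1, i]))
  prob
}

#' Threshold a probability map into a binary mask
#'
#' @param prob Probability matrix (or array) with values in `[0, 1]`.
#' @param threshold Pixels strictly above this value become 1.
#' @return An integer 0/1 object of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (any(prob < 0) || any(prob > 1)) abort("`prob` values must lie in [0, 1]")
  out <- (prob > threshold)
  storage.mode(out) <- "integer"
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a serialized list with a `manifest` describing the
#' format version, the architecture, and the training provenance (stage,
#' selected epoch, validation loss, seed).
#'
#' @param model A `seg_model`.
#' @param path File path for the checkpoint.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `seg_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    manifest = list(format = "cherenkovseg-checkpoint", version = 1L,
                    config = unclass(model$config),
                    provenance = model$provenance),
    params = model$params, running = model$running)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$manifest$format, "cherenkovseg-checkpoint")) {
    abort("not a cherenkovseg checkpoint")
  }
  cfg <- obj$manifest$config
  config <- network_config(cfg$init_filters, cfg$levels, cfg$blocks,
                           cfg$kernel, cfg$residual, cfg$bn_eps,
                           cfg$bn_momentum)
  structure(list(params = obj$params, running = obj$running, config = config,
                 provenance = obj$manifest$provenance),
            class = "seg_model")
}
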