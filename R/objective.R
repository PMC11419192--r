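# The compound segmentation objective: weighted soft Dice loss plus weighted
# (binary) cross-entropy, both consuming sigmoid probabilities.

#' Configuration of the compound segmentation loss
#'
#' The training objective is
#' `lambda_dice * L_Dice + lambda_ce * L_CE`; the defaults
#' (`lambda_dice = 1`, `lambda_ce = 0.1`) are the weighting under which the
#' combined objective trains best. `eps` smooths the Dice ratio so empty
#' masks are well-defined; `delta` clips probabilities away from {0, 1}
#' before the cross-entropy logarithms.
#'
#' @param lambda_dice Non-negative Dice weight.
#' @param lambda_ce Non-negative cross-entropy weight.
#' @param eps Dice smoothing constant.
#' @param delta Log-clipping constant for the cross-entropy.
#' @return A `loss_config` object.
#' @export
loss_config <- function(lambda_dice = 1, lambda_ce = 0.1, eps = 1e-5,
                        delta = 1e-7) {
  if (lambda_dice < 0 || lambda_ce < 0) {
    abort("loss weights must be non-negative")
  }
  if (eps <= 0) abort("`eps` must be > 0")
  structure(list(lambda_dice = lambda_dice, lambda_ce = lambda_ce,
                 eps = eps, delta = delta),
            class = "loss_config")
}

check_loss_inputs <- function(yp, yt) {
  yp <- as_batch4(yp, "yp"); yt <- as_batch4(yt, "yt")
  check_same_shape(yp, yt, c("yp", "yt"))
  list(yp = yp, yt = yt)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(yp * yt) + eps) / (sum(yp) + sum(yt) + eps)` per sample,
#' averaged over the batch. Zero when prediction and target agree exactly,
#' one when they are disjoint.
#'
#' @param yp Predicted probability map(s) in `[0, 1]`: a matrix, list of
#'   matrices, or `(H, W, 1, N)` array.
#' @param yt Binary ground-truth mask(s) of the same shape.
#' @param eps Smoothing constant.
#' @param weights Optional per-pixel weight array (same shape); the neutral
#'   default weighs every pixel 1.
#' @return A non-negative scalar.
#' @export
dice_loss <- function(yp, yt, eps = 1e-5, weights = NULL) {
  z <- check_loss_inputs(yp, yt); yp <- z$yp; yt <- z$yt
  if (!is.null(weights)) { yp <- yp * weights; yt <- yt * weights }
  n <- dim(yp)[4]
  per_sample <- vapply(seq_len(n), function(i) {
    p <- yp[, , , i]; t <- yt[, , , i]
    1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  mean(per_sample)
}

#' Binary cross-entropy loss on probabilities
#'
#' Mean over all pixels of `-(yt * log(yp) + (1 - yt) * log(1 - yp))`, with
#' `yp` clipped to `[delta, 1 - delta]` first.
#'
#' @inheritParams dice_loss
#' @param delta Log-clipping constant.
#' @return A non-negative scalar.
#' @export
ce_loss <- function(yp, yt, delta = 1e-7, weights = NULL) {
  z <- check_loss_inputs(yp, yt); yp <- z$yp; yt <- z$yt
  p <- pmin(pmax(yp, delta), 1 - delta)
  ll <- -(yt * log(p) + (1 - yt) * log(1 - p))
  if (is.null(weights)) mean(ll) else sum(ll * weights) / sum(weights)
}

#' Compound segmentation loss
#'
#' `lambda_dice * dice_loss + lambda_ce * ce_loss`; linear in the two
#' weights.
#'
#' @inheritParams dice_loss
#' @param config A [loss_config()].
#' @return A non-negative scalar.
#' @export
seg_loss <- function(yp, yt, config = loss_config()) {
  config$lambda_dice * dice_loss(yp, yt, eps = config$eps) +
    config$lambda_ce * ce_loss(yp, yt, delta = config$delta)
}

#' Analytic gradient of the compound loss with respect to the probabilities
#'
#' Returns `d seg_loss / d yp` with the same shape as `yp`; used by the
#' training loop (chained through the sigmoid) and checkable against central
#' finite differences.
#'
#' @inheritParams seg_loss
#' @return An array shaped like `yp`.
#' @export
seg_loss_grad <- function(yp, yt, config = loss_config()) {
  z <- check_loss_inputs(yp, yt)
  yp4 <- z$yp; yt4 <- z$yt
  d <- dim(yp4); n <- d[4]
  g <- array(0, dim = d)
  eps <- config$eps
  for (i in seq_len(n)) {
    p <- yp4[, , , i]; t <- yt4[, , , i]
    I <- sum(p * t); S <- sum(p) + sum(t)
    # d/dp of 1 - (2I + eps)/(S + eps), averaged over the batch
    g[, , , i] <- -(2 * t * (S + eps) - (2 * I + eps)) / (S + eps)^2 / n
  }
  g <- config$lambda_dice * g
  pc <- pmin(pmax(yp4, config$delta), 1 - config$delta)
  g + config$lambda_ce * (pc - yt4) / (pc * (1 - pc)) / length(yp4)
}
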