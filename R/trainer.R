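# Two-stage transfer learning: pretrain on source-domain patches, fine-tune
# on target-domain patches with every parameter trainable, select the
# checkpoint with minimum validation loss (the warm start at epoch 0 is
# evaluated and selectable).

#' Training-stage configuration
#'
#' Defaults follow the published protocol: batch size 24, RMSProp with
#' learning rate `1e-5`, 400 pretraining epochs with an `1e-8` L2
#' regularization decay, and 100 fine-tuning epochs without decay.
#'
#' @param stage `"pretrain"` or `"finetune"`; sets the epoch and decay
#'   defaults.
#' @param epochs Number of epochs (defaults: 400 pretrain, 100 fine-tune).
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSProp learning rate.
#' @param weight_decay L2 regularization decay (defaults: `1e-8` pretrain, 0
#'   fine-tune).
#' @param loss A [loss_config()].
#' @param augment An [augment_policy()] applied on the fly to training
#'   patches each epoch (validation patches are never augmented).
#' @param seed Seed driving initialization order, shuffling and
#'   augmentation.
#' @param rmsprop_alpha,rmsprop_eps RMSProp smoothing constant and
#'   denominator floor.
#' @return A `train_config` object.
#' @export
train_config <- function(stage = c("pretrain", "finetune"), epochs = NULL,
                         batch_size = 24, learning_rate = 1e-5,
                         weight_decay = NULL, loss = loss_config(),
                         augment = augment_policy(), seed = 1,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8) {
  stage <- match.arg(stage)
  if (is.null(epochs)) epochs <- if (stage == "pretrain") 400L else 100L
  if (is.null(weight_decay)) {
    weight_decay <- if (stage == "pretrain") 1e-8 else 0
  }
  if (batch_size < 1) abort("`batch_size` must be positive")
  if (learning_rate < 0) abort("`learning_rate` must be >= 0")
  if (epochs < 0) abort("`epochs` must be >= 0")
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 loss = loss, augment = augment, seed = as.integer(seed),
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps),
            class = "train_config")
}

patches_to_arrays <- function(ps, which_split = NULL) {
  rows <- if (is.null(which_split)) ps else ps[!is.na(ps$split) &
                                                ps$split == which_split, ]
  list(images = rows$image, masks = rows$mask, n = nrow(rows))
}

eval_on <- function(model, images, masks, loss_cfg, batch_size,
                    threshold = 0.5) {
  n <- length(images)
  losses <- numeric(0); dices <- numeric(0); weights <- numeric(0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- as_batch4(images[idx])
    y <- as_batch4(masks[idx])
    prob <- net_forward(model, x, train = FALSE)$prob
    losses <- c(losses, seg_loss(prob, y, loss_cfg))
    weights <- c(weights, length(idx))
    dices <- c(dices, vapply(seq_along(idx), function(i) {
      dice_score(binarize(prob[, , 1, i], threshold), masks[idx][[i]])
    }, numeric(1)))
  }
  list(loss = sum(losses * weights) / sum(weights), dice = mean(dices))
}

#' Train a model for one stage
#'
#' Runs `config$epochs` epochs of seeded mini-batch RMSProp on the training
#' split, with on-the-fly augmentation, evaluating the compound loss on the
#' un-augmented validation split before training (epoch 0) and after every
#' epoch. The returned model is the checkpoint with minimum validation loss.
#'
#' @param model A `seg_model` (see [build_model()]).
#' @param patches A split `patch_set` with non-empty train and val splits.
#' @param config A [train_config()].
#' @param evaluator Optional function `(model, epoch) -> validation loss`
#'   replacing the built-in validation pass (used for harness tests).
#' @param verbose Print one structured log line per epoch.
#' @return A `seg_fit`: the selected `model`, the per-epoch `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`, `val_dice`; epoch 0 is the
#'   pre-update warm start), and the `config`. `tidy()` returns the history,
#'   `glance()` the selection summary, `autoplot()` the loss curves.
#' @export
train_stage <- function(model, patches, config = train_config(),
                        evaluator = NULL, verbose = FALSE) {
  if (!inherits(model, "seg_model")) abort("`model` must be a seg_model")
  if (config$epochs == 0L) {
    return(new_seg_fit(model, tibble(
      epoch = integer(), train_loss = numeric(), val_loss = numeric(),
      val_dice = numeric()), config))
  }
  tr <- patches_to_arrays(patches, "train")
  va <- patches_to_arrays(patches, "val")
  if (tr$n == 0) abort("training split is empty")
  if (va$n == 0 && is.null(evaluator)) {
    abort("validation split is empty; re-split the patches with another seed")
  }
  loss_cfg <- config$loss
  evaluate <- function(m, epoch) {
    if (!is.null(evaluator)) {
      list(loss = evaluator(m, epoch), dice = NA_real_)
    } else {
      eval_on(m, va$images, va$masks, loss_cfg, config$batch_size)
    }
  }

  P <- model$params
  V <- lapply(P, function(a) a * 0)  # RMSProp second-moment state
  running <- model$running
  mk_model <- function() {
    structure(list(params = P, running = running, config = model$config,
                   provenance = model$provenance), class = "seg_model")
  }

  ev0 <- evaluate(mk_model(), 0L)
  history <- list(tibble(epoch = 0L, train_loss = NA_real_,
                         val_loss = ev0$loss, val_dice = ev0$dice))
  best <- list(params = P, running = running, val = ev0$loss,
               dice = ev0$dice, epoch = 0L)

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(tr$n)
      batch_losses <- numeric(0)
      for (start in seq(1, tr$n, by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1, tr$n)]
        aug <- purrr::map(idx, function(i) {
          augment_patch(tr$images[[i]], tr$masks[[i]], config$augment)
        })
        x <- as_batch4(purrr::map(aug, "image"))
        y <- as_batch4(purrr::map(aug, "mask"))
        m <- mk_model()
        fwd <- net_forward(m, x, train = TRUE)
        running <- fwd$running
        batch_losses <- c(batch_losses, seg_loss(fwd$prob, y, loss_cfg))
        dprob <- seg_loss_grad(fwd$prob, y, loss_cfg)
        dlogits <- dprob * fwd$prob * (1 - fwd$prob)
        G <- net_backward(m, fwd, dlogits)
        for (nm in names(G)) {
          g <- G[[nm]]
          if (config$weight_decay > 0) g <- g + config$weight_decay * P[[nm]]
          V[[nm]] <- config$rmsprop_alpha * V[[nm]] +
            (1 - config$rmsprop_alpha) * g * g
          P[[nm]] <- P[[nm]] -
            config$learning_rate * g / (sqrt(V[[nm]]) + config$rmsprop_eps)
        }
      }
      ev <- evaluate(mk_model(), epoch)
      history[[epoch + 1L]] <- tibble(
        epoch = as.integer(epoch), train_loss = mean(batch_losses),
        val_loss = ev$loss, val_dice = ev$dice)
      if (ev$loss < best$val) {
        best <- list(params = P, running = running, val = ev$loss,
                     dice = ev$dice, epoch = as.integer(epoch))
      }
      if (verbose) {
        message(sprintf(
          "stage=%s epoch=%d train_loss=%.5f val_loss=%.5f lr=%g seed=%d",
          config$stage, epoch, mean(batch_losses), ev$loss,
          config$learning_rate, config$seed))
      }
    }
  })

  out <- structure(list(
    params = best$params, running = best$running, config = model$config,
    provenance = list(stage = config$stage, epoch = best$epoch,
                      val_loss = best$val, seed = config$seed)),
    class = "seg_model")
  new_seg_fit(out, dplyr::bind_rows(history), config,
              selected = best$epoch, val_dice = best$dice)
}

new_seg_fit <- function(model, history, config, selected = NA_integer_,
                        val_dice = NA_real_) {
  structure(list(model = model, history = history, config = config,
                 selected_epoch = selected, selected_val_dice = val_dice),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit [%s]: %d epochs, selected epoch %s (val loss %s)>\n",
              x$config$stage, max(0, nrow(x$history) - 1),
              x$selected_epoch,
              format(x$model$provenance$val_loss, digits = 4)))
  invisible(x)
}

#' @export
tidy.seg_fit <- function(x, ...) x$history

#' @export
glance.seg_fit <- function(x, ...) {
  tibble(stage = x$config$stage, epochs = max(0L, nrow(x$history) - 1L),
         selected_epoch = x$selected_epoch,
         val_loss = x$model$provenance$val_loss,
         val_dice = x$selected_val_dice)
}

#' @export
autoplot.seg_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h[!is.na(h$loss), ],
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::labs(x = "epoch", y = "compound loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Pretrain on the source domain, then fine-tune on the target domain
#'
#' Builds a model, pretrains it on the source patches, initializes the
#' fine-tuning stage from the selected (minimum-validation-loss) pretrain
#' checkpoint with *all* parameters trainable, fine-tunes on the target
#' patches, and returns the selected fine-tuned model. Setting
#' `pretrain = FALSE` skips the first stage, reducing the pipeline to
#' training from scratch on the target domain. `joint_weight` enables an
#' experimental joint mode in which each fine-tuning batch mixes source
#' patches in with that probability; the default (off) is the sequential
#' procedure.
#'
#' @param source,target Split `patch_set`s for the two domains.
#' @param net_config A [network_config()].
#' @param pretrain_config,finetune_config [train_config()]s for the two
#'   stages.
#' @param pretrain Run the pretraining stage (ablation switch).
#' @param joint_weight `NULL` (sequential, default) or a mixing probability
#'   in `(0, 1)`.
#' @param verbose Passed to [train_stage()].
#' @return A `transfer_fit`: the final `model` plus the two stage fits
#'   (`pretrain` may be `NULL`).
#' @export
transfer_pipeline <- function(source, target, net_config = network_config(),
                              pretrain_config = train_config("pretrain"),
                              finetune_config = train_config("finetune"),
                              pretrain = TRUE, joint_weight = NULL,
                              verbose = FALSE) {
  model <- build_model(net_config, seed = pretrain_config$seed)
  fit_pre <- NULL
  if (pretrain) {
    fit_pre <- train_stage(model, source, pretrain_config, verbose = verbose)
    model <- fit_pre$model
  }
  target_ft <- target
  if (!is.null(joint_weight)) {
    if (joint_weight <= 0 || joint_weight >= 1) {
      abort("`joint_weight` must lie in (0, 1)")
    }
    # Experimental joint mode: dilute the fine-tuning training split with
    # source-domain training patches in the given proportion.
    src_tr <- source[!is.na(source$split) & source$split == "train", ]
    n_tgt <- sum(target$split == "train", na.rm = TRUE)
    n_mix <- min(nrow(src_tr), ceiling(joint_weight / (1 - joint_weight) *
                                         n_tgt))
    mix <- with_local_seed(finetune_config$seed + 1L,
                           src_tr[sample.int(nrow(src_tr), n_mix), ])
    target_ft <- bind_patches(list(target, mix))
  }
  fit_ft <- train_stage(model, target_ft, finetune_config, verbose = verbose)
  structure(list(model = fit_ft$model, pretrain = fit_pre,
                 finetune = fit_ft),
            class = "transfer_fit")
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat("<transfer_fit>\n")
  if (!is.null(x$pretrain)) print(x$pretrain)
  print(x$finetune)
  invisible(x)
}

#' @export
glance.transfer_fit <- function(x, ...) {
  dplyr::bind_rows(if (!is.null(x$pretrain)) glance(x$pretrain),
                   glance(x$finetune))
}

#' Scaled two-domain transfer benchmark on phantoms
#'
#' Quantifies the transfer benefit at desk scale: for each seed it builds a
#' high-contrast source patch set and a small noisy beam-limited target
#' patch set, trains (a) pretrain-then-fine-tune and (b) from scratch on the
#' target only, with identical seeds and budgets, and compares the selected
#' validation Dice scores. The scaled conditions are 200 source / 20 target
#' patches of 64 x 64 px, a 2-level network, and 30 + 30 epochs; see the
#' methods vignette for the learning-rate rationale at this scale.
#'
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed.
#' @param n_source,n_target Patch counts for the two domains.
#' @param patch_size Patch side length in pixels.
#' @param epochs Epochs for each stage (pretrain, fine-tune and scratch all
#'   use this budget).
#' @param learning_rate RMSProp learning rate for the scaled benchmark.
#' @param batch_size Mini-batch size.
#' @param verbose Print per-epoch logs.
#' @return A tibble with one row per seed: `finetuned_dice`, `scratch_dice`,
#'   `transfer_wins`.
#' @export
phantom_transfer_benchmark <- function(n_seeds = 5, seed = 1, n_source = 200,
                                       n_target = 20, patch_size = 64,
                                       epochs = 30, learning_rate = 1e-3,
                                       batch_size = 24, verbose = FALSE) {
  net <- network_config(init_filters = 8, levels = 2, blocks = c(1, 1))
  purrr::map(seq_len(n_seeds), function(i) {
    s <- seed + 1000L * (i - 1L)
    source <- phantom_patches("source", n_source, patch_size, seed = s)
    target <- phantom_patches("target", n_target, patch_size, seed = s + 500L)
    cfg_pre <- train_config("pretrain", epochs = epochs,
                            batch_size = batch_size,
                            learning_rate = learning_rate, seed = s)
    cfg_ft <- train_config("finetune", epochs = epochs,
                           batch_size = batch_size,
                           learning_rate = learning_rate, seed = s)
    fit <- transfer_pipeline(source, target, net, cfg_pre, cfg_ft,
                             verbose = verbose)
    scratch <- train_stage(build_model(net, seed = s), target, cfg_ft,
                           verbose = verbose)
    tibble(seed = s,
           finetuned_dice = fit$finetune$selected_val_dice,
           scratch_dice = scratch$selected_val_dice,
           transfer_wins = fit$finetune$selected_val_dice >
             scratch$selected_val_dice)
  }) |> dplyr::bind_rows()
}

#' Generate a split phantom patch set for one domain
#'
#' Draws phantom images, tiles them into `patch_size` patches, applies the
#' 5% retention filter, keeps the first `n` qualifying patches, and splits
#' 90/10.
#'
#' @param domain `"source"` or `"target"`.
#' @param n Number of patches to keep.
#' @param patch_size Patch side length; phantom images are drawn at three
#'   patch widths per side.
#' @param seed Base seed.
#' @param threshold Retention threshold.
#' @return A split `patch_set` of `n` patches.
#' @export
phantom_patches <- function(domain, n, patch_size = 64, seed = 1,
                            threshold = 0.05) {
  spec <- phantom_spec(domain, image_size = 3 * patch_size,
                       step_length = max(3, patch_size %/% 16),
                       width_range = c(2, 5), max_steps = 60)
  sets <- list(); got <- 0; i <- 0
  while (got < n && i < 50 * ceiling(n / 9)) {
    i <- i + 1
    tree <- sample_vessel_tree(spec, seed = seed + i)
    img <- render_annotated(tree, spec, id = sprintf("%s_%04d", domain, i),
                            seed = seed + 100000L + i)
    ps <- retention_filter(extract_patches(img, patch_size), threshold)
    if (nrow(ps) > 0) {
      sets[[length(sets) + 1]] <- ps
      got <- got + nrow(ps)
    }
  }
  all <- bind_patches(sets)
  if (nrow(all) < n) {
    abort(sprintf("could only generate %d of %d requested patches",
                  nrow(all), n))
  }
  split_patches(all[seq_len(n), ], train_fraction = 0.9, seed = seed)
}
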