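# Automated evaluation protocols: prediction robustness under input
# perturbations, and segmentation of sub-cumulative frame sums from video
# streams.

#' An input perturbation for the robustness suite
#'
#' @param kind `"none"`, `"rotate90"`, `"rotate180"`, or `"noise"`.
#' @param magnitude Gaussian noise standard deviation as a fraction of the
#'   dynamic range (the published robustness test uses 0.10); ignored for
#'   rotations.
#' @param seed Optional seed for the noise draw.
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(kind = c("none", "rotate90", "rotate180",
                                       "noise"),
                              magnitude = 0.1, seed = NULL) {
  kind <- match.arg(kind)
  if (magnitude < 0) abort("`magnitude` must be >= 0")
  structure(list(kind = kind, magnitude = magnitude, seed = seed),
            class = "perturbation_spec")
}

# Any segmenter is a function image -> probability map; seg_models are
# wrapped via predict().
as_segmenter <- function(x) {
  if (inherits(x, "seg_model")) {
    function(img) predict(x, img)
  } else if (is.function(x)) {
    x
  } else {
    abort("`segmenter` must be a seg_model or a function(image) -> prob map")
  }
}

#' A fixed-threshold stub segmenter
#'
#' Returns a segmenter function mapping an image to the probability map
#' `1 - image` (vessels are dark, so darker pixels score higher). Exactly
#' equivariant under flips and right-angle rotations, which makes it the
#' reference harness probe for the robustness suite.
#'
#' @return A function `image -> probability map`.
#' @export
threshold_segmenter <- function() {
  function(img) 1 - img
}

apply_perturbation <- function(img, spec) {
  switch(spec$kind,
    none = img,
    rotate90 = rot90k(img, 1L),
    rotate180 = rot90k(img, 2L),
    noise = {
      if (spec$magnitude == 0) return(img)
      with_local_seed(spec$seed, {
        clip01(img + matrix(rnorm(length(img), 0, spec$magnitude),
                            nrow(img), ncol(img)))
      })
    })
}

invert_perturbation_mask <- function(mask, spec) {
  switch(spec$kind,
    rotate90 = rot90k(mask, -1L),
    rotate180 = rot90k(mask, -2L),
    mask)
}

#' Prediction robustness under input perturbations
#'
#' For each image the reference is the binarized prediction on the original;
#' each perturbation is applied to the input, the perturbed prediction is
#' binarized and mapped back to the reference frame (inverse rotation), both
#' masks are optionally reduced to their largest connected component, and
#' the Dice score against the reference is recorded.
#'
#' @param segmenter A `seg_model` or a function `image -> probability map`.
#' @param images A list of grayscale matrices (or [annotated_image()]s).
#' @param specs A list of [perturbation_spec()]s.
#' @param threshold Binarization threshold.
#' @param use_largest_component Reduce masks to their largest connected
#'   component before scoring (the published example protocol).
#' @return A tibble with one row per image x perturbation: `image`,
#'   `perturbation`, `magnitude`, `dice`. Summarize with
#'   [summarise_robustness()].
#' @export
robustness_suite <- function(segmenter, images, specs, threshold = 0.5,
                             use_largest_component = TRUE) {
  f <- as_segmenter(segmenter)
  if (inherits(images, "annotated_image") || is.matrix(images)) {
    images <- list(images)
  }
  if (inherits(specs, "perturbation_spec")) specs <- list(specs)
  reduce <- function(m) if (use_largest_component) largest_component(m) else m
  purrr::imap(images, function(img, i) {
    id <- if (inherits(img, "annotated_image")) img$id else as.character(i)
    x <- if (inherits(img, "annotated_image")) img$image else img
    ref <- reduce(binarize(f(x), threshold))
    purrr::map(specs, function(sp) {
      pred <- binarize(f(apply_perturbation(x, sp)), threshold)
      pred <- reduce(invert_perturbation_mask(pred, sp))
      tibble(image = id, perturbation = sp$kind,
             magnitude = if (sp$kind == "noise") sp$magnitude else NA_real_,
             dice = dice_score(pred, ref))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Mean and standard deviation of robustness Dice scores per perturbation
#'
#' @param tbl The output of [robustness_suite()].
#' @return A tibble with `perturbation`, `n`, `mean_dice`, `sd_dice`.
#' @export
summarise_robustness <- function(tbl) {
  tbl |>
    dplyr::group_by(.data$perturbation) |>
    dplyr::summarise(n = dplyr::n(), mean_dice = mean(.data$dice),
                     sd_dice = sd(.data$dice), .groups = "drop")
}

#' Aggregate a window of video frames into one image
#'
#' Pixelwise mean of frames `start, ..., start + gate - 1`, min-max rescaled
#' to `[0, 1]` (constant images pass through unchanged). Averaging rather
#' than summing keeps the intensity scale gate-invariant before the model
#' input; summation followed by rescaling is equivalent.
#'
#' @param fs A [frame_stack()].
#' @param gate Number of frames to aggregate.
#' @param start 1-based index of the first frame.
#' @return A matrix in `[0, 1]`.
#' @export
cumulate_frames <- function(fs, gate = length(fs$frames), start = 1) {
  n <- length(fs$frames)
  if (gate < 1) abort("`gate` must be >= 1")
  if (start < 1 || start + gate - 1 > n) {
    abort(sprintf("window [%d, %d] exceeds the %d available frames",
                  start, start + gate - 1, n))
  }
  acc <- Reduce(`+`, fs$frames[start:(start + gate - 1)]) / gate
  rng <- range(acc)
  if (rng[2] > rng[1]) (acc - rng[1]) / (rng[2] - rng[1]) else acc
}

#' Convert a frame-count gate to seconds
#'
#' `gate / fps`, reported to one decimal (at the 19.6 fps camera rate, 10
#' frames correspond to 0.5 s and 120 frames to 6.1 s).
#'
#' @param gate Frame count (>= 1).
#' @param fps Frame rate in frames per second.
#' @return Seconds, rounded to one decimal.
#' @export
gate_to_seconds <- function(gate, fps = 19.6) {
  if (any(gate < 1)) abort("`gate` must be >= 1")
  if (fps <= 0) abort("`fps` must be positive")
  round(gate / fps, 1)
}

#' Segmentation consistency across sub-cumulative frame windows
#'
#' The reference is the binarized prediction on the cumulation of the whole
#' stack. For each gate size, predictions on all disjoint consecutive
#' windows of that size are compared to the reference by Dice; the per-gate
#' mean and standard error quantify how much temporal resolution can be
#' traded for SNR before segmentation quality degrades.
#'
#' @inheritParams robustness_suite
#' @param fs A [frame_stack()].
#' @param gates Integer vector of gate sizes (frame counts).
#' @return A `gate_sweep` tibble with `gate_frames`, `gate_seconds`,
#'   `n_windows`, `mean_dice`, `se_dice`; `autoplot()` draws the mean ± SE
#'   trend.
#' @export
subcumulative_analysis <- function(segmenter, fs, gates, threshold = 0.5) {
  f <- as_segmenter(segmenter)
  n <- length(fs$frames)
  if (any(gates < 1) || any(gates > n)) {
    abort("all gates must lie in [1, n_frames]")
  }
  ref <- binarize(f(cumulate_frames(fs)), threshold)
  out <- purrr::map(gates, function(g) {
    starts <- seq(1, by = g, length.out = n %/% g)
    dices <- vapply(starts, function(s) {
      pred <- binarize(f(cumulate_frames(fs, gate = g, start = s)), threshold)
      dice_score(pred, ref)
    }, numeric(1))
    tibble(gate_frames = as.integer(g),
           gate_seconds = gate_to_seconds(g, fs$fps),
           n_windows = length(starts), mean_dice = mean(dices),
           se_dice = if (length(dices) > 1) {
             sd(dices) / sqrt(length(dices))
           } else NA_real_)
  }) |> dplyr::bind_rows()
  class(out) <- c("gate_sweep", class(out))
  out
}

#' @export
autoplot.gate_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gate_seconds,
                                       y = .data$mean_dice)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_dice - .data$se_dice,
      ymax = .data$mean_dice + .data$se_dice), width = 0.1, na.rm = TRUE) +
    ggplot2::labs(x = "cumulation time (s)", y = "Dice vs full cumulation") +
    ggplot2::theme_minimal()
}

#' Pairwise consistency of repeated segmentations
#'
#' Scores every unordered pair of masks by Dice and boundary IoU — the
#' computation a repeated-rater consistency study needs (the raters
#' themselves are outside this package's scope).
#'
#' @param masks A list of binary matrices (repeated segmentations of one
#'   image).
#' @param boundary_d Boundary-band half-width.
#' @return A tibble with one row per pair: `a`, `b`, `dice`, `boundary_iou`.
#' @export
pairwise_consistency <- function(masks, boundary_d = 2) {
  n <- length(masks)
  pairs <- utils::combn(n, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble(a = i, b = j, dice = dice_score(masks[[i]], masks[[j]]),
           boundary_iou = boundary_iou(masks[[i]], masks[[j]],
                                       d = boundary_d))
  }) |> dplyr::bind_rows()
}
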