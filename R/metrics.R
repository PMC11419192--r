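# Overlap metrics between binary masks: Dice, IoU (Jaccard), boundary IoU,
# and largest-connected-component reduction.

#' Dice score between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly and score 1; an
#' empty versus a non-empty mask scores 0.
#'
#' @param a,b Binary matrices of identical shape.
#' @return A value in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  check_same_shape(a, b, c("a", "b"))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Intersection-over-union (Jaccard) score between two binary masks
#'
#' `|A n B| / |A u B|`; two empty masks score 1.
#'
#' @inheritParams dice_score
#' @return A value in `[0, 1]`.
#' @export
iou_score <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  check_same_shape(a, b, c("a", "b"))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Mask pixels within Euclidean distance d of the mask's contour, where the
# image border also counts as contour (the mask is embedded in a one-pixel
# background ring before the exact distance transform).
boundary_band <- function(m, d) {
  H <- nrow(m); W <- ncol(m)
  padded <- matrix(0L, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- m
  dt <- cpp_distance_transform(padded)[2:(H + 1L), 2:(W + 1L)]
  (m == 1L) & (dt <= d)
}

#' Boundary IoU between two binary masks
#'
#' Each mask is intersected with the `d`-neighborhood of its own contour
#' (the set of mask pixels within Euclidean distance `d` of a background
#' pixel, with the image border treated as background); the IoU of the two
#' boundary bands is returned. Sensitive to boundary placement errors that
#' plain IoU dilutes over the mask interior; as `d` grows past the image
#' diagonal it reduces to [iou_score()].
#'
#' @inheritParams dice_score
#' @param d Band half-width in pixels (>= 1). The default of 2 px suits
#'   vessel-scale structures; the distance metric is Euclidean.
#' @return A value in `[0, 1]`.
#' @export
boundary_iou <- function(a, b, d = 2) {
  if (d < 1) abort("`d` must be >= 1")
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  check_same_shape(a, b, c("a", "b"))
  iou_score(boundary_band(a, d), boundary_band(b, d))
}

#' Largest connected foreground component of a binary mask
#'
#' Used to reduce a vessel prediction to its dominant connected structure
#' before consistency comparisons. Size ties are broken in favor of the
#' component containing the smallest row-major pixel position.
#'
#' @param m A binary matrix.
#' @param connectivity 4 or 8 (default 8: thin diagonal vessel strokes stay
#'   connected).
#' @return A binary matrix keeping only the largest component (an empty mask
#'   maps to itself).
#' @export
largest_component <- function(m, connectivity = 8) {
  m <- as_binary_mask(m)
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  if (sum(m) == 0) return(m)
  lab <- cpp_label_components(m, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # row-major position of each candidate's first pixel
    W <- ncol(m)
    key <- vapply(best, function(l) {
      idx <- which(lab == l)
      rows <- (idx - 1L) %% nrow(m)
      cols <- (idx - 1L) %/% nrow(m)
      min(rows * W + cols)
    }, numeric(1))
    best <- best[which.min(key)]
  }
  out <- (lab == best[1])
  storage.mode(out) <- "integer"
  out
}

#' Evaluate a predicted mask against a reference
#'
#' @param pred,ref Binary matrices of identical shape.
#' @param boundary_d Boundary-band half-width for [boundary_iou()].
#' @param connectivity Connectivity recorded alongside the report.
#' @return A one-row tibble with `dice`, `iou`, `boundary_iou`, `boundary_d`
#'   and `connectivity`.
#' @export
evaluate_masks <- function(pred, ref, boundary_d = 2, connectivity = 8) {
  tibble(
    dice = dice_score(pred, ref),
    iou = iou_score(pred, ref),
    boundary_iou = boundary_iou(pred, ref, d = boundary_d),
    boundary_d = boundary_d,
    connectivity = connectivity)
}

#' Evaluate many predicted/reference mask pairs
#'
#' @param pred,ref Lists of binary matrices (paired by position).
#' @param ids Optional identifiers (defaults to positions).
#' @inheritParams evaluate_masks
#' @return A tibble with one row per pair.
#' @export
evaluate_mask_pairs <- function(pred, ref, ids = NULL, boundary_d = 2,
                                connectivity = 8) {
  if (length(pred) != length(ref)) {
    abort("`pred` and `ref` must have equal length")
  }
  if (is.null(ids)) ids <- as.character(seq_along(pred))
  purrr::map2(pred, ref, evaluate_masks, boundary_d = boundary_d,
              connectivity = connectivity) |>
    dplyr::bind_rows() |>
    dplyr::mutate(id = ids, .before = 1)
}
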