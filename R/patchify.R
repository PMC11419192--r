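# Patch-based dataset construction: ROI selection, non-overlapping 224x224
# tiling, the 5%-labeled-area retention filter, and the 90/10 split.

new_patch_set <- function(tbl, patch_size, split_seed = NA_integer_) {
  tbl <- as_tibble(tbl)
  class(tbl) <- c("patch_set", class(tbl))
  attr(tbl, "patch_size") <- as.integer(patch_size)
  attr(tbl, "split_seed") <- split_seed
  tbl
}

#' @export
print.patch_set <- function(x, ...) {
  ps <- attr(x, "patch_size")
  spl <- if ("split" %in% names(x) && !all(is.na(x$split))) {
    sprintf(" (%d train / %d val)", sum(x$split == "train", na.rm = TRUE),
            sum(x$split == "val", na.rm = TRUE))
  } else ""
  cat(sprintf("<patch_set: %d patches of %d x %d px%s>\n",
              nrow(x), ps, ps, spl))
  NextMethod()
}

patch_size_of <- function(ps) {
  v <- attr(ps, "patch_size")
  if (is.null(v)) nrow(ps$image[[1]]) else v
}

#' Crop a centered square region sized for exact patch tiling
#'
#' Selects an `(N * patch_size)`-square region of interest. Fundus-like
#' source images use a centered crop by default (`N = 6` reproduces the
#' 36-patch layout used for 224 px patches); Cherenkov-like target images are
#' restricted to `N <= 4`, matching the beam-limited field of view, and
#' typically get an explicit center chosen from the vessel locations.
#'
#' @param img An [annotated_image()].
#' @param n_grid Integer `N`: the crop spans `N * patch_size` pixels per side.
#' @param center Optional `(row, col)` crop center; defaults to the image
#'   center.
#' @param patch_size Patch side length in pixels (224 throughout the paper's
#'   pipeline).
#' @return The cropped [annotated_image()]; the crop origin (0-based
#'   `(row, col)` of the top-left corner) is recorded in attribute
#'   `"roi_origin"`.
#' @export
select_roi <- function(img, n_grid, center = NULL, patch_size = 224) {
  if (!inherits(img, "annotated_image")) {
    abort("`img` must be an annotated_image")
  }
  n_grid <- as.integer(n_grid)
  if (n_grid < 1) abort("`n_grid` must be >= 1")
  if (img$domain == "target" && n_grid > 4) {
    abort("target-domain ROIs are limited to N <= 4 patch widths")
  }
  H <- nrow(img$image); W <- ncol(img$image)
  size <- n_grid * patch_size
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  r0 <- floor(center[1] - size / 2) + 1L
  c0 <- floor(center[2] - size / 2) + 1L
  if (r0 < 1 || r0 + size - 1 > H) {
    abort(sprintf("ROI rows out of bounds: need %d rows, image has %d",
                  size, H))
  }
  if (c0 < 1 || c0 + size - 1 > W) {
    abort(sprintf("ROI cols out of bounds: need %d cols, image has %d",
                  size, W))
  }
  rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
  out <- annotated_image(img$image[rows, cols], img$mask[rows, cols],
                         img$domain, img$id)
  attr(out, "roi_origin") <- as.integer(c(r0 - 1, c0 - 1))
  out
}

#' Tile an image into non-overlapping square patches
#'
#' Both image dimensions must be exact multiples of `patch_size`. Patches are
#' emitted in row-major order (left-to-right within a row of tiles, top row
#' first), so reassembling them at their recorded origins reconstructs the
#' input losslessly.
#'
#' @param img An [annotated_image()] (typically the output of
#'   [select_roi()]).
#' @param patch_size Patch side length in pixels.
#' @return A `patch_set`: a tibble with columns `parent`, `origin_row`,
#'   `origin_col` (0-based offsets of the tile in the parent image),
#'   `labeled_fraction`, list-columns `image` and `mask`, and a `split`
#'   column (`NA` until [split_patches()] is applied).
#' @export
extract_patches <- function(img, patch_size = 224) {
  if (!inherits(img, "annotated_image")) {
    abort("`img` must be an annotated_image")
  }
  H <- nrow(img$image); W <- ncol(img$image)
  if (H %% patch_size != 0 || W %% patch_size != 0) {
    abort(sprintf(
      "image dimensions (%d x %d) must be exact multiples of the patch size %d",
      H, W, patch_size))
  }
  nr <- H %/% patch_size; nc <- W %/% patch_size
  rows <- list()
  for (pr in seq_len(nr) - 1L) {
    for (pc in seq_len(nc) - 1L) {
      ri <- pr * patch_size + seq_len(patch_size)
      ci <- pc * patch_size + seq_len(patch_size)
      tile_m <- img$mask[ri, ci]
      rows[[length(rows) + 1]] <- tibble(
        parent = img$id,
        origin_row = pr * as.integer(patch_size),
        origin_col = pc * as.integer(patch_size),
        labeled_fraction = mean(tile_m),
        image = list(img$image[ri, ci]),
        mask = list(tile_m),
        split = NA_character_)
    }
  }
  new_patch_set(dplyr::bind_rows(rows), patch_size)
}

#' Retain patches whose labeled area exceeds a threshold
#'
#' Keeps exactly the patches whose vessel-positive pixel fraction is
#' *strictly* greater than `threshold` (default 5% of the patch area),
#' preserving order. Idempotent.
#'
#' @param ps A `patch_set`.
#' @param threshold Labeled-area fraction in `[0, 1)`.
#' @return The filtered `patch_set`.
#' @export
retention_filter <- function(ps, threshold = 0.05) {
  if (threshold < 0 || threshold >= 1) abort("`threshold` must lie in [0, 1)")
  keep <- ps$labeled_fraction > threshold
  new_patch_set(ps[keep, ], patch_size_of(ps), attr(ps, "split_seed"))
}

#' Randomly split patches into training and validation sets
#'
#' A uniformly random permutation under `seed` assigns the first
#' `round(train_fraction * n)` patches (round half up) to training and the
#' rest to validation; deterministic per seed.
#'
#' @param ps A `patch_set` with at least one patch.
#' @param train_fraction Training fraction (0.9 in the paper's protocol).
#' @param seed RNG seed.
#' @return The `patch_set` with its `split` column filled with
#'   `"train"` / `"val"`. Warns when the validation split comes out empty.
#' @export
split_patches <- function(ps, train_fraction = 0.9, seed = 1) {
  n <- nrow(ps)
  if (n == 0) abort("cannot split an empty patch set")
  n_train <- min(n, floor(train_fraction * n + 0.5))
  perm <- with_local_seed(seed, sample.int(n))
  split <- rep("val", n)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_train == n) {
    warn("validation split is empty; consider more patches or a smaller train_fraction")
  }
  ps$split <- split
  new_patch_set(ps, patch_size_of(ps), as.integer(seed))
}

#' ROI-crop, tile, filter and split one annotated image
#'
#' Chains [select_roi()], [extract_patches()], [retention_filter()] and
#' [split_patches()].
#'
#' @inheritParams select_roi
#' @inheritParams retention_filter
#' @inheritParams split_patches
#' @return A split `patch_set`.
#' @export
patchify_image <- function(img, n_grid, center = NULL, patch_size = 224,
                           threshold = 0.05, train_fraction = 0.9, seed = 1) {
  img |>
    select_roi(n_grid, center = center, patch_size = patch_size) |>
    extract_patches(patch_size = patch_size) |>
    retention_filter(threshold = threshold) |>
    split_patches(train_fraction = train_fraction, seed = seed)
}

#' Combine patch sets from several images
#'
#' @param ... `patch_set` objects (or a single list of them).
#' @return One `patch_set` with rows concatenated.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "patch_set")) {
    sets <- sets[[1]]
  }
  ps <- patch_size_of(sets[[1]])
  new_patch_set(dplyr::bind_rows(lapply(sets, as_tibble)), ps)
}
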