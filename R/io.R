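# Readers and writers for the standard interchange formats: PNG/TIFF
# image+mask pairs with YAML sidecars, multi-page TIFF frame stacks, and
# patch archives with CSV manifests.

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format: '%s'", ext)))
  if (length(dim(img)) == 3) {
    # simple luminance for RGB(A) input
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

write_gray <- function(img, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
    abort(sprintf("unsupported image format: '%s'", ext)))
  invisible(path)
}

#' Read an image/mask pair from disk
#'
#' Images are read as grayscale in `[0, 1]` (RGB input is converted by
#' luminance); masks are binarized at 0.5 (so 0/255 8-bit masks round-trip).
#'
#' @param image_path,mask_path PNG or TIFF files.
#' @param domain `"source"` or `"target"`.
#' @param id Identifier; defaults to the image file stem.
#' @return An [annotated_image()].
#' @export
read_annotated <- function(image_path, mask_path, domain = "source",
                           id = NULL) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(image_path))
  mask <- read_gray(mask_path) > 0.5
  storage.mode(mask) <- "integer"
  annotated_image(clip01(read_gray(image_path)), mask,
                  domain = domain, id = id)
}

#' Write an image/mask pair plus a YAML sidecar
#'
#' Writes `<id>_image.<fmt>`, `<id>_mask.<fmt>` (mask as 0/255 8-bit) and
#' `<id>.yaml` recording the domain, id, and any phantom spec/seed supplied.
#'
#' @param img An [annotated_image()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @param spec Optional [phantom_spec()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_annotated <- function(img, dir, format = c("png", "tiff"), spec = NULL,
                            seed = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, img$id)
  write_gray(img$image, paste0(base, "_image.", format))
  write_gray(img$mask + 0, paste0(base, "_mask.", format), bits = 8L)
  meta <- list(id = img$id, domain = img$domain,
               shape = dim(img$image), labeled_fraction = mean(img$mask))
  if (!is.null(spec)) {
    meta$spec <- lapply(unclass(spec), function(v) {
      if (is.null(v)) NULL else unclass(v)
    })
  }
  if (!is.null(seed)) meta$seed <- seed
  yaml::write_yaml(meta, paste0(base, ".yaml"))
  invisible(paste0(base, ".yaml"))
}

#' Write / read a frame stack as multi-page TIFF with a YAML sidecar
#'
#' Frames are stored as 16-bit grayscale pages; the sidecar records the
#' frame rate and frame count, and the reference mask (if any) is stored as
#' `<stem>_refmask.png`.
#'
#' @param fs A [frame_stack()].
#' @param path Output `.tiff` path.
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns the [frame_stack()].
#' @export
write_frame_stack <- function(fs, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(fs$frames, path, bits.per.sample = 16L)
  stem <- tools::file_path_sans_ext(path)
  if (!is.null(fs$ref_mask)) {
    png::writePNG(fs$ref_mask + 0, paste0(stem, "_refmask.png"))
  }
  yaml::write_yaml(list(fps = fs$fps, n_frames = length(fs$frames),
                        shape = dim(fs$frames[[1]])),
                   paste0(stem, ".yaml"))
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  stem <- tools::file_path_sans_ext(path)
  meta_path <- paste0(stem, ".yaml")
  fps <- 19.6
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$fps)) fps <- meta$fps
  }
  ref <- NULL
  ref_path <- paste0(stem, "_refmask.png")
  if (file.exists(ref_path)) {
    ref <- ifelse(png::readPNG(ref_path) > 0.5, 1L, 0L)
  }
  frame_stack(frames, fps = fps, ref_mask = ref)
}

#' Write / read a patch archive
#'
#' One PNG pair per patch plus `manifest.csv` with columns `patch`,
#' `parent`, `origin_row`, `origin_col`, `labeled_fraction`, `split`.
#'
#' @param ps A `patch_set`.
#' @param dir Archive directory.
#' @return `write_patches()` returns `dir` invisibly; `read_patches()`
#'   returns the `patch_set`.
#' @export
write_patches <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names_ <- sprintf("patch_%05d", seq_len(nrow(ps)))
  for (i in seq_len(nrow(ps))) {
    png::writePNG(ps$image[[i]], file.path(dir, paste0(names_[i], "_image.png")))
    png::writePNG(ps$mask[[i]] + 0, file.path(dir, paste0(names_[i], "_mask.png")))
  }
  manifest <- tibble(patch = names_, parent = ps$parent,
                     origin_row = ps$origin_row, origin_col = ps$origin_col,
                     labeled_fraction = ps$labeled_fraction,
                     split = ps$split)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patches
#' @export
read_patches <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- purrr::map(manifest$patch, function(p) {
    clip01(read_gray(file.path(dir, paste0(p, "_image.png"))))
  })
  masks <- purrr::map(manifest$patch, function(p) {
    m <- read_gray(file.path(dir, paste0(p, "_mask.png")))
    m <- (m > 0.5)
    storage.mode(m) <- "integer"
    m
  })
  tbl <- tibble(parent = manifest$parent,
                origin_row = as.integer(manifest$origin_row),
                origin_col = as.integer(manifest$origin_col),
                labeled_fraction = manifest$labeled_fraction,
                image = images, mask = masks,
                split = as.character(manifest$split))
  tbl$split[tbl$split %in% c("", "NA")] <- NA_character_
  new_patch_set(tbl, nrow(images[[1]]))
}
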