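# Synthetic vascular phantoms for the two imaging domains.
#
# The generator grows a connected branching vessel tree by a biased random
# walk and renders it either as a high-contrast fundus-like image (source
# domain) or as a noisy, beam-limited Cherenkov-like image (target domain),
# plus optional video streams with sinusoidal breathing displacement.

#' Parameters of the synthetic vessel phantom
#'
#' Describes both the vessel-tree growth process and the rendering of one of
#' the two imaging domains. Unspecified arguments take domain-dependent
#' defaults: the source domain mimics high-contrast fundus photographs
#' (bright background, dark well-resolved vessels, little noise); the target
#' domain mimics cumulative Cherenkov images (low vessel contrast, strong
#' noise, signal confined to a bright beam-shaped region).
#'
#' @param domain `"source"` or `"target"`.
#' @param image_size Image extent in pixels; a scalar (square) or
#'   `c(rows, cols)`.
#' @param n_roots Number of root vessels seeded on a circle around the image
#'   center.
#' @param branch_prob Probability, per growth step, that the growing vessel
#'   bifurcates into two children.
#' @param step_length Centerline step length in pixels.
#' @param max_steps Total step budget along any root-to-tip path; branching
#'   children inherit the remaining budget, so growth always terminates.
#' @param width_range Range (pixels) from which each root stroke width is
#'   drawn; child branches shrink by `width_decay`.
#' @param width_decay Multiplicative width reduction at each bifurcation.
#' @param turn_sd Standard deviation (radians) of the per-step random heading
#'   change of the biased walk.
#' @param branch_angle Mean half-angle (radians) between the two children at
#'   a bifurcation.
#' @param contrast Vessel-to-background contrast in `(0, 1]`: vessel pixels
#'   render at `background * (1 - contrast)`.
#' @param background Background intensity level in `[0, 1]`.
#' @param noise_sigma Standard deviation of additive Gaussian noise, as a
#'   fraction of the `[0, 1]` dynamic range.
#' @param beam Target-domain beam region, a list with elements `semi_axes`
#'   (fractions of the image half-extent), `exponent` (superellipse shape
#'   exponent) and `floor` (multiplicative intensity retained outside the
#'   beam). Ignored for the source domain.
#' @param motion_amplitude Breathing displacement amplitude in pixels
#'   (video only; 0 reproduces the breath-hold regime).
#' @param motion_period Breathing period in seconds (video only).
#' @param seed Default RNG seed used by the generators when no explicit seed
#'   is passed.
#' @return A `phantom_spec` object (a validated list).
#' @examples
#' spec <- phantom_spec("source", image_size = 256, seed = 1)
#' tree <- sample_vessel_tree(spec)
#' ann <- render_annotated(tree, spec)
#' range(ann$image)
#' @export
phantom_spec <- function(domain = c("source", "target"),
                         image_size = 448,
                         n_roots = 3,
                         branch_prob = 0.1,
                         step_length = 6,
                         max_steps = 40,
                         width_range = c(3, 7),
                         width_decay = 0.75,
                         turn_sd = 0.22,
                         branch_angle = 0.5,
                         contrast = NULL,
                         background = NULL,
                         noise_sigma = NULL,
                         beam = NULL,
                         motion_amplitude = 0,
                         motion_period = 3,
                         seed = NULL) {
  domain <- match.arg(domain)
  if (is.null(contrast)) contrast <- if (domain == "source") 0.8 else 0.35
  if (is.null(background)) background <- if (domain == "source") 0.85 else 0.6
  if (is.null(noise_sigma)) noise_sigma <- if (domain == "source") 0.03 else 0.12
  if (domain == "target" && is.null(beam)) {
    beam <- list(semi_axes = c(0.8, 0.9), exponent = 4, floor = 0.03)
  }
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  spec <- structure(list(
    domain = domain, image_size = as.integer(image_size), n_roots = n_roots,
    branch_prob = branch_prob, step_length = step_length,
    max_steps = as.integer(max_steps), width_range = width_range,
    width_decay = width_decay, turn_sd = turn_sd, branch_angle = branch_angle,
    contrast = contrast, background = background, noise_sigma = noise_sigma,
    beam = beam, motion_amplitude = motion_amplitude,
    motion_period = motion_period, seed = seed
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec")
  if (any(spec$image_size < 1)) abort("`image_size` must be positive")
  if (spec$branch_prob < 0 || spec$branch_prob > 1) {
    abort("`branch_prob` must lie in [0, 1]")
  }
  if (spec$noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  if (spec$contrast <= 0 || spec$contrast > 1) {
    abort("`contrast` must lie in (0, 1]")
  }
  if (spec$background < 0 || spec$background > 1) {
    abort("`background` must lie in [0, 1]")
  }
  if (spec$step_length <= 0) abort("`step_length` must be positive")
  if (spec$max_steps < 1) abort("`max_steps` must be >= 1")
  if (any(spec$width_range <= 0)) abort("`width_range` must be positive")
  if (spec$motion_amplitude < 0) abort("`motion_amplitude` must be >= 0")
  if (spec$motion_period <= 0) abort("`motion_period` must be positive")
  invisible(spec)
}

#' Construct a vessel tree directly
#'
#' Mostly used by [sample_vessel_tree()]; direct construction is useful for
#' controlled fixtures (including the empty tree).
#'
#' @param segments List of centerline polylines, each an `n x 2` matrix of
#'   `(row, col)` pixel coordinates with at least two points.
#' @param widths Per-segment stroke width in pixels.
#' @param extent Image extent `c(rows, cols)` the tree lives in.
#' @param parents Integer parent index per segment (`NA` for roots). When
#'   given, each child must start on its parent's centerline.
#' @return A `vessel_tree` object.
#' @export
vessel_tree <- function(segments, widths, extent,
                        parents = rep(NA_integer_, length(segments))) {
  if (length(segments) != length(widths)) {
    abort("`segments` and `widths` must have equal length")
  }
  for (s in segments) {
    if (!is.matrix(s) || ncol(s) != 2 || nrow(s) < 2) {
      abort("every segment must be an n x 2 matrix with at least 2 points")
    }
  }
  if (length(widths) && any(widths <= 0)) abort("all widths must be > 0")
  for (i in seq_along(parents)) {
    p <- parents[i]
    if (!is.na(p)) {
      d <- sqrt(colSums((t(segments[[p]]) - segments[[i]][1, ])^2))
      if (min(d) > 1e-6) {
        abort("each non-root segment must start on its parent's centerline")
      }
    }
  }
  structure(list(segments = segments, widths = widths,
                 extent = as.integer(extent), parents = parents),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree: %d segments in %d x %d px>\n",
              length(x$segments), x$extent[1], x$extent[2]))
  invisible(x)
}

#' Sample a random branching vessel tree
#'
#' Grows a connected tree by a biased random walk: each vessel advances in
#' steps of `step_length` pixels with a small random heading change, and at
#' every step may bifurcate (probability `branch_prob`) into two thinner
#' children that inherit the remaining step budget. The result is
#' deterministic in `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A [vessel_tree()].
#' @export
sample_vessel_tree <- function(spec, seed = spec$seed) {
  validate_phantom_spec(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_local_seed(seed, {
    segments <- list(); widths <- numeric(); parents <- integer()
    stack <- list()
    ctr <- c((H + 1) / 2, (W + 1) / 2)
    rad <- 0.42 * min(H, W)
    for (i in seq_len(spec$n_roots)) {
      theta <- runif(1, 0, 2 * pi)
      start <- ctr + rad * c(sin(theta), cos(theta))
      # heading toward the center, jittered
      inward <- atan2(ctr[2] - start[2], ctr[1] - start[1])
      stack[[length(stack) + 1]] <- list(
        pos = start, angle = inward + rnorm(1, 0, 0.3),
        budget = spec$max_steps,
        width = runif(1, spec$width_range[1], spec$width_range[2]),
        parent = NA_integer_)
    }
    while (length(stack)) {
      task <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      p <- task$pos; a <- task$angle
      budget <- task$budget; w <- task$width
      pts <- matrix(p, ncol = 2)
      child_tasks <- list()
      while (budget > 0) {
        a <- a + rnorm(1, 0, spec$turn_sd)
        p <- p + spec$step_length * c(cos(a), sin(a))
        clamped <- pmin(pmax(p, 1), c(H, W))
        hit_border <- any(clamped != p)
        p <- clamped
        pts <- rbind(pts, p)
        budget <- budget - 1
        if (hit_border) break
        if (budget > 0 && runif(1) < spec$branch_prob) {
          wc <- max(w * spec$width_decay, 1)
          phi <- abs(spec$branch_angle + rnorm(1, 0, 0.15))
          child_tasks <- list(
            list(pos = p, angle = a + phi, budget = budget, width = wc),
            list(pos = p, angle = a - phi, budget = budget, width = wc))
          break
        }
      }
      if (nrow(pts) >= 2) {
        segments[[length(segments) + 1]] <- unname(pts)
        widths <- c(widths, w)
        parents <- c(parents, task$parent)
        for (ct in child_tasks) {
          ct$parent <- length(segments)
          stack[[length(stack) + 1]] <- ct
        }
      }
    }
    vessel_tree(segments, widths, c(H, W), parents)
  })
}

#' Rasterize a vessel tree to a binary mask
#'
#' Strokes each centerline with its segment width by stamping disks along a
#' densely resampled polyline. An optional `(row, col)` shift displaces the
#' centerlines *before* rasterization, so sub-pixel motion introduces no
#' interpolation artifacts.
#'
#' @param tree A [vessel_tree()].
#' @param shift Numeric `(row, col)` displacement in pixels.
#' @param extent Output extent; defaults to the tree's.
#' @return An integer 0/1 matrix.
#' @export
rasterize_tree <- function(tree, shift = c(0, 0), extent = tree$extent) {
  if (!inherits(tree, "vessel_tree")) abort("`tree` must be a vessel_tree")
  if (length(tree$segments) == 0) {
    return(matrix(0L, extent[1], extent[2]))
  }
  pts <- vector("list", length(tree$segments))
  rads <- vector("list", length(tree$segments))
  for (i in seq_along(tree$segments)) {
    seg <- tree$segments[[i]]
    dens <- resample_polyline(seg, spacing = 0.5)
    pts[[i]] <- dens
    rads[[i]] <- rep(tree$widths[i] / 2, nrow(dens))
  }
  allpts <- do.call(rbind, pts)
  allpts[, 1] <- allpts[, 1] + shift[1]
  allpts[, 2] <- allpts[, 2] + shift[2]
  cpp_draw_disks(allpts, unlist(rads), extent[1], extent[2])
}

# Resample a polyline at roughly even arc-length spacing (keeps vertices).
resample_polyline <- function(seg, spacing = 0.5) {
  out <- list(seg[1, , drop = FALSE])
  for (i in seq_len(nrow(seg) - 1)) {
    a <- seg[i, ]; b <- seg[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / spacing))
    t <- seq_len(n) / n
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' An annotated image: intensity field plus binary vasculature mask
#'
#' @param image Numeric matrix with finite values in `[0, 1]`.
#' @param mask Binary matrix of the same shape (1 on vessel).
#' @param domain `"source"` or `"target"`.
#' @param id Identifier string.
#' @return An `annotated_image` object.
#' @export
annotated_image <- function(image, mask, domain = c("source", "target"),
                            id = "image") {
  domain <- match.arg(domain)
  if (!is.matrix(image)) abort("`image` must be a matrix")
  mask <- as_binary_mask(mask)
  check_same_shape(image, mask, c("image", "mask"))
  if (any(!is.finite(image)) || any(image < 0) || any(image > 1)) {
    abort("`image` values must be finite and lie in [0, 1]")
  }
  structure(list(image = image, mask = mask, domain = domain, id = id),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image '%s': %d x %d px, %s domain, %.1f%% labeled>\n",
              x$id, nrow(x$image), ncol(x$image), x$domain,
              100 * mean(x$mask)))
  invisible(x)
}

beam_region <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  b <- spec$beam
  ctr <- if (!is.null(b$center)) b$center else c((H + 1) / 2, (W + 1) / 2)
  ar <- b$semi_axes[1] * (H / 2)
  ac <- b$semi_axes[2] * (W / 2)
  r <- abs((seq_len(H) - ctr[1]) / ar)^b$exponent
  c <- abs((seq_len(W) - ctr[2]) / ac)^b$exponent
  outer(r, c, `+`) <= 1
}

#' Render a vessel tree as an annotated image
#'
#' The mask is the rasterized tree; the image is a uniform background with
#' vessels darkened by the contrast factor
#' (`background * (1 - contrast)` on vessel pixels), plus additive Gaussian
#' noise clipped to `[0, 1]`. In the target domain the signal (and the
#' annotation) is restricted to a bright superellipse beam region; outside it
#' the intensity drops to the beam floor, mimicking the Cherenkov beam
#' footprint.
#'
#' @param tree A [vessel_tree()].
#' @param spec The [phantom_spec()] that describes the rendering domain.
#' @param id Identifier for the resulting image.
#' @param seed RNG seed for the noise draw; defaults to `spec$seed`.
#' @param clip Clip intensities to `[0, 1]` after noise addition (the
#'   default). Disable to inspect raw noise moments; the result may then
#'   leave `[0, 1]` and is returned as a plain list.
#' @return An [annotated_image()] (or a plain list when `clip = FALSE`).
#' @export
render_annotated <- function(tree, spec, id = "phantom", seed = spec$seed,
                             clip = TRUE) {
  validate_phantom_spec(spec)
  mask <- rasterize_tree(tree, extent = spec$image_size)
  img <- spec$background * (1 - spec$contrast * mask)
  if (spec$domain == "target") {
    inside <- beam_region(spec)
    img[!inside] <- img[!inside] * spec$beam$floor
    mask[!inside] <- 0L
  }
  if (spec$noise_sigma > 0) {
    img <- img + with_local_seed(seed, {
      matrix(rnorm(length(img), 0, spec$noise_sigma), nrow(img), ncol(img))
    })
  }
  if (!clip) {
    return(list(image = img, mask = mask, domain = spec$domain, id = id))
  }
  annotated_image(clip01(img), mask, spec$domain, id)
}

#' An ordered stack of video frames with a frame rate
#'
#' @param frames List of numeric matrices of identical shape.
#' @param fps Frame rate in frames per second (19.6 for the Cherenkov camera
#'   this package models).
#' @param ref_mask Optional ground-truth vasculature mask at the rest
#'   position.
#' @param masks Optional per-frame ground-truth masks.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps = 19.6, ref_mask = NULL, masks = NULL) {
  if (length(frames) < 1) abort("a frame stack needs at least one frame")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) abort("all frames must have the same shape")
  }
  if (fps <= 0) abort("`fps` must be positive")
  if (!is.null(ref_mask)) ref_mask <- as_binary_mask(ref_mask, "ref_mask")
  structure(list(frames = frames, fps = fps, ref_mask = ref_mask,
                 masks = masks),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack: %d frames of %d x %d px at %.1f fps (%.1f s)>\n",
              length(x$frames), d[1], d[2], x$fps, length(x$frames) / x$fps))
  invisible(x)
}

#' Render a phantom video stream
#'
#' Each frame is an independent-noise rendering of the tree. With a positive
#' motion amplitude the centerlines are displaced vertically by
#' `A * sin(2 * pi * t / period)` sampled at the frame rate (free-breathing
#' mode); amplitude 0 reproduces the static breath-hold regime. The reference
#' mask is the rasterization at the rest position.
#'
#' @param tree A [vessel_tree()].
#' @param spec A [phantom_spec()]; `motion_amplitude` (pixels) and
#'   `motion_period` (seconds) control the breathing displacement.
#' @param n_frames Number of frames (>= 1).
#' @param fps Frame rate in frames per second.
#' @param seed RNG seed for the per-frame noise.
#' @param return_masks Also keep the per-frame displaced ground-truth masks.
#' @return A [frame_stack()].
#' @export
render_video <- function(tree, spec, n_frames, fps = 19.6, seed = spec$seed,
                         return_masks = FALSE) {
  validate_phantom_spec(spec)
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  H <- spec$image_size[1]; W <- spec$image_size[2]
  inside <- if (spec$domain == "target") beam_region(spec) else NULL
  ref_mask <- rasterize_tree(tree, extent = spec$image_size)
  if (!is.null(inside)) ref_mask[!inside] <- 0L
  with_local_seed(seed, {
    frames <- vector("list", n_frames)
    masks <- if (return_masks) vector("list", n_frames) else NULL
    for (f in seq_len(n_frames)) {
      t <- (f - 1) / fps
      disp <- spec$motion_amplitude * sin(2 * pi * t / spec$motion_period)
      m <- rasterize_tree(tree, shift = c(disp, 0), extent = spec$image_size)
      img <- spec$background * (1 - spec$contrast * m)
      if (!is.null(inside)) {
        img[!inside] <- img[!inside] * spec$beam$floor
        m[!inside] <- 0L
      }
      if (spec$noise_sigma > 0) {
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma), H, W)
      }
      frames[[f]] <- clip01(img)
      if (return_masks) masks[[f]] <- m
    }
    frame_stack(frames, fps = fps, ref_mask = ref_mask, masks = masks)
  })
}

#' Simulate a batch of annotated phantom images
#'
#' Convenience wrapper drawing `n` independent trees and rendering each;
#' image `i` uses seed `seed + i - 1`.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of images.
#' @param seed Base RNG seed.
#' @return A list of [annotated_image()] objects.
#' @export
simulate_annotated <- function(spec, n, seed = 1) {
  purrr::map(seq_len(n), function(i) {
    s <- seed + i - 1
    tree <- sample_vessel_tree(spec, seed = s)
    render_annotated(tree, spec, id = sprintf("%s_%03d", spec$domain, i),
                     seed = s + 500000L)
  })
}
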