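test_that("tree growth is deterministic and respects the branching process", {
  spec <- phantom_spec("source", image_size = 256, seed = 42)
  t1 <- sample_vessel_tree(spec)
  t2 <- sample_vessel_tree(spec)
  expect_identical(t1, t2)

  # no branching events possible
  solo <- phantom_spec("source", image_size = 256, n_roots = 1,
                       branch_prob = 0, max_steps = 10, seed = 7)
  expect_length(sample_vessel_tree(solo)$segments, 1L)

  # certain bifurcation: segment count equals the full binary expansion of
  # the step budget, checked against an independent enumeration
  for (budget in 1:4) {
    certain <- phantom_spec("source", image_size = 2048, n_roots = 1,
                            branch_prob = 1, max_steps = budget,
                            step_length = 2, seed = 3)
    expect_length(sample_vessel_tree(certain)$segments,
                  oracle_full_binary_segments(budget))
  }
})

test_that("generated trees are connected and geometrically valid", {
  spec <- phantom_spec("target", image_size = 300, seed = 11)
  tree <- sample_vessel_tree(spec)
  expect_true(all(tree$widths > 0))
  for (i in seq_along(tree$segments)) {
    seg <- tree$segments[[i]]
    expect_gte(nrow(seg), 2)
    expect_true(all(seg[, 1] >= 1 & seg[, 1] <= 300))
    p <- tree$parents[i]
    if (!is.na(p)) {
      gaps <- sqrt(colSums((t(tree$segments[[p]]) - seg[1, ])^2))
      expect_lt(min(gaps), 1e-8)
    }
  }
})

test_that("noise-free rendering is exact and co-registered with the mask", {
  tree <- straight_tree(64, width = 3)
  spec <- phantom_spec("source", image_size = 64, contrast = 1,
                       background = 1, noise_sigma = 0)
  ann <- render_annotated(tree, spec)
  # centerline pixels at full contrast on unit background are exactly 0
  expect_true(all(ann$image[32, 10:54] == 0))
  expect_true(all(ann$image[ann$mask == 0] == 1))
  # pixels darker than background are exactly the mask support
  dimmer <- phantom_spec("source", image_size = 64, contrast = 0.6,
                         background = 0.8, noise_sigma = 0)
  ann2 <- render_annotated(tree, dimmer)
  expect_identical((ann2$image < 0.8) + 0L, ann2$mask + 0L)
})

test_that("an empty tree renders an all-zero mask", {
  empty <- vessel_tree(list(), numeric(), extent = c(32, 32))
  spec <- phantom_spec("source", image_size = 32, noise_sigma = 0)
  ann <- render_annotated(empty, spec)
  expect_identical(sum(ann$mask), 0L)
})

test_that("background noise has the configured standard deviation", {
  empty <- vessel_tree(list(), numeric(), extent = c(128, 128))
  spec <- phantom_spec("source", image_size = 128, background = 0.5,
                       noise_sigma = 0.1, seed = 5)
  raw <- render_annotated(empty, spec, clip = FALSE)
  expect_lt(abs(sd(raw$image - 0.5) - 0.1), 0.01)
})

test_that("target-domain rendering restricts signal to the beam region", {
  spec <- phantom_spec("target", image_size = 128, noise_sigma = 0, seed = 2)
  tree <- sample_vessel_tree(spec)
  ann <- render_annotated(tree, spec)
  inside <- cherenkovseg:::beam_region(spec)
  expect_true(all(ann$mask[!inside] == 0L))
  expect_lt(max(ann$image[!inside]), 0.1)
  expect_gt(mean(ann$image[inside]), 0.3)
})

test_that("video rendering reproduces static, periodic and displaced regimes", {
  tree <- straight_tree(48, width = 3, margin = 14)
  static <- phantom_spec("source", image_size = 48, noise_sigma = 0,
                         motion_amplitude = 0)
  fs <- render_video(tree, static, n_frames = 5, seed = 1)
  for (f in fs$frames[-1]) expect_identical(f, fs$frames[[1]])

  # a full breathing cycle returns to the starting displacement
  n <- 8; fps <- 19.6
  cyc <- phantom_spec("source", image_size = 48, noise_sigma = 0,
                      motion_amplitude = 4, motion_period = n / fps)
  fsc <- render_video(tree, cyc, n_frames = n + 1, fps = fps, seed = 1,
                      return_masks = TRUE)
  expect_identical(fsc$masks[[n + 1]], fsc$masks[[1]])

  # quarter-period frame shifts the mask centroid by exactly the amplitude
  f0 <- 5
  quarter <- phantom_spec("source", image_size = 48, noise_sigma = 0,
                          motion_amplitude = 3,
                          motion_period = 4 * f0 / fps)
  fsq <- render_video(tree, quarter, n_frames = f0 + 1, fps = fps, seed = 1,
                      return_masks = TRUE)
  centroid_row <- function(m) mean(which(m == 1, arr.ind = TRUE)[, 1])
  expect_equal(centroid_row(fsq$masks[[f0 + 1]]) -
                 centroid_row(fsq$masks[[1]]), 3, tolerance = 1e-10)

  expect_error(render_video(tree, static, n_frames = 0), "n_frames")
})

test_that("frame averaging improves SNR as the square root of the gate", {
  tree <- straight_tree(96, width = 5, margin = 20)
  spec <- phantom_spec("source", image_size = 96, background = 0.6,
                       contrast = 0.5, noise_sigma = 0.08,
                       motion_amplitude = 0)
  fs <- render_video(tree, spec, n_frames = 64, seed = 9)
  mask <- fs$ref_mask == 1L
  snr <- function(img) {
    (mean(img[!mask]) - mean(img[mask])) / sd(img[!mask])
  }
  base <- snr(cumulate_frames(fs, gate = 1))
  for (k in c(4, 16, 64)) {
    ratio <- snr(cumulate_frames(fs, gate = k)) / base
    expect_lt(abs(ratio - sqrt(k)) / sqrt(k), 0.10)
  }
})

test_that("phantom specs are validated", {
  expect_error(phantom_spec("source", image_size = 0), "image_size")
  expect_error(phantom_spec("source", branch_prob = 1.4), "branch_prob")
  expect_error(phantom_spec("source", noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec("source", contrast = 0), "contrast")
})
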