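stub <- threshold_segmenter()

make_phantom_image <- function(seed = 1, size = 96, noise = 0) {
  spec <- phantom_spec("source", image_size = size, noise_sigma = noise,
                       background = 0.8, contrast = 0.7)
  render_annotated(sample_vessel_tree(spec, seed = seed), spec,
                   id = paste0("ph", seed), seed = seed + 100)
}

test_that("the robustness harness scores an equivariant segmenter perfectly", {
  imgs <- lapply(1:3, make_phantom_image)
  specs <- list(perturbation_spec("none"),
                perturbation_spec("rotate90"),
                perturbation_spec("rotate180"),
                perturbation_spec("noise", magnitude = 0))
  tbl <- robustness_suite(stub, imgs, specs)
  expect_identical(nrow(tbl), 12L)
  expect_true(all(tbl$dice == 1))
  smry <- summarise_robustness(tbl)
  expect_true(all(smry$mean_dice == 1))
})

test_that("noise perturbations degrade while rotations stay exact", {
  imgs <- lapply(4:6, make_phantom_image, noise = 0.05)
  specs <- list(perturbation_spec("rotate90"),
                perturbation_spec("rotate180"),
                perturbation_spec("noise", magnitude = 0.10, seed = 2))
  tbl <- robustness_suite(stub, imgs, specs)
  rot <- tbl$dice[tbl$perturbation != "noise"]
  noi <- tbl$dice[tbl$perturbation == "noise"]
  expect_true(all(rot == 1))
  expect_true(all(noi < 1))
  expect_true(all(noi > 0.5))
})

test_that("rotate-predict-unrotate is the identity pipeline on a stub", {
  img <- make_phantom_image(7)$image
  for (kind in c("rotate90", "rotate180")) {
    sp <- perturbation_spec(kind)
    pert <- cherenkovseg:::apply_perturbation(img, sp)
    pred <- binarize(stub(pert))
    back <- cherenkovseg:::invert_perturbation_mask(pred, sp)
    expect_identical(back, binarize(stub(img)))
  }
})

test_that("frame cumulation has the documented limit behaviors", {
  tree <- straight_tree(48, width = 3, margin = 12)
  spec <- phantom_spec("source", image_size = 48, noise_sigma = 0)
  fs <- render_video(tree, spec, n_frames = 6, seed = 1)
  # noiseless static stack: any gate gives the same image
  full <- cumulate_frames(fs)
  for (k in c(1, 2, 3, 6)) {
    expect_equal(cumulate_frames(fs, gate = k), full, tolerance = 1e-12)
  }
  # k = 1 is the (rescaled) first frame
  f1 <- fs$frames[[1]]
  r <- range(f1)
  expect_equal(cumulate_frames(fs, gate = 1), (f1 - r[1]) / diff(r),
               tolerance = 1e-12)
  expect_error(cumulate_frames(fs, gate = 7), "exceeds")
  expect_error(cumulate_frames(fs, gate = 3, start = 5), "exceeds")
})

test_that("gate-to-seconds conversion matches the camera arithmetic", {
  expect_equal(gate_to_seconds(120), 6.1)
  expect_equal(gate_to_seconds(10), 0.5)
  expect_equal(gate_to_seconds(98), 5.0)
  expect_equal(gate_to_seconds(49), 2.5)
  expect_error(gate_to_seconds(0), "gate")
})

test_that("sub-cumulative sweeps match a brute-force window enumeration", {
  tree <- straight_tree(64, width = 4, margin = 16)
  spec <- phantom_spec("source", image_size = 64, background = 0.65,
                       contrast = 0.7, noise_sigma = 0.3,
                       motion_amplitude = 0)
  fs <- render_video(tree, spec, n_frames = 12, seed = 3)
  gates <- c(2, 3, 4, 12)
  sweep <- subcumulative_analysis(stub, fs, gates)
  expect_s3_class(sweep, "gate_sweep")
  # independent recomputation over all disjoint windows
  ref <- binarize(stub(cumulate_frames(fs)))
  for (r in seq_len(nrow(sweep))) {
    g <- sweep$gate_frames[r]
    starts <- seq(1, by = g, length.out = 12 %/% g)
    dices <- sapply(starts, function(s) {
      dice_score(binarize(stub(cumulate_frames(fs, g, s))), ref)
    })
    expect_equal(sweep$mean_dice[r], mean(dices), tolerance = 1e-12)
    expect_identical(sweep$n_windows[r], length(starts))
  }
  # the full gate is a self-comparison
  expect_equal(sweep$mean_dice[sweep$gate_frames == 12], 1)
  # noiseless static stack scores 1 at every gate
  quiet <- phantom_spec("source", image_size = 64, noise_sigma = 0)
  fsq <- render_video(tree, quiet, n_frames = 12, seed = 4)
  sq <- subcumulative_analysis(stub, fsq, gates)
  expect_true(all(sq$mean_dice == 1))
})

test_that("longer gates help a static stream and motion hurts", {
  tree <- straight_tree(96, width = 4, margin = 20)
  base <- list(image_size = 96, background = 0.65, contrast = 0.7,
               noise_sigma = 0.35)
  static <- do.call(phantom_spec, c(list("source"), base,
                                    list(motion_amplitude = 0)))
  moving <- do.call(phantom_spec, c(list("source"), base,
                                    list(motion_amplitude = 6,
                                         motion_period = 2.5)))
  fs_s <- render_video(tree, static, n_frames = 120, seed = 5)
  fs_m <- render_video(tree, moving, n_frames = 120, seed = 5)
  gates <- seq(10, 60, by = 10)
  sw_s <- subcumulative_analysis(stub, fs_s, gates)
  sw_m <- subcumulative_analysis(stub, fs_m, gates)
  rho <- cor(sw_s$gate_frames, sw_s$mean_dice, method = "spearman")
  expect_gt(rho, 0)
  expect_lt(sw_m$mean_dice[sw_m$gate_frames == 60],
            sw_s$mean_dice[sw_s$gate_frames == 60])
})

test_that("pairwise consistency reports every unordered pair", {
  set.seed(20)
  masks <- replicate(4, random_mask(12, 12), simplify = FALSE)
  tbl <- pairwise_consistency(masks)
  expect_identical(nrow(tbl), 6L)
  expect_equal(tbl$dice[1], dice_score(masks[[1]], masks[[2]]))
})
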