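# Stochastic training-time augmentation: horizontal flip, right-angle
# rotation, and additive Gaussian noise, applied on the fly each epoch.

#' Training-time augmentation policy
#'
#' The three transforms are independent events, so one patch can receive all
#' of them: with probability `flip_prob` the patch is mirrored horizontally;
#' with probability `rotate_prob` it is rotated by an angle drawn uniformly
#' from `angles`; with probability `noise_prob` Gaussian noise with a
#' standard deviation drawn uniformly in `(0, noise_max]` of the dynamic
#' range is added to the image only. Geometric transforms are exact pixel
#' permutations applied identically to image and mask; the mask is never
#' touched by noise.
#'
#' @param flip_prob Probability of a horizontal flip (paper policy: 0.33).
#' @param rotate_prob Probability of a right-angle rotation (0.33).
#' @param angles Allowed rotation angles, a subset of `c(90, 180, 270)`
#'   degrees.
#' @param noise_prob Probability of additive Gaussian noise (0.50).
#' @param noise_max Upper bound on the noise standard deviation as a fraction
#'   of the `[0, 1]` dynamic range (0.25).
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(flip_prob = 0.33, rotate_prob = 0.33,
                           angles = c(90, 180, 270), noise_prob = 0.5,
                           noise_max = 0.25) {
  probs <- c(flip_prob, rotate_prob, noise_prob)
  if (any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (!all(angles %in% c(90, 180, 270))) {
    abort("`angles` must be a subset of {90, 180, 270}")
  }
  if (noise_max < 0) abort("`noise_max` must be >= 0")
  structure(list(flip_prob = flip_prob, rotate_prob = rotate_prob,
                 angles = angles, noise_prob = noise_prob,
                 noise_max = noise_max),
            class = "augment_policy")
}

#' Augment one image/mask patch
#'
#' Draws the three independent transform events from the current RNG stream
#' (seed it with `set.seed()` or let the trainer's seeded loop drive it).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary matrix of the same shape.
#' @param policy An [augment_policy()].
#' @return A list with the transformed `image` and `mask` and an `applied`
#'   record (`flip`, `angle` in degrees with 0 = none, and the noise `sigma`
#'   or `NA`).
#' @export
augment_patch <- function(image, mask, policy = augment_policy()) {
  check_same_shape(image, mask, c("image", "mask"))
  applied <- list(flip = FALSE, angle = 0, sigma = NA_real_)
  if (runif(1) < policy$flip_prob) {
    image <- flip_horizontal(image)
    mask <- flip_horizontal(mask)
    applied$flip <- TRUE
  }
  if (runif(1) < policy$rotate_prob) {
    angle <- policy$angles[[sample.int(length(policy$angles), 1)]]
    k <- angle %/% 90
    image <- rot90k(image, k)
    mask <- rot90k(mask, k)
    applied$angle <- angle
  }
  if (runif(1) < policy$noise_prob && policy$noise_max > 0) {
    sigma <- runif(1, 0, policy$noise_max)
    image <- clip01(image + matrix(rnorm(length(image), 0, sigma),
                                   nrow(image), ncol(image)))
    applied$sigma <- sigma
  }
  list(image = image, mask = mask, applied = applied)
}
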