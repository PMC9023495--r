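#' Augmentation and preprocessing configuration
#'
#' Holds the parameters of the train-time four-step augmentation (random
#' scale, random aspect ratio, random crop, resize) and the test-time
#' two-step preprocessing (resize, center crop), plus the channel
#' normalization constants applied after float conversion.
#'
#' The scale range is an AREA fraction sampled log-uniformly; the aspect
#' ratio (width/height) is sampled log-uniformly and applied at constant
#' area; the crop samples its region size uniformly over [0.5, 1] of each
#' current dimension and its location uniformly within the image.
#'
#' @param scale_range length-2 numeric, area-fraction interval, default
#'   `c(0.08, 1)`.
#' @param ratio_range length-2 numeric, width/height interval, default
#'   `c(3/4, 4/3)`.
#' @param train_out square output side for training, default 224.
#' @param test_resize side the test image is first resized to, default 256.
#' @param test_crop centered square cropped afterwards, default 224.
#' @param crop_frac_range region-size fraction interval for the random crop.
#' @param mean,sd per-channel normalization constants (length 1 or 3);
#'   normalization is `(x - mean) / sd` after conversion to [0,1] floats.
#' @return an object of class `aug_config`.
#' @export
aug_config <- function(scale_range = c(0.08, 1), ratio_range = c(3/4, 4/3),
                       train_out = 224, test_resize = 256, test_crop = 224,
                       crop_frac_range = c(0.5, 1),
                       mean = c(0, 0, 0), sd = c(1, 1, 1)) {
  cn_assert(length(scale_range) == 2 && scale_range[1] > 0 &&
              scale_range[1] <= scale_range[2] && scale_range[2] <= 1,
            "config", "scale_range must satisfy 0 < lo <= hi <= 1")
  cn_assert(length(ratio_range) == 2 && ratio_range[1] > 0 &&
              ratio_range[1] <= ratio_range[2],
            "config", "ratio_range must satisfy 0 < lo <= hi")
  cn_assert(is_count(train_out) && is_count(test_resize) && is_count(test_crop),
            "config", "output sizes must be positive integers")
  cn_assert(test_crop <= test_resize, "config", "test_crop must be <= test_resize")
  cn_assert(length(crop_frac_range) == 2 && crop_frac_range[1] > 0 &&
              crop_frac_range[1] <= crop_frac_range[2] && crop_frac_range[2] <= 1,
            "config", "crop_frac_range must lie in (0,1]")
  if (length(mean) == 1) mean <- rep(mean, 3)
  if (length(sd) == 1) sd <- rep(sd, 3)
  cn_assert(all(sd > 0), "config", "sd must be positive")
  structure(list(scale_range = scale_range, ratio_range = ratio_range,
                 train_out = as.integer(train_out),
                 test_resize = as.integer(test_resize),
                 test_crop = as.integer(test_crop),
                 crop_frac_range = crop_frac_range,
                 mean = mean, sd = sd),
            class = "aug_config")
}

check_image <- function(image) {
  d <- dim(image)
  cn_assert(length(d) == 3 && d[3] == 3, "input",
            "image must be an (H, W, 3) array")
  cn_assert(d[1] >= 2 && d[2] >= 2, "input", "image must be at least 2x2")
  invisible(d)
}

resize_image <- function(image, out_h, out_w) {
  cpp_resize(image, as.integer(out_h), as.integer(out_w))
}

# Draw the raw random numbers of augmentation steps 1-3. Exposed internally
# so empirical tests of the sampler do not pay for image resampling.
sample_aug_params <- function(cfg) {
  list(
    area = exp(runif(1, log(cfg$scale_range[1]), log(cfg$scale_range[2]))),
    ratio = exp(runif(1, log(cfg$ratio_range[1]), log(cfg$ratio_range[2]))),
    crop_frac = runif(2, cfg$crop_frac_range[1], cfg$crop_frac_range[2]),
    crop_loc = runif(2)
  )
}

target_side <- function(x) max(8L, as.integer(round_half_up(x)))

# Integer geometry of augmentation steps 1-3 for an (h, w) input given the
# sampled parameters: sizes after scaling and ratio change, then the crop
# rectangle. Pure arithmetic, exposed for property tests.
aug_geometry <- function(h, w, pr) {
  s <- sqrt(pr$area)
  h1 <- target_side(h * s); w1 <- target_side(w * s)
  area <- h1 * w1
  w2 <- target_side(sqrt(area * pr$ratio))
  h2 <- target_side(sqrt(area / pr$ratio))
  ch <- max(1L, as.integer(round_half_up(pr$crop_frac[1] * h2)))
  cw <- max(1L, as.integer(round_half_up(pr$crop_frac[2] * w2)))
  top <- 1L + as.integer(floor(pr$crop_loc[1] * (h2 - ch + 1)))
  left <- 1L + as.integer(floor(pr$crop_loc[2] * (w2 - cw + 1)))
  list(h1 = h1, w1 = w1, h2 = h2, w2 = w2,
       ch = ch, cw = cw, top = top, left = left)
}

normalize_chw <- function(img_hw3, mean, sd) {
  # (H, W, 3) in [0,1] -> normalized (3, H, W)
  out <- aperm(img_hw3, c(3, 1, 2))
  (out - mean) / sd
}

#' Train-time augmentation
#'
#' Applies, in order: (1) random area scaling at fixed aspect ratio;
#' (2) random aspect ratio at fixed area; (3) random crop with size and
#' location sampled within the image; (4) resize to `train_out`; then
#' converts to float and normalizes channel-wise. Randomness is drawn from
#' R's global RNG, so a `set.seed()` before the call makes it reproducible.
#'
#' @param image an (H, W, 3) array with values in [0,1].
#' @param cfg an [aug_config()].
#' @return normalized float array of dim (3, train_out, train_out).
#' @export
train_transform <- function(image, cfg) {
  d <- check_image(image)
  pr <- sample_aug_params(cfg)
  g <- aug_geometry(d[1], d[2], pr)
  # (1) random scaling: area fraction, aspect ratio kept
  img <- resize_image(image, g$h1, g$w1)
  # (2) random ratio: width/height changed, area kept
  img <- resize_image(img, g$h2, g$w2)
  # (3) random crop: region size and location within the image
  img <- img[g$top:(g$top + g$ch - 1L), g$left:(g$left + g$cw - 1L), ,
             drop = FALSE]
  # (4) resize to the network input side
  img <- resize_image(img, cfg$train_out, cfg$train_out)
  normalize_chw(img, cfg$mean, cfg$sd)
}

#' Test-time preprocessing
#'
#' Deterministic: resize to `test_resize` x `test_resize`, crop the centered
#' `test_crop` square, float-convert and normalize.
#'
#' @inheritParams train_transform
#' @return normalized float array of dim (3, test_crop, test_crop).
#' @export
test_transform <- function(image, cfg) {
  check_image(image)
  img <- resize_image(image, cfg$test_resize, cfg$test_resize)
  off <- (cfg$test_resize - cfg$test_crop) %/% 2L
  img <- img[(off + 1L):(off + cfg$test_crop),
             (off + 1L):(off + cfg$test_crop), , drop = FALSE]
  normalize_chw(img, cfg$mean, cfg$sd)
}

#' Per-channel mean and sd of a dataset
#'
#' Computed once from the training split and stored in the augmentation
#' config, in place of fixed published constants.
#'
#' @param ds a `labeled_dataset`.
#' @return list with numeric length-3 `mean` and `sd`.
#' @export
compute_norm_stats <- function(ds) {
  px <- vapply(ds$images, function(im) {
    c(colMeans(matrix(im, ncol = 3)), colMeans(matrix(im, ncol = 3)^2))
  }, numeric(6))
  m <- rowMeans(px)[1:3]
  v <- rowMeans(px)[4:6] - m^2
  list(mean = m, sd = sqrt(pmax(v, 1e-8)))
}

# Assemble a list of (H, W, 3) images into a (3, S, S, N) batch tensor.
assemble_batch <- function(tensors) {
  d <- dim(tensors[[1]])
  out <- array(0, c(d, length(tensors)))
  for (i in seq_along(tensors)) out[, , , i] <- tensors[[i]]
  out
}
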