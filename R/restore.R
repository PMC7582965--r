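#' Restoration training configuration
#'
#' Protocol parameters for the paired low/high-SNR restorer. Paper-scale
#' values (128 px patches, 35,200 patches, 100 epochs x 30 steps) are
#' expressible; the defaults are the desk-scale regime the synthetic
#' benchmark runs at (64 px patches, a few thousand patch pairs), which the
#' methods vignette documents.
#'
#' @param patch_px patch side; one of 64, 128, 256 (the patch-size study's
#'   admissible sizes).
#' @param input_accums input accumulation counts.
#' @param gt_accum ground-truth accumulation count.
#' @param val_fraction validation fraction in (0, 1).
#' @param epochs,steps_per_epoch training schedule.
#' @param batch_size patches per gradient step.
#' @param learning_rate Adam step size.
#' @param lr_decay per-epoch multiplicative learning-rate decay.
#' @param base_features conv channels at full resolution.
#' @param residual add the input back to the network output (residual
#'   head) instead of predicting the restored image directly.
#' @param augment random flips/transposition of training patches.
#' @param input_sigmas Gaussian blur scales (px) appended to the input as
#'   extra channels: pre-aggregated photon counts at several scales, which
#'   helps at ~1 detected photon per pixel. Empty vector disables.
#' @param p_low,p_high normalization percentiles.
#' @param seed training seed.
#' @return object of class `restoration_config`.
#' @export
restoration_config <- function(patch_px = 64L, input_accums = c(7L, 15L),
                               gt_accum = 70L, val_fraction = 0.10,
                               epochs = 40L, steps_per_epoch = 30L,
                               batch_size = 8L, learning_rate = 1e-3,
                               lr_decay = 0.97, base_features = 8L,
                               residual = FALSE, augment = TRUE,
                               input_sigmas = c(1, 2, 4),
                               p_low = 0.1, p_high = 99.9, seed = 1L) {
  check(patch_px %in% c(64L, 128L, 256L), "patch_px must be 64, 128 or 256")
  check(val_fraction > 0 && val_fraction < 1, "val_fraction must be in (0, 1)")
  check(epochs >= 1 && steps_per_epoch >= 1 && batch_size >= 1,
        "schedule values must be >= 1")
  structure(as.list(environment()), class = "restoration_config")
}

#' Number of patch positions on a regular grid
#'
#' Bookkeeping helper: how many `patch_px` patches a stride-`stride` grid
#' cuts from an `image_px` image per axis, squared. 1024 px images with
#' 128 px patches at stride 128 give 64 patches each, so 550 image pairs
#' give 35,200.
#'
#' @param image_px image side length (px).
#' @param patch_px patch side length (px).
#' @param stride grid stride (px), default `patch_px`.
#' @return integer patch count per image.
#' @export
#' @examples
#' patch_grid_count(1024, 128)       # 64
#' 550 * patch_grid_count(1024, 128) # 35200
patch_grid_count <- function(image_px, patch_px, stride = patch_px) {
  check(image_px >= patch_px, "image smaller than patch")
  n <- floor((image_px - patch_px) / stride) + 1
  as.integer(n * n)
}

#' Extract registered patch pairs
#'
#' Cuts input and ground-truth patches at identical grid coordinates from
#' each registered image pair. Order is deterministic; with `max_patches`
#' a seeded subsample is taken.
#'
#' @param pairs list of pairs as from [make_training_pairs()] (fields
#'   `input`, `gt`), or any list of two-matrix lists.
#' @param patch_px patch side (px).
#' @param stride grid stride (default `patch_px`, non-overlapping).
#' @param max_patches optional cap; a seeded random subset is kept.
#' @param seed seed for the subsample.
#' @return list of `list(input, gt)` patch pairs.
#' @export
extract_patches <- function(pairs, patch_px = 64L, stride = patch_px,
                            max_patches = NULL, seed = 1L) {
  out <- list()
  for (p in pairs) {
    d <- dim(p$input)
    check(all(d == dim(p$gt)), "pair images must share shape")
    check(all(d >= patch_px), "image smaller than patch")
    r0 <- seq(1L, d[1] - patch_px + 1L, by = stride)
    c0 <- seq(1L, d[2] - patch_px + 1L, by = stride)
    for (r in r0) for (cc in c0) {
      ri <- r + seq_len(patch_px) - 1L
      ci <- cc + seq_len(patch_px) - 1L
      out[[length(out) + 1L]] <- list(input = p$input[ri, ci],
                                      gt = p$gt[ri, ci])
    }
  }
  if (!is.null(max_patches) && length(out) > max_patches) {
    keep <- with_seed(seed, sample.int(length(out), max_patches))
    out <- out[sort(keep)]
  }
  out
}

#' Random train/validation split
#'
#' Seeded random partition: `floor(val_fraction * N)` elements go to the
#' validation set, the rest to training; the sets are disjoint and
#' exhaustive.
#'
#' @param patches list (or vector) to split.
#' @param val_fraction validation fraction.
#' @param seed integer seed.
#' @return list with `train` and `val`.
#' @export
#' @examples
#' s <- split_train_val(1:35200, 0.10, seed = 1)
#' length(s$val)    # 3520
#' length(s$train)  # 31680
split_train_val <- function(patches, val_fraction = 0.10, seed = 1L) {
  n <- length(patches)
  check(n >= 2, "need at least 2 items to split")
  n_val <- floor(val_fraction * n)
  idx <- with_seed(seed, sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  list(train = patches[setdiff(seq_len(n), val_idx)],
       val = patches[val_idx])
}

#' Percentile normalization
#'
#' Affine rescaling used throughout the restoration pipeline:
#' `(x - q_low) / (q_high - q_low)` with the percentiles taken from the
#' image itself. A constant image cannot be scaled meaningfully: a warning
#' is raised and the identity transform returned.
#'
#' @param image numeric matrix.
#' @param p_low,p_high percentiles (0-100).
#' @return list: `image` (normalized), `offset`, `scale` such that
#'   `image * scale + offset` recovers the input.
#' @export
normalize_percentile <- function(image, p_low = 0.1, p_high = 99.9) {
  q <- stats::quantile(image, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: returning identity normalization")
    return(list(image = image, offset = 0, scale = 1))
  }
  list(image = (image - q[1]) / (q[2] - q[1]), offset = q[1], scale = q[2] - q[1])
}

#' Invert a percentile normalization
#'
#' @param norm a [normalize_percentile()] result (optionally with the
#'   `image` replaced, e.g. by a restored version).
#' @param image optional matrix to denormalize instead of `norm$image`.
#' @return matrix on the original intensity scale.
#' @export
denormalize <- function(norm, image = norm$image) {
  image * norm$scale + norm$offset
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM of two images with the reference parameterisation: local
#' statistics under an 11-tap Gaussian window (sigma 1.5, truncated at 3.5
#' sigma), stabilisers `K1 = 0.01`, `K2 = 0.03`, population covariance, and
#' the mean taken over the interior (a filter-radius strip at the border is
#' ignored). Agrees with scikit-image's `structural_similarity` with
#' Gaussian weights to machine precision.
#'
#' @param x,y numeric matrices of identical shape (at least 11 x 11).
#' @param data_range value range of the data (for normalized images, 1).
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stabiliser constants.
#' @return scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 1, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  check(all(dim(x) == dim(y)), "images must share shape")
  r <- as.integer(3.5 * sigma + 0.5)
  check(all(dim(x) > 2L * r), "image too small for the SSIM window")
  k <- exp(-0.5 * (seq(-r, r))^2 / sigma^2)
  k <- k / sum(k)
  ux <- sep_conv_valid(x, k); uy <- sep_conv_valid(y, k)
  vx <- sep_conv_valid(x * x, k) - ux^2
  vy <- sep_conv_valid(y * y, k) - uy^2
  cxy <- sep_conv_valid(x * y, k) - ux * uy
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mean(((2 * ux * uy + C1) * (2 * cxy + C2)) /
         ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
}

#' Evaluate restoration quality against ground truth
#'
#' Computes MSE, MAE and SSIM for the raw inputs and for the restored images
#' against the ground truth, on percentile-normalized intensities (each
#' image normalized by its own 0.1/99.9 percentiles, which puts the
#' normalized data range at 1 for SSIM). Reports mean and standard
#' deviation per arm.
#'
#' @param restored,inputs,gts lists of registered matrices (same length and
#'   shapes). `restored` may be `NULL` to evaluate the inputs only.
#' @param p_low,p_high normalization percentiles.
#' @return data.frame with one row per arm and columns
#'   `mse_mean, mse_sd, mae_mean, mae_sd, ssim_mean, ssim_sd`; the
#'   per-image values are attached as attribute `"per_image"` (a data.frame
#'   with `arm`, `image`, `mse`, `mae`, `ssim`), enabling paired tests
#'   between arms.
#' @export
evaluate_restoration <- function(restored, inputs, gts,
                                 p_low = 0.1, p_high = 99.9) {
  check(length(inputs) == length(gts), "inputs/gts length mismatch")
  norm <- function(m) normalize_percentile(m, p_low, p_high)$image
  gt_n <- lapply(gts, norm)
  one_arm <- function(imgs) {
    t(vapply(seq_along(imgs), function(i) {
      a <- norm(imgs[[i]]); b <- gt_n[[i]]
      c(mse = mean((a - b)^2), mae = mean(abs(a - b)),
        ssim = ssim(a, b, data_range = 1))
    }, numeric(3)))
  }
  arms <- list(input = one_arm(inputs))
  if (!is.null(restored)) {
    check(length(restored) == length(gts), "restored/gts length mismatch")
    arms$restored <- one_arm(restored)
  }
  rows <- lapply(arms, function(m)
    c(mse_mean = mean(m[, 1]), mse_sd = stats::sd(m[, 1]),
      mae_mean = mean(m[, 2]), mae_sd = stats::sd(m[, 2]),
      ssim_mean = mean(m[, 3]), ssim_sd = stats::sd(m[, 3])))
  out <- as.data.frame(do.call(rbind, rows))
  out$arm <- names(rows)
  out <- out[, c("arm", setdiff(names(out), "arm"))]
  per <- do.call(rbind, lapply(names(arms), function(nm)
    data.frame(arm = nm, image = seq_len(nrow(arms[[nm]])),
               mse = arms[[nm]][, 1], mae = arms[[nm]][, 2],
               ssim = arms[[nm]][, 3], row.names = NULL)))
  attr(out, "per_image") <- per
  out
}
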