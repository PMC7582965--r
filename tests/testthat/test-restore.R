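test_that("patch bookkeeping reproduces the reference training-set bookkeeping", {
  # 1024-px images cut into 128-px patches: 8 x 8 = 64 per image
  expect_equal(patch_grid_count(1024, 128), 64L)
  # 550 image pairs pooled -> 35,200 patches
  expect_equal(550 * patch_grid_count(1024, 128), 35200)
  expect_equal(patch_grid_count(128, 128), 1L)
  expect_error(patch_grid_count(100, 128), "smaller")
})

test_that("patch extraction cuts registered pairs deterministically", {
  set.seed(10)
  img <- matrix(stats::rnorm(256 * 256), 256, 256)
  pair <- list(list(input = img, gt = 2 * img))
  ps <- extract_patches(pair, patch_px = 64)
  expect_length(ps, 16)                     # 4 x 4 grid
  expect_equal(dim(ps[[1]]$input), c(64, 64))
  # identical coordinates for input and ground truth
  expect_equal(ps[[7]]$gt, 2 * ps[[7]]$input)
  expect_equal(ps[[1]]$input, img[1:64, 1:64])
  # patch == image size: one identity crop
  one <- extract_patches(pair, patch_px = 256)
  expect_length(one, 1)
  expect_equal(one[[1]]$input, img)
  # seeded subsampling is reproducible
  s1 <- extract_patches(pair, 64, max_patches = 5, seed = 2)
  s2 <- extract_patches(pair, 64, max_patches = 5, seed = 2)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  expect_error(extract_patches(pair, patch_px = 512), "smaller")
})

test_that("train/validation split is a seeded disjoint partition", {
  s <- split_train_val(seq_len(35200), 0.10, seed = 1)
  expect_length(s$val, 3520)
  expect_length(s$train, 31680)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), seq_len(35200))
  expect_length(split_train_val(1:10, 0.10, seed = 1)$val, 1)
  expect_length(split_train_val(1:101, 0.10, seed = 1)$val, 10)
  expect_identical(split_train_val(1:100, seed = 3),
                   split_train_val(1:100, seed = 3))
  expect_error(split_train_val(list(1), 0.1), "at least 2")
})

test_that("percentile normalization is invertible and flags constants", {
  set.seed(11)
  img <- matrix(stats::rexp(1e4), 100, 100)
  n <- normalize_percentile(img)
  expect_equal(denormalize(n), img, tolerance = 1e-6)
  # the two percentiles map to 0 and 1
  q <- stats::quantile(img, c(0.001, 0.999), names = FALSE)
  expect_equal((q - n$offset) / n$scale, c(0, 1), tolerance = 1e-12)
  expect_warning(nc <- normalize_percentile(matrix(5, 4, 4)), "constant")
  expect_equal(nc$image, matrix(5, 4, 4))
  expect_equal(nc$scale, 1)
})

test_that("SSIM matches the reference implementation and its properties", {
  x <- as.matrix(read.table(test_path("fixtures", "ssim_x.txt")))
  y <- as.matrix(read.table(test_path("fixtures", "ssim_y.txt")))
  dimnames(x) <- dimnames(y) <- NULL
  # frozen value from scikit-image structural_similarity (Wang et al.
  # parameterisation: gaussian_weights, sigma 1.5, population covariance)
  expect_equal(ssim(x, y, data_range = 1), 0.945120246980, tolerance = 1e-10)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))  # symmetry
  # SSIM decreases as independent noise grows
  set.seed(12)
  base <- gblur_mat(matrix(stats::runif(96 * 96), 96, 96), 2)
  vals <- vapply(c(0.05, 0.15, 0.4), function(s)
    ssim(base, base + matrix(stats::rnorm(96 * 96, 0, s), 96, 96),
         data_range = diff(range(base))), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(ssim(x, y[1:10, 1:10]), "shape")
})

test_that("evaluation metrics are exact on identical and shifted images", {
  set.seed(13)
  imgs <- replicate(3, matrix(stats::rexp(64 * 64), 64, 64), simplify = FALSE)
  m <- evaluate_restoration(imgs, imgs, imgs)
  expect_equal(m$mse_mean, c(0, 0))
  expect_equal(m$mae_mean, c(0, 0))
  expect_equal(m$ssim_mean, c(1, 1))
  # input-only evaluation
  m2 <- evaluate_restoration(NULL, imgs, imgs)
  expect_equal(nrow(m2), 1)
  # normalization makes the metrics invariant to affine intensity changes
  shifted <- lapply(imgs, function(i) 3 * i + 7)
  m3 <- evaluate_restoration(shifted, imgs, imgs)
  expect_equal(m3$mse_mean[2], 0, tolerance = 1e-12)
  expect_equal(m3$ssim_mean[2], 1, tolerance = 1e-12)
})

test_that("the restorer can learn the identity task", {
  set.seed(14)
  patches <- lapply(1:60, function(i) {
    p <- gblur_mat(matrix(stats::runif(32 * 32), 32, 32), 1.5)
    list(input = p, gt = p)
  })
  s <- split_train_val(patches, 0.2, seed = 1)
  cfg <- restoration_config(epochs = 12, steps_per_epoch = 20,
                            batch_size = 4, base_features = 8,
                            learning_rate = 5e-3, seed = 5)
  m <- train_restorer(s$train, s$val, cfg)
  # identity pairs: validation MSE collapses well below the signal variance
  sig_var <- stats::var(as.vector(patches[[1]]$gt))
  expect_lt(m$history$val_mse[nrow(m$history)], 0.2 * sig_var)
  expect_lt(m$history$val_mse[nrow(m$history)], m$history$val_mse[1])
  expect_s3_class(m, "restorer")
  expect_equal(nrow(m$history), 12)
})

test_that("training is seed-deterministic and divergence is reported", {
  set.seed(15)
  patches <- lapply(1:20, function(i) {
    p <- matrix(stats::runif(16 * 16), 16, 16)
    list(input = p, gt = p)
  })
  s <- split_train_val(patches, 0.2, seed = 1)
  cfg <- restoration_config(epochs = 2, steps_per_epoch = 5, batch_size = 2,
                            base_features = 4, seed = 9)
  m1 <- train_restorer(s$train, s$val, cfg)
  m2 <- train_restorer(s$train, s$val, cfg)
  expect_identical(m1$params, m2$params)
  # non-finite data drives the validation loss non-finite: explicit failure
  cfg_plain <- restoration_config(epochs = 2, steps_per_epoch = 5,
                                  batch_size = 2, base_features = 4,
                                  input_sigmas = numeric(0), seed = 9)
  bad <- patches
  for (i in seq_along(bad)) bad[[i]]$gt[1, 1] <- NaN
  expect_error(train_restorer(bad, bad, cfg_plain), "diverged")
})

test_that("tiled inference equals whole-image inference and keeps shape", {
  set.seed(16)
  cfg <- restoration_config(epochs = 1, steps_per_epoch = 2, batch_size = 2,
                            base_features = 4, seed = 2)
  patches <- lapply(1:8, function(i) {
    p <- matrix(stats::runif(64 * 64), 64, 64)
    list(input = p, gt = p)
  })
  s <- split_train_val(patches, 0.25, seed = 1)
  m <- train_restorer(s$train, s$val, cfg)
  img <- matrix(stats::runif(200 * 232), 200, 232)
  full <- restore_image(m, img, tile_px = 256, normalize = FALSE)
  tiled <- restore_image(m, img, tile_px = 128, normalize = FALSE)
  expect_equal(dim(tiled), dim(img))
  expect_lt(sqrt(mean((tiled - full)^2)), 1e-3)
  # odd sizes are handled
  odd <- restore_image(m, img[1:199, 1:231], tile_px = 256, normalize = FALSE)
  expect_equal(dim(odd), c(199, 231))
  # restoring a zero image yields a constant interior (borders feel the
  # zero padding, which for a zero image equals the interior anyway only
  # beyond the receptive field)
  z <- restore_image(m, matrix(0, 64, 64), normalize = FALSE)
  expect_lt(stats::sd(z[17:48, 17:48]), 1e-9)
  expect_identical(predict(m, img, tile_px = 256, normalize = FALSE), full)
})

test_that("training on a smooth field beats the best Gaussian blur", {
  set.seed(17)
  mkfield <- function() {
    b <- matrix(stats::runif(48 * 48), 48, 48) > 0.97
    f <- gblur_mat(b * 1.0, 1.5)
    f / max(f, 0.01)
  }
  pairs <- lapply(1:100, function(i) {
    f <- mkfield()
    list(input = f + matrix(stats::rnorm(48 * 48, 0, 0.15), 48, 48), gt = f)
  })
  s <- split_train_val(pairs, 0.2, seed = 1)
  cfg <- restoration_config(epochs = 15, steps_per_epoch = 20, batch_size = 4,
                            base_features = 6, seed = 3)
  m <- train_restorer(s$train, s$val, cfg)
  mses <- vapply(1:5, function(i) {
    f <- mkfield()
    ti <- f + matrix(stats::rnorm(48 * 48, 0, 0.15), 48, 48)
    blur_best <- min(vapply(seq(0.5, 4, by = 0.25), function(sg)
      mean((gblur_mat(ti, sg) - f)^2), numeric(1)))
    c(net = mean((restore_image(m, ti, normalize = FALSE) - f)^2),
      blur = blur_best)
  }, numeric(2))
  expect_lt(mean(mses["net", ]), mean(mses["blur", ]))
})
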