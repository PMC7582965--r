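#' Normalize image pairs and cut training patches
#'
#' Preprocessing bridge between the photon simulator and the trainer: every
#' input and ground-truth image is percentile-normalized independently, then
#' registered patch pairs are extracted on a stride grid and split into
#' train/validation sets.
#'
#' With `val_by = "image"` (the default) whole images are assigned to the
#' validation set before patches are cut, so validation patches share no
#' pixels with training patches even on an overlapping patch grid; with
#' `val_by = "patch"` the split randomizes over pooled patches, the
#' protocol's reference bookkeeping.
#'
#' @param pairs list of pairs from [make_training_pairs()].
#' @param config a [restoration_config()].
#' @param stride patch grid stride (px); defaults to half a patch
#'   (overlapping grid).
#' @param max_patches optional cap on the number of training patch pairs
#'   (seeded subsample).
#' @param val_by `"image"` or `"patch"` (see above).
#' @return list with `train` and `val` patch-pair lists.
#' @export
prepare_restoration_data <- function(pairs, config = restoration_config(),
                                     stride = config$patch_px / 2,
                                     max_patches = NULL,
                                     val_by = c("image", "patch")) {
  val_by <- match.arg(val_by)
  norm_pairs <- lapply(pairs, function(p) list(
    input = normalize_percentile(p$input, config$p_low, config$p_high)$image,
    gt = normalize_percentile(p$gt, config$p_low, config$p_high)$image))
  if (val_by == "patch") {
    patches <- extract_patches(norm_pairs, config$patch_px, stride = stride,
                               max_patches = max_patches,
                               seed = derive_seed(config$seed, "pairs"))
    return(split_train_val(patches, config$val_fraction,
                           seed = derive_seed(config$seed, "train")))
  }
  # group sibling pairs that image the same section (e.g. the 7- and
  # 15-accumulation inputs sharing one ground truth), so no section leaks
  # across the split
  key <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (!is.null(p$phantom_seed) && !is.null(p$depth_um)) {
      paste(p$phantom_seed, p$depth_um)
    } else as.character(i)
  }, character(1))
  groups <- unique(key)
  sp <- split_train_val(groups, config$val_fraction,
                        seed = derive_seed(config$seed, "train"))
  list(
    train = extract_patches(norm_pairs[key %in% sp$train], config$patch_px,
                            stride = stride, max_patches = max_patches,
                            seed = derive_seed(config$seed, "pairs")),
    val = extract_patches(norm_pairs[key %in% sp$val], config$patch_px,
                          stride = config$patch_px)
  )
}

#' Synthetic paired-restoration benchmark
#'
#' The package's reference experiment, mirroring the paired acquisition
#' protocol at desk scale: simulate epidermal sections of procedural skin
#' phantoms under the calibrated photon budget, pair 7- and 15-accumulation
#' inputs with 70-accumulation ground truth, train the small restorer on
#' ~2,000 64-px patch pairs pooled over both input levels, and evaluate
#' MSE/MAE/SSIM of raw 15-accumulation inputs and restored images against
#' ground truth on held-out sections never seen in training.
#'
#' Problem sizes (12 phantoms x 4 depths = 48 sections of 256 x 256 px at
#' 0.9 um pitch, 20 held out) are the package's desk-scale study conditions;
#' the methods vignette discusses the choice.
#'
#' @param seed integer seed controlling phantoms, photon noise, patch
#'   subsampling, split and training.
#' @param n_phantoms number of phantoms.
#' @param depths section depths (um) per phantom.
#' @param n_holdout number of held-out evaluation sections.
#' @param shape,pitch phantom grid (see [generate_phantom()]).
#' @param config a [restoration_config()]; its `seed` is overridden by
#'   `seed`.
#' @param eval_accum input accumulation level of the evaluation arm.
#' @param max_patches cap on training patch pairs.
#' @param attenuation_length depth attenuation length (um).
#' @param verbose print progress.
#' @return list: `metrics` (data.frame from [evaluate_restoration()]),
#'   `input_ssim`, `restored_ssim` (means over held-out sections), `model`,
#'   `n_eval`, `n_train_patches`.
#' @export
restoration_benchmark <- function(seed = 1L, n_phantoms = 12L,
                                  depths = c(15, 22.5, 30, 37.5),
                                  n_holdout = 20L,
                                  shape = c(24, 256, 256),
                                  pitch = c(2.5, 0.9, 0.9),
                                  config = restoration_config(
                                    epochs = 30L, steps_per_epoch = 30L,
                                    batch_size = 8L, base_features = 8L,
                                    learning_rate = 2e-3),
                                  eval_accum = 15L, max_patches = 2000L,
                                  attenuation_length = 100,
                                  verbose = FALSE) {
  config$seed <- derive_seed(seed, "train")
  sections <- list()
  for (i in seq_len(n_phantoms)) {
    if (verbose) message("phantom ", i, "/", n_phantoms)
    ph <- generate_phantom(seed = derive_seed(seed, "phantom", i),
                           shape = shape, pitch = pitch)
    prs <- make_training_pairs(ph, depths, input_accums = c(7L, 15L),
                               gt_accum = 70L,
                               seed = derive_seed(seed, "pairs", i),
                               attenuation_length = attenuation_length)
    # group the two accumulation levels of one section together
    for (j in seq(1, length(prs), by = 2)) {
      sections[[length(sections) + 1L]] <- prs[j:(j + 1)]
    }
    rm(ph)
  }
  n_sec <- length(sections)
  check(n_sec > n_holdout, "not enough sections for the requested holdout")
  hold <- with_seed(derive_seed(seed, "eval"),
                    sort(sample.int(n_sec, n_holdout)))
  train_pairs <- unlist(sections[setdiff(seq_len(n_sec), hold)],
                        recursive = FALSE)
  sets <- prepare_restoration_data(train_pairs, config,
                                   max_patches = max_patches)
  if (verbose) message(length(sets$train), " training / ",
                       length(sets$val), " validation patches")
  model <- train_restorer(sets$train, sets$val, config)
  eval_inputs <- list(); eval_gts <- list()
  for (k in hold) {
    grp <- sections[[k]]
    pick <- which(vapply(grp, `[[`, numeric(1), "input_accum") == eval_accum)[1]
    eval_inputs[[length(eval_inputs) + 1L]] <- grp[[pick]]$input
    eval_gts[[length(eval_gts) + 1L]] <- grp[[pick]]$gt
  }
  restored <- lapply(eval_inputs, function(img) restore_image(model, img))
  metrics <- evaluate_restoration(restored, eval_inputs, eval_gts,
                                  config$p_low, config$p_high)
  list(metrics = metrics,
       input_ssim = metrics$ssim_mean[metrics$arm == "input"],
       restored_ssim = metrics$ssim_mean[metrics$arm == "restored"],
       model = model, n_eval = length(eval_inputs),
       n_train_patches = length(sets$train))
}

#' Melanin-discrimination benchmark on a default phantom
#'
#' Simulates a gated z-stack of one default phantom at the standard
#' 15-accumulation budget, applies the 3D virtual melanin stain, and scores
#' the corrected-red channel against the phantom's ground-truth melanin
#' voxels: ROC AUC of the continuous score and Dice of the thresholded
#' stain, with the truth mask taken at the nearest voxel slice per imaged
#' depth.
#'
#' The imaged planes sit at voxel centers through the melanin-bearing
#' viable epidermis (12.5 to 42.5 um every 5 um by default), so each
#' optical section is dominated by exactly the voxel slice whose truth mask
#' it is scored against.
#'
#' @param seed integer seed.
#' @param n_accum accumulated frames per section.
#' @param depth_range_um,step_um z-stack geometry; the planned planes are
#'   shifted by half a step to voxel centers.
#' @param shape,pitch phantom grid.
#' @return list: `auc`, `dice`, `threshold`, `fraction_by_depth`,
#'   `stain` (the [melanin_stain_3d()] result), `truth` (stacked mask).
#' @export
melanin_benchmark <- function(seed = 1L, n_accum = 15L, depth_range_um = 35,
                              step_um = 5, shape = c(40, 256, 256),
                              pitch = c(5, 0.9, 0.9)) {
  ph <- generate_phantom(seed = derive_seed(seed, "phantom"), shape = shape,
                         pitch = pitch)
  zp <- plan_zstack(depth_range_um, step_um)
  depths <- zp$depths_um + 10 - step_um / 2  # voxel centers below the SC
  zc <- (seq_len(shape[1]) - 0.5) * pitch[1]
  stack <- list()
  truth <- array(FALSE, dim = c(zp$n_planes, shape[2], shape[3]))
  score <- array(0, dim = c(zp$n_planes, shape[2], shape[3]))
  for (k in seq_len(zp$n_planes)) {
    d <- depths[k]
    ci <- simulate_channel_image(ph, d, n_accum = n_accum,
                                 seed = derive_seed(seed, "zstack", k),
                                 shg = FALSE)
    stack[[k]] <- ci
    truth[k, , ] <- ph$melanin_truth[which.min(abs(zc - d)), , ]
    score[k, , ] <- ci$corrected_red
  }
  stain <- melanin_stain_3d(stack, depths)
  sc <- melanin_recovery_score(stain$mask, truth, score = score)
  list(auc = sc$auc, dice = sc$dice, threshold = stain$threshold,
       fraction_by_depth = stain$fraction_by_depth, stain = stain,
       truth = truth)
}
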