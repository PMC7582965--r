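#' Integrate a time-binned frame into red/green lifetime channels
#'
#' Sums photon counts over the arrival-time bins belonging to each gate
#' window (center-snapping rule, see [window_to_bins()]). With the default
#' configuration the two windows share bin 2, reproducing the deliberate
#' integration-window overlap of the two detection channels.
#'
#' @param frame a [simulate_frame()] result.
#' @param windows a [gate_windows()].
#' @return list with integer matrices `red` and `green`.
#' @export
integrate_channels <- function(frame, windows = gate_windows()) {
  stopifnot(inherits(frame, "time_binned_frame"), inherits(windows, "gate_windows"))
  cfg <- frame$pulse_cfg
  rb <- window_to_bins(windows$red, cfg)
  gb <- window_to_bins(windows$green, cfg)
  sum_bins <- function(idx) {
    if (length(idx) == 1) frame$counts[, , idx]
    else rowSums(frame$counts[, , idx, drop = FALSE], dims = 2)
  }
  list(red = sum_bins(rb), green = sum_bins(gb))
}

#' Corrected-red melanin channel
#'
#' Subtracts the long-lifetime (green-window) counts from the short-lifetime
#' (red-window) counts and clips negatives to zero. Because the two windows
#' overlap and the red window is short, long-lifetime fluorophores
#' contribute more green than red and are removed; the surviving positive
#' values are dominated by the short-lifetime melanin signal. Clipping is
#' applied after channel integration, per image, not per bin.
#'
#' @param red,green count matrices of identical shape.
#' @return `pmax(red - green, 0)`, same shape.
#' @export
#' @examples
#' corrected_red(matrix(5), matrix(8))   # 0
#' corrected_red(matrix(10), matrix(4))  # 6
corrected_red <- function(red, green) {
  check(all(dim(red) == dim(green)), "red and green must share shape")
  pmax(red - green, 0)
}

#' Assemble a gated channel image
#'
#' Convenience constructor bundling the gated channels of one acquisition:
#' red, green, the corrected-red melanin channel, and optionally the SHG
#' channel (detected spectrally, not by arrival time).
#'
#' @param frame a fluorescence [simulate_frame()] result.
#' @param windows a [gate_windows()].
#' @param shg optional SHG count matrix of the same shape.
#' @return object of class `channel_image` with fields `red`, `green`,
#'   `corrected_red`, `shg`, `windows`, `source`.
#' @export
channel_image <- function(frame, windows = gate_windows(), shg = NULL) {
  ch <- integrate_channels(frame, windows)
  if (!is.null(shg)) check(all(dim(shg) == dim(ch$red)), "shg shape mismatch")
  structure(list(
    red = ch$red, green = ch$green,
    corrected_red = corrected_red(ch$red, ch$green),
    shg = shg, windows = windows,
    source = list(n_accum = frame$n_accum, depth_um = frame$depth_um,
                  provenance = frame$provenance)
  ), class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "Channel image %d x %d px: mean red %.3g, green %.3g, corrected red %.3g%s\n",
    nrow(x$red), ncol(x$red), mean(x$red), mean(x$green), mean(x$corrected_red),
    if (is.null(x$shg)) "" else sprintf(", shg %.3g", mean(x$shg))))
  invisible(x)
}

#' Simulate a fully gated acquisition of one phantom section
#'
#' Runs the forward model for both detection channels at one depth: the
#' fluorescence (TPEF) frame is time-binned and gated into red/green/
#' corrected-red, and the SHG channel is simulated as its own
#' spectrally-separated acquisition.
#'
#' @inheritParams expected_bin_rates
#' @param n_accum accumulated frames.
#' @param windows a [gate_windows()].
#' @param seed integer seed.
#' @param shg logical; also simulate the SHG channel.
#' @return a [channel_image()].
#' @export
simulate_channel_image <- function(phantom, depth, n_accum = 15L,
                                   windows = gate_windows(), seed = 1L,
                                   shg = TRUE, ...) {
  ef <- expected_bin_rates(phantom, depth, channel = "fluorescence", ...)
  fr <- simulate_frame(ef, n_accum, seed = derive_seed(seed, "simulate", 1L))
  shg_img <- NULL
  if (shg) {
    es <- expected_bin_rates(phantom, depth, channel = "shg", ...)
    fs <- simulate_frame(es, n_accum, seed = derive_seed(seed, "simulate", 2L))
    shg_img <- total_counts(fs)
  }
  channel_image(fr, windows, shg = shg_img)
}

#' Compose an 8-bit RGB display image from gated channels
#'
#' Maps corrected red -> R, green -> G, SHG -> B, each independently
#' contrast-stretched between the configured low/high percentiles of its own
#' histogram. Deterministic.
#'
#' @param channels a [channel_image()].
#' @param p_low,p_high stretch percentiles (defaults 0.1 / 99.9).
#' @return integer array (ny x nx x 3) with values 0-255.
#' @export
compose_color <- function(channels, p_low = 0.1, p_high = 99.9) {
  stopifnot(inherits(channels, "channel_image"))
  stretch <- function(m) {
    if (is.null(m)) return(matrix(0L, nrow(channels$red), ncol(channels$red)))
    q <- stats::quantile(m, c(p_low, p_high) / 100, names = FALSE)
    if (q[2] <= q[1]) return(matrix(0L, nrow(m), ncol(m)))
    v <- pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
    matrix(as.integer(round(255 * v)), nrow(m), ncol(m))
  }
  out <- array(0L, dim = c(nrow(channels$red), ncol(channels$red), 3))
  out[, , 1] <- stretch(channels$corrected_red)
  out[, , 2] <- stretch(channels$green)
  out[, , 3] <- stretch(channels$shg)
  out
}

# Otsu threshold of a value vector via a 256-level histogram (maximizes
# between-class variance). Returns the threshold on the value scale and the
# separation quality eta^2 = between-class / total variance, used to detect
# unimodal histograms where Otsu's split is meaningless.
otsu_stats <- function(v) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) return(list(threshold = NA_real_, eta2 = 0))
  mx <- max(v)
  br <- seq(0, mx, length.out = 257)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  sigma_b2 <- (mu_t * w0 - mu0)^2 / pmax(w0 * (1 - w0), 1e-12)
  k <- which.max(sigma_b2[-256])
  total_var <- sum(p * (mids - mu_t)^2)
  list(threshold = br[k + 1], eta2 = sigma_b2[k] / max(total_var, 1e-12),
       mu_below = mu0[k] / max(w0[k], 1e-12))
}

#' 3D virtual melanin staining of a gated z-stack
#'
#' Thresholds the corrected-red channel across a z-stack to produce a binary
#' melanin volume and the melanin-positive pixel fraction per depth. The
#' default policy is Otsu's method on the pooled nonzero corrected-red
#' histogram of the whole stack, accepted only when its lower class is a
#' genuine background mode (below-class mean under the shot-noise floor
#' `2 sqrt(mean(red + green))`, the scale of clipping-induced false
#' positives of the subtraction); otherwise — an all-melanin field with no
#' background mode, or a melanin-free field with a degenerate histogram —
#' the noise floor itself is the threshold. A fixed-quantile policy is also
#' available.
#'
#' @param zstack list of [channel_image()]s, ordered by depth.
#' @param depths strictly increasing depths (um), one per image.
#' @param threshold `"otsu"` (default, with the noise-floor guard) or
#'   `"quantile"`.
#' @param quantile_level quantile for the `"quantile"` policy.
#' @return list: `mask` (nz x ny x nx logical array), `threshold` (counts),
#'   `fraction_by_depth` (data.frame depth_um, fraction).
#' @export
melanin_stain_3d <- function(zstack, depths, threshold = c("otsu", "quantile"),
                             quantile_level = 0.99) {
  threshold <- match.arg(threshold)
  check(length(zstack) > 0, "empty z-stack")
  check(length(depths) == length(zstack) && all(diff(depths) > 0),
        "depths must be strictly increasing, one per image")
  cr <- lapply(zstack, function(ci) ci$corrected_red)
  pooled <- unlist(cr)
  nonzero <- pooled[pooled > 0]
  noise_floor <- 2 * sqrt(mean(unlist(lapply(zstack, function(ci)
    ci$red + ci$green))))
  if (threshold == "quantile") {
    thr <- stats::quantile(pooled, quantile_level, names = FALSE)
  } else {
    ot <- otsu_stats(nonzero)
    thr <- if (is.finite(ot$threshold) && ot$mu_below <= noise_floor) {
      ot$threshold
    } else {
      noise_floor
    }
  }
  nz <- length(zstack)
  mask <- array(FALSE, dim = c(nz, nrow(cr[[1]]), ncol(cr[[1]])))
  frac <- numeric(nz)
  for (k in seq_len(nz)) {
    m <- cr[[k]] > thr
    mask[k, , ] <- m
    frac[k] <- mean(m)
  }
  list(mask = mask, threshold = thr,
       fraction_by_depth = data.frame(depth_um = depths, fraction = frac))
}

#' Dice coefficient and ROC AUC of melanin recovery
#'
#' Quantifies how well the virtual stain recovers the phantom's ground-truth
#' melanin distribution: the Dice coefficient of the binary mask against the
#' truth mask, and the ROC AUC of the continuous corrected-red score against
#' the truth labels (computed with `pROC`).
#'
#' @param mask logical array/volume (the virtual stain).
#' @param truth logical array of the same shape (ground-truth melanin).
#' @param score optional numeric array of the same shape (corrected-red
#'   counts) for the AUC; `NULL` returns `auc = NA`.
#' @return list with `dice` and `auc`.
#' @export
melanin_recovery_score <- function(mask, truth, score = NULL) {
  check(all(dim(mask) == dim(truth)), "mask and truth must share shape")
  if (all(truth) || !any(truth)) {
    stop("truth labels are all one class; AUC/Dice are undefined")
  }
  inter <- sum(mask & truth)
  dice <- 2 * inter / (sum(mask) + sum(truth))
  auc <- NA_real_
  if (!is.null(score)) {
    check(all(dim(score) == dim(truth)), "score and truth must share shape")
    auc <- as.numeric(pROC::auc(
      pROC::roc(as.vector(truth), as.vector(score),
                quiet = TRUE, direction = "<")))
  }
  list(dice = dice, auc = auc)
}
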