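#' Resonant-scan timing configuration
#'
#' Frame timing of a resonant-galvo raster scan. A 4 kHz resonant mirror
#' scanned bidirectionally yields 8000 lines/s, so a 1024 x 1024 frame takes
#' 0.128 s and each pixel is dwelt on for ~0.122 us per frame; accumulating
#' frames multiplies the effective dwell (70 frames ~ 9 us).
#'
#' @param resonant_freq resonant mirror frequency, Hz.
#' @param bidirectional logical; acquire on both sweep directions.
#' @param lines_per_frame,pixels_per_line raster dimensions.
#' @return object of class `scan_timing_config` with derived `line_rate`,
#'   `frame_time_s` and `dwell_us_per_frame`.
#' @export
#' @examples
#' scan_timing_config()$frame_time_s  # 0.128
scan_timing_config <- function(resonant_freq = 4000, bidirectional = TRUE,
                               lines_per_frame = 1024L, pixels_per_line = 1024L) {
  check(resonant_freq > 0, "resonant_freq must be > 0")
  check(lines_per_frame >= 1 && pixels_per_line >= 1, "raster dims must be >= 1")
  line_rate <- resonant_freq * (if (bidirectional) 2 else 1)
  frame_time_s <- lines_per_frame / line_rate
  structure(list(
    resonant_freq = resonant_freq, bidirectional = bidirectional,
    lines_per_frame = as.integer(lines_per_frame),
    pixels_per_line = as.integer(pixels_per_line),
    line_rate = line_rate, frame_time_s = frame_time_s,
    dwell_us_per_frame = frame_time_s / (lines_per_frame * pixels_per_line) * 1e6
  ), class = "scan_timing_config")
}

#' @export
print.scan_timing_config <- function(x, ...) {
  cat(sprintf(
    "Resonant scan: %g kHz %s, %d x %d px, frame %.4g s, dwell %.3g us/frame\n",
    x$resonant_freq / 1000, if (x$bidirectional) "bidirectional" else "unidirectional",
    x$lines_per_frame, x$pixels_per_line, x$frame_time_s, x$dwell_us_per_frame))
  invisible(x)
}

#' Effective pixel dwell time under frame accumulation
#'
#' @param timing a [scan_timing_config()].
#' @param n_accum number of accumulated frames (`>= 0`).
#' @return effective dwell time in microseconds.
#' @export
#' @examples
#' effective_dwell_us(scan_timing_config(), 70)  # ~ 9 us
#' effective_dwell_us(scan_timing_config(), 15)  # ~ 2 us
effective_dwell_us <- function(timing = scan_timing_config(), n_accum) {
  stopifnot(inherits(timing, "scan_timing_config"))
  check(n_accum >= 0, "n_accum must be >= 0")
  n_accum * timing$dwell_us_per_frame
}

#' Expected per-pixel, per-bin photon counts for one frame
#'
#' Forward model for one optical section: for each fluorophore `f` the
#' expected detected photons per pixel per frame are
#' `E_f = ground_truth_image(f, depth) * dwell_us_per_frame * exp(-depth / attenuation_length)`,
#' distributed over arrival-time bins by the fluorophore's analytic decay
#' histogram ([decay_bin_probs()]); a uniform dark-count rate adds
#' `dark_rate * dwell / n_bins` per bin.
#'
#' @param phantom a [generate_phantom()] result.
#' @param depth section depth, um.
#' @param psf a [psf_config()].
#' @param timing a [scan_timing_config()].
#' @param pulse_cfg a [pulse_train_config()].
#' @param irf an [irf_config()].
#' @param attenuation_length depth attenuation length, um (> 0).
#' @param dark_rate dark counts per us of dwell.
#' @param channel which detection channel to assemble (`"fluorescence"`,
#'   `"shg"`, or `"all"`).
#' @return object of class `expected_frame`: list with `means` (ny x nx x
#'   n_bins array of expected counts per single frame), and the acquisition
#'   metadata.
#' @export
expected_bin_rates <- function(phantom, depth, psf = psf_config(),
                               timing = scan_timing_config(),
                               pulse_cfg = pulse_train_config(),
                               irf = irf_config(),
                               attenuation_length = 100, dark_rate = 0,
                               channel = "fluorescence") {
  stopifnot(inherits(phantom, "skin_phantom"))
  check(attenuation_length > 0, "attenuation_length must be > 0")
  check(dark_rate >= 0, "dark_rate must be >= 0")
  fl <- phantom$fluorophores
  if (channel != "all") fl <- Filter(function(f) f$display_channel == channel, fl)
  ny <- phantom$shape[2]; nx <- phantom$shape[3]
  nb <- pulse_cfg$n_bins
  dwell <- timing$dwell_us_per_frame
  att <- exp(-depth / attenuation_length)
  means <- array(0, dim = c(ny, nx, nb))
  for (nm in names(fl)) {
    g <- ground_truth_image(phantom, depth, nm, psf)
    if (all(g == 0)) next
    e_f <- g * dwell * att
    probs <- decay_bin_probs(fl[[nm]]$lifetimes, irf, pulse_cfg,
                             prompt = fl[[nm]]$prompt)
    for (b in seq_len(nb)) means[, , b] <- means[, , b] + e_f * probs[b]
  }
  if (dark_rate > 0) means <- means + dark_rate * dwell / nb
  structure(list(means = means, depth_um = depth, pulse_cfg = pulse_cfg,
                 dwell_us_per_frame = dwell, channel = channel,
                 phantom_seed = phantom$seed),
            class = "expected_frame")
}

#' Simulate an accumulated time-binned photon-count frame
#'
#' Draws independent Poisson counts with mean `n_accum * expected` for every
#' pixel-bin. Accumulating n frames of a Poisson process is itself Poisson
#' with n-fold mean, so a single draw at `n_accum` is distributionally equal
#' to summing `n_accum` single frames.
#'
#' @param expected an [expected_bin_rates()] result, or a bare ny x nx x
#'   n_bins array of per-frame expected counts.
#' @param n_accum number of accumulated frames (`>= 1`).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return object of class `time_binned_frame`: integer `counts` array
#'   (ny x nx x n_bins) plus acquisition metadata.
#' @export
simulate_frame <- function(expected, n_accum = 1L, seed = NULL) {
  check(n_accum >= 1, "n_accum must be >= 1")
  meta <- NULL
  if (inherits(expected, "expected_frame")) {
    meta <- expected
    expected <- expected$means
  }
  check(is.array(expected) && length(dim(expected)) == 3,
        "expected must be an ny x nx x n_bins array")
  check(all(expected >= 0), "expected counts must be nonnegative")
  counts <- with_seed(seed, {
    array(stats::rpois(length(expected), n_accum * expected), dim = dim(expected))
  })
  structure(list(
    counts = counts, n_accum = as.integer(n_accum),
    dwell_us_per_frame = if (is.null(meta)) NA_real_ else meta$dwell_us_per_frame,
    depth_um = if (is.null(meta)) NA_real_ else meta$depth_um,
    pulse_cfg = if (is.null(meta)) pulse_train_config(n_bins = dim(expected)[3]) else meta$pulse_cfg,
    provenance = list(seed = seed,
                      phantom_seed = if (is.null(meta)) NA else meta$phantom_seed)
  ), class = "time_binned_frame")
}

#' @export
print.time_binned_frame <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "Time-binned frame: %d x %d px, %d bins, %d accumulations, %.3g counts/px total\n",
    d[1], d[2], d[3], x$n_accum, mean(apply(x$counts, c(1, 2), sum))))
  invisible(x)
}

#' Total (bin-summed) intensity image of a frame
#'
#' @param frame a [simulate_frame()] result.
#' @return numeric matrix of photon counts summed over arrival-time bins.
#' @export
total_counts <- function(frame) {
  stopifnot(inherits(frame, "time_binned_frame"))
  rowSums(frame$counts, dims = 2)
}

#' Paired low/high-SNR training images
#'
#' Emulates the paired acquisition protocol used to train the restorer: for
#' every phantom section the expected-counts field is computed once, then
#' the low-SNR input (7 or 15 accumulations) and the high-SNR ground truth
#' (70 accumulations) are drawn as independent Poisson realizations of that
#' same field, so pairs are pixel-registered by construction. Ground truth
#' is itself a (much less noisy) acquisition, not a noise-free image. Only
#' the fluorescence (TPEF) channel is paired: restoration is not applied to
#' the SHG channel. One ground truth is drawn per section and shared by
#' both input accumulation levels.
#'
#' @param phantoms list of [generate_phantom()] results.
#' @param depths numeric vector of section depths (um), recycled over
#'   phantoms (each phantom contributes every depth).
#' @param input_accums input accumulation counts (default `c(7, 15)`).
#' @param gt_accum ground-truth accumulation count (default 70).
#' @param seed integer seed.
#' @param ... further arguments passed to [expected_bin_rates()].
#' @return list of pairs; each has `input`, `gt` (count matrices summed over
#'   bins), `input_accum`, `gt_accum`, `depth_um`, `phantom_seed`.
#' @export
make_training_pairs <- function(phantoms, depths, input_accums = c(7L, 15L),
                                gt_accum = 70L, seed = 1L, ...) {
  check(length(phantoms) > 0 && length(depths) > 0,
        "need at least one phantom and one depth")
  if (inherits(phantoms, "skin_phantom")) phantoms <- list(phantoms)
  pairs <- list()
  sec <- 0L
  for (pi in seq_along(phantoms)) {
    for (d in depths) {
      sec <- sec + 1L
      exp_frame <- expected_bin_rates(phantoms[[pi]], d, ...)
      gt_frame <- simulate_frame(exp_frame, gt_accum,
                                 seed = derive_seed(seed, "pairs", sec * 100L))
      gt_img <- total_counts(gt_frame)
      for (ai in seq_along(input_accums)) {
        # degenerate pairing (input_accum == gt_accum) reuses the ground
        # truth's stream, so the pair is identical rather than a re-draw
        in_seed <- if (input_accums[ai] == gt_accum) {
          derive_seed(seed, "pairs", sec * 100L)
        } else {
          derive_seed(seed, "pairs", sec * 100L + ai)
        }
        in_frame <- simulate_frame(exp_frame, input_accums[ai], seed = in_seed)
        pairs[[length(pairs) + 1L]] <- list(
          input = total_counts(in_frame), gt = gt_img,
          input_accum = input_accums[ai], gt_accum = gt_accum,
          depth_um = d, phantom_seed = phantoms[[pi]]$seed)
      }
    }
  }
  pairs
}
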