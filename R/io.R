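# File formats: multi-page 16-bit TIFF for time-binned count stacks (one
# page per arrival-time bin) with a JSON sidecar carrying acquisition
# metadata, and float TIFF + sidecar for channel images and phantoms.
# Sidecars live next to the TIFF as "<path>.json".

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
}

num_or_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a time-binned frame as a multi-page 16-bit TIFF
#'
#' One TIFF page per arrival-time bin, 16-bit unsigned, counts stored
#' exactly (error if any count exceeds 65535); a JSON sidecar
#' (`<path>.json`) records `n_bins`, `n_accum`, dwell, depth, the pulse
#' configuration and provenance. The write/read round trip is bit-identical
#' in counts and metadata.
#'
#' @param frame a [simulate_frame()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_time_binned_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "time_binned_frame"))
  check(max(frame$counts) <= 65535, "counts exceed 16-bit range")
  nb <- dim(frame$counts)[3]
  pages <- lapply(seq_len(nb), function(b) frame$counts[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  write_sidecar(path, list(
    format = "time_binned_frame", n_bins = nb, n_accum = frame$n_accum,
    dwell_us_per_frame = frame$dwell_us_per_frame, depth_um = frame$depth_um,
    pulse_cfg = unclass(frame$pulse_cfg)[c("rep_rate", "n_bins", "bin_phase")],
    provenance = frame$provenance))
  invisible(path)
}

#' Read a time-binned frame written by [write_time_binned_tiff()]
#'
#' A missing sidecar yields default metadata with a warning; a page count
#' that contradicts the sidecar's `n_bins` is a format error.
#'
#' @param path TIFF path.
#' @return a `time_binned_frame`.
#' @export
read_time_binned_tiff <- function(path) {
  check(file.exists(path), paste("no such file:", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(path)
  if (is.null(meta)) {
    warning("missing sidecar ", sidecar_path(path), "; using default metadata")
    meta <- list(n_bins = length(pages), n_accum = 1L,
                 dwell_us_per_frame = NA_real_, depth_um = NA_real_,
                 pulse_cfg = NULL, provenance = NULL)
  }
  if (length(pages) != meta$n_bins) {
    stop(sprintf("format error: %d TIFF pages but sidecar declares %d bins",
                 length(pages), meta$n_bins))
  }
  counts <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) counts[, , b] <- pages[[b]]
  pc <- if (is.null(meta$pulse_cfg)) {
    pulse_train_config(n_bins = length(pages))
  } else {
    pulse_train_config(meta$pulse_cfg$rep_rate, meta$pulse_cfg$n_bins,
                       meta$pulse_cfg$bin_phase)
  }
  structure(list(
    counts = counts, n_accum = as.integer(meta$n_accum),
    dwell_us_per_frame = num_or_na(meta$dwell_us_per_frame),
    depth_um = num_or_na(meta$depth_um), pulse_cfg = pc,
    provenance = meta$provenance
  ), class = "time_binned_frame")
}

#' Write a gated channel image as a multi-page float TIFF
#'
#' Pages in order corrected-red, green, red, plus SHG when present; the
#' sidecar records page order, gate windows and pixel size.
#'
#' @param channels a [channel_image()].
#' @param path output TIFF path.
#' @param pixel_size_um physical pixel pitch recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(channels, path, pixel_size_um = 0.9) {
  stopifnot(inherits(channels, "channel_image"))
  mx <- max(1, channels$red, channels$green,
            if (is.null(channels$shg)) 0 else channels$shg)
  pages <- list(channels$corrected_red / mx, channels$green / mx,
                channels$red / mx)
  names <- c("corrected_red", "green", "red")
  if (!is.null(channels$shg)) {
    pages <- c(pages, list(channels$shg / mx))
    names <- c(names, "shg")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  write_sidecar(path, list(format = "channel_image", channels = names,
                           scale = mx, pixel_size_um = pixel_size_um,
                           windows = unclass(channels$windows),
                           source = channels$source))
  invisible(path)
}

#' Export a phantom to a directory of TIFF stacks
#'
#' One multi-page float TIFF per fluorophore (one page per z-slice), 8-bit
#' mask TIFFs for the melanin/dendrite truth, and a `phantom.json` sidecar
#' with pitch, layer boundaries, seed, parameters and fluorophore
#' photophysics — enough to reproduce or reload the phantom.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "skin_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- phantom$shape[1]
  mx <- list()
  for (nm in names(phantom$concentration)) {
    arr <- phantom$concentration[[nm]]
    m <- max(arr, 1e-12)
    mx[[nm]] <- m
    pages <- lapply(seq_len(nz), function(k) arr[k, , ] / m)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32, compression = "none")
  }
  for (nm in c("melanin_truth", "dendrite_truth")) {
    pages <- lapply(seq_len(nz), function(k) phantom[[nm]][k, , ] * 1)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 8, compression = "none")
  }
  fl <- lapply(phantom$fluorophores, function(f) list(
    name = f$name, prompt = f$prompt, brightness = f$brightness,
    display_channel = f$display_channel,
    lifetimes = if (f$prompt) NULL else f$lifetimes))
  jsonlite::write_json(list(
    format = "skin_phantom", shape = phantom$shape,
    voxel_pitch = phantom$voxel_pitch,
    layer_boundaries = as.list(phantom$layer_boundaries),
    seed = phantom$seed, params = phantom$params, scale = mx,
    fluorophores = fl
  ), file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}

#' Import a phantom exported by [export_phantom()]
#'
#' @param dir directory containing the TIFF stacks and `phantom.json`.
#' @return a `skin_phantom` (concentrations restored to within float32
#'   precision).
#' @export
import_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  read_stack <- function(path, scale = 1) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * scale
    arr
  }
  fl <- lapply(meta$fluorophores, function(rec) {
    fluorophore(rec$name,
                lifetimes = if (isTRUE(rec$prompt)) data.frame(tau = 1, fraction = 1)
                else as.data.frame(rec$lifetimes),
                prompt = isTRUE(rec$prompt), brightness = rec$brightness,
                display_channel = rec$display_channel)
  })
  names(fl) <- vapply(fl, `[[`, character(1), "name")
  conc <- lapply(names(fl), function(nm)
    read_stack(file.path(dir, paste0(nm, ".tif")), meta$scale[[nm]]))
  names(conc) <- names(fl)
  params <- meta$params
  structure(list(
    concentration = conc, fluorophores = fl,
    melanin_truth = read_stack(file.path(dir, "melanin_truth.tif")) > 0.5,
    dendrite_truth = read_stack(file.path(dir, "dendrite_truth.tif")) > 0.5,
    voxel_pitch = meta$voxel_pitch,
    layer_boundaries = unlist(meta$layer_boundaries),
    shape = shape, seed = meta$seed, params = params
  ), class = "skin_phantom")
}

#' Default run configuration
#'
#' The resolved configuration of a pipeline run. Every stage parameter
#' defaults to the standard operating values: 16 arrival-time bins at
#' 80 MHz, gate windows -0.4/1.2 and 0.4/12 ns, 0.75 mm strips under a
#' 13 mm travel limit, 0.9 mm tiles, 5 um z-steps, 7/15 input and 70
#' ground-truth accumulations, 128 px patches with a 10% validation split.
#' A frozen copy of the resolved configuration is written into every output
#' directory so reruns are reproducible.
#'
#' @param ... overrides as `section$name = value` nested lists; unknown
#'   sections are rejected.
#' @param seed global seed fanned out per stage via [derive_seed()].
#' @param out_dir default output directory.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(..., seed = 1L, out_dir = "skinflim-out") {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    pulse = list(rep_rate = 8e7, n_bins = 16L, bin_phase = -0.4),
    irf = list(sigma = 0.57 / (2 * sqrt(2 * log(2)))),
    windows = list(red = c(-0.4, 1.2), green = c(0.4, 12.0)),
    timing = list(resonant_freq = 4000, bidirectional = TRUE,
                  lines_per_frame = 1024L, pixels_per_line = 1024L),
    phantom = list(shape = c(24L, 256L, 256L), pitch = c(2.5, 0.9, 0.9)),
    simulate = list(depth_um = 25, n_accum = 15L, attenuation_length = 100),
    strip = list(strip_width_mm = 0.75, travel_limit_mm = 13),
    tile = list(tile_fov_mm = 0.9, overlap = 0),
    zstack = list(depth_range_um = 150, step_um = 5),
    restore = list(patch_px = 128L, input_accums = c(7L, 15L),
                   gt_accum = 70L, val_fraction = 0.10,
                   epochs = 100L, steps_per_epoch = 30L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Sections missing from the file keep their defaults; the result is fully
#' resolved.
#'
#' @param path JSON file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  check(file.exists(path), paste("no such config file:", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Freeze a resolved run configuration into an output directory
#'
#' @param cfg a [run_config()].
#' @param dir output directory.
#' @return path of the frozen file, invisibly.
#' @export
write_run_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_config.json")
  out <- unclass(cfg)
  out$package_version <- as.character(utils::packageVersion("skinflim"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
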