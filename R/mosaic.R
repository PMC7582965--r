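#' Plan a strip-mosaic acquisition
#'
#' Strip mosaics cover a large area with long, narrow swaths: the resonant
#' mirror scans the fast axis across the strip width while the slow stage
#' travels the strip length; between strips the stage steps laterally by one
#' strip width and reverses travel direction (serpentine). Strip length is
#' bounded by the stage travel range.
#'
#' @param area_w_mm lateral extent to cover (across strips).
#' @param area_h_mm extent along the strip (stage travel direction).
#' @param strip_width_mm strip width (default 0.75 mm).
#' @param travel_limit_mm stage travel range (default 13 mm).
#' @param pixel_pitch_along_um,pixel_pitch_across_um pixel pitches of the
#'   acquired raster along/across the strip.
#' @return object of class `strip_scan_plan` with `n_strips`,
#'   `strip_length_mm` and a serpentine offset table.
#' @export
#' @examples
#' plan_strip_scan(12, 10)$n_strips  # 16 strips cover 10 x 12 mm
plan_strip_scan <- function(area_w_mm, area_h_mm, strip_width_mm = 0.75,
                            travel_limit_mm = 13,
                            pixel_pitch_along_um = 1.25,
                            pixel_pitch_across_um = 1.0) {
  check(area_w_mm > 0 && area_h_mm > 0, "area dimensions must be positive")
  check(strip_width_mm > 0, "strip_width_mm must be positive")
  if (area_h_mm > travel_limit_mm) {
    stop(sprintf(
      "requested strip length %.3g mm exceeds the stage travel limit of %.3g mm",
      area_h_mm, travel_limit_mm))
  }
  n_strips <- ceiling(area_w_mm / strip_width_mm)
  serp <- data.frame(
    strip = seq_len(n_strips),
    x_offset_mm = (seq_len(n_strips) - 1) * strip_width_mm,
    direction = rep_len(c(1L, -1L), n_strips)
  )
  structure(list(
    strip_length_mm = area_h_mm, strip_width_mm = strip_width_mm,
    n_strips = n_strips, travel_limit_mm = travel_limit_mm,
    serpentine = serp,
    pixel_pitch_along_um = pixel_pitch_along_um,
    pixel_pitch_across_um = pixel_pitch_across_um
  ), class = "strip_scan_plan")
}

#' @export
print.strip_scan_plan <- function(x, ...) {
  cat(sprintf("Strip scan: %d strips of %g x %g mm (covers %g x %g mm)\n",
              x$n_strips, x$strip_length_mm, x$strip_width_mm,
              x$strip_length_mm, x$n_strips * x$strip_width_mm))
  invisible(x)
}

#' Plan a tile-mosaic acquisition
#'
#' Tile mosaics step the stage on a grid of full optical fields of view.
#' Nominal megapixels follow the 1 MPx-per-1024^2-tile convention.
#'
#' @param area_w_mm,area_h_mm area to cover.
#' @param tile_fov_mm tile field of view (default 0.9 mm).
#' @param overlap fractional tile overlap in `[0, 0.5)`.
#' @param tile_pixels tile raster size per axis (default 1024).
#' @return object of class `tile_scan_plan` with `grid` (rows, cols) and
#'   `nominal_mpx`.
#' @export
#' @examples
#' plan_tile_scan(4.5, 4.5)$nominal_mpx  # 25
#' plan_tile_scan(6.3, 6.3)$grid         # 7 x 7
plan_tile_scan <- function(area_w_mm, area_h_mm, tile_fov_mm = 0.9,
                           overlap = 0, tile_pixels = 1024L) {
  check(area_w_mm > 0 && area_h_mm > 0, "area dimensions must be positive")
  check(overlap >= 0 && overlap < 0.5, "overlap must lie in [0, 0.5)")
  step <- tile_fov_mm * (1 - overlap)
  cols <- max(1L, ceiling(area_w_mm / step))
  rows <- max(1L, ceiling(area_h_mm / step))
  structure(list(
    tile_fov_mm = tile_fov_mm, grid = c(rows = rows, cols = cols),
    overlap_fraction = overlap, tile_pixels = as.integer(tile_pixels),
    nominal_mpx = rows * cols * (as.numeric(tile_pixels)^2 / 1024^2)
  ), class = "tile_scan_plan")
}

#' @export
print.tile_scan_plan <- function(x, ...) {
  cat(sprintf("Tile scan: %d x %d tiles of %g mm (%g%% overlap), %g MPx nominal\n",
              x$grid[1], x$grid[2], x$tile_fov_mm, 100 * x$overlap_fraction,
              x$nominal_mpx))
  invisible(x)
}

#' Plan a volumetric z-stack
#'
#' Planes are placed at `k * step` for `k = 1..n` below the reference
#' surface, with `n = round(depth_range / step)`; a 150 um range at 5 um
#' steps gives 30 planes. A step larger than the range degenerates to a
#' single plane at `depth_range`.
#'
#' @param depth_range_um depth range below the surface.
#' @param step_um axial step (> 0).
#' @return object of class `zstack_plan` with `n_planes` and `depths_um`.
#' @export
#' @examples
#' plan_zstack(150, 5)$n_planes  # 30
plan_zstack <- function(depth_range_um = 150, step_um = 5) {
  check(step_um > 0, "step_um must be > 0")
  check(depth_range_um > 0, "depth_range_um must be > 0")
  if (step_um > depth_range_um) {
    return(structure(list(depth_range_um = depth_range_um, step_um = step_um,
                          n_planes = 1L, depths_um = depth_range_um),
                     class = "zstack_plan"))
  }
  n <- round(depth_range_um / step_um)
  structure(list(depth_range_um = depth_range_um, step_um = step_um,
                 n_planes = as.integer(n), depths_um = step_um * seq_len(n)),
            class = "zstack_plan")
}

#' @export
print.zstack_plan <- function(x, ...) {
  cat(sprintf("Z-stack: %d planes, %g to %g um every %g um\n",
              x$n_planes, x$depths_um[1], x$depths_um[x$n_planes], x$step_um))
  invisible(x)
}

#' Simulate strip acquisitions from a wide-field truth image
#'
#' Cuts each planned strip out of a noise-free truth image (rows = along the
#' strip, columns = across), applying seeded Gaussian lateral jitter to the
#' strip offsets to emulate imperfect stage repeatability, and resampling to
#' the plan's pixel pitches. With zero jitter and matched pitches the strips
#' are an exact partition of the truth crop. Strips scanned in the reverse
#' serpentine direction are stored as acquired (row order reversed);
#' [stitch_strips()] undoes the reversal.
#'
#' @param truth numeric matrix; the scene.
#' @param truth_pitch_um pixel pitch of `truth` (um, isotropic).
#' @param plan a [plan_strip_scan()].
#' @param jitter_um standard deviation of lateral strip offset error (um).
#' @param seed integer seed for the jitter draws.
#' @return list of strips; each has `image`, `x_offset_mm`, `direction`.
#' @export
simulate_strips <- function(truth, truth_pitch_um, plan, jitter_um = 0,
                            seed = 1L) {
  stopifnot(inherits(plan, "strip_scan_plan"))
  len_px <- round(plan$strip_length_mm * 1000 / plan$pixel_pitch_along_um)
  wid_px <- round(plan$strip_width_mm * 1000 / plan$pixel_pitch_across_um)
  need_rows <- plan$strip_length_mm * 1000 / truth_pitch_um
  need_cols <- plan$n_strips * plan$strip_width_mm * 1000 / truth_pitch_um
  check(nrow(truth) >= floor(need_rows) && ncol(truth) >= floor(need_cols),
        "truth image smaller than the planned scan area")
  jit <- with_seed(seed, stats::rnorm(plan$n_strips, 0, jitter_um))
  if (jitter_um == 0) jit[] <- 0
  strips <- vector("list", plan$n_strips)
  for (i in seq_len(plan$n_strips)) {
    x0_um <- plan$serpentine$x_offset_mm[i] * 1000 + jit[i]
    # sample strip pixel centers from the truth grid
    rows_um <- (seq_len(len_px) - 0.5) * plan$pixel_pitch_along_um
    cols_um <- x0_um + (seq_len(wid_px) - 0.5) * plan$pixel_pitch_across_um
    img <- sample_grid(truth, truth_pitch_um, rows_um, cols_um)
    dir <- plan$serpentine$direction[i]
    if (dir < 0) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    strips[[i]] <- list(image = img, x_offset_mm = plan$serpentine$x_offset_mm[i],
                        direction = dir)
  }
  strips
}

# Sample a matrix at physical coordinates (um): exact indexing when the
# requested centers coincide with pixel centers, Catmull-Rom interpolation
# otherwise. Row/col coordinate of pixel i is (i - 0.5) * pitch.
sample_grid <- function(truth, pitch_um, rows_um, cols_um) {
  ri <- rows_um / pitch_um + 0.5
  ci <- cols_um / pitch_um + 0.5
  exact <- function(x) max(abs(x - round(x))) < 1e-9
  if (exact(ri) && exact(ci)) {
    return(truth[round(ri), round(ci), drop = FALSE])
  }
  # separable cubic interpolation at arbitrary positions
  interp_axis <- function(img, pos, axis) {
    if (axis == 1L) return(t(interp_axis(t(img), pos, 2L)))
    n <- ncol(img)
    i0 <- floor(pos); t_ <- pos - i0
    w1 <- ((-t_ + 2) * t_ - 1) * t_ / 2
    w2 <- (((3 * t_ - 5) * t_) * t_ + 2) / 2
    w3 <- ((-3 * t_ + 4) * t_ + 1) * t_ / 2
    w4 <- ((t_ - 1) * t_ * t_) / 2
    cl <- function(i) pmin(pmax(i, 1L), n)
    img[, cl(i0 - 1)] * rep(w1, each = nrow(img)) +
      img[, cl(i0)] * rep(w2, each = nrow(img)) +
      img[, cl(i0 + 1)] * rep(w3, each = nrow(img)) +
      img[, cl(i0 + 2)] * rep(w4, each = nrow(img))
  }
  interp_axis(interp_axis(truth, ci, 2L), ri, 1L)
}

#' Stitch strips into a mosaic
#'
#' Places each strip at its planned serpentine offset, restoring the
#' acquisition row order of reverse-direction strips. Placement is abutting
#' (no blending): stitching fidelity is attributed to scan synchronization,
#' and registration error is exposed via the jitter parameter of
#' [simulate_strips()] instead.
#'
#' @param strips a [simulate_strips()] result (or conforming list).
#' @param plan the [plan_strip_scan()] used.
#' @return numeric matrix mosaic of all strips.
#' @export
stitch_strips <- function(strips, plan) {
  stopifnot(inherits(plan, "strip_scan_plan"))
  check(length(strips) == plan$n_strips,
        "strip count does not match the plan")
  wid_px <- round(plan$strip_width_mm * 1000 / plan$pixel_pitch_across_um)
  len_px <- nrow(strips[[1]]$image)
  out <- matrix(0, len_px, wid_px * plan$n_strips)
  for (i in seq_along(strips)) {
    img <- strips[[i]]$image
    check(ncol(img) == wid_px, "strip width does not match the plan")
    if (strips[[i]]$direction < 0) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    out[, (i - 1) * wid_px + seq_len(wid_px)] <- img
  }
  attr(out, "pixel_pitch_um") <- c(plan$pixel_pitch_along_um,
                                   plan$pixel_pitch_across_um)
  out
}

#' Rebin an anisotropic raster to isotropic pixels
#'
#' Bicubic (Catmull-Rom) resampling of the coarser-pitch axis up to the
#' finer pitch, so output pixels are square in physical units while the
#' physical extent is preserved (to within half a pixel). Equal pitches
#' return the input unchanged. A 64 MPx raster whose along-strip pitch is
#' 1.25x its across pitch rebins to 80 MPx.
#'
#' @param mosaic numeric matrix.
#' @param pitch_row_um,pitch_col_um physical pitch of rows / columns (um).
#' @return resampled matrix with attribute `pixel_pitch_um` (isotropic).
#' @export
rebin_aspect <- function(mosaic, pitch_row_um, pitch_col_um) {
  check(pitch_row_um > 0 && pitch_col_um > 0, "pitches must be positive")
  if (pitch_row_um == pitch_col_um) {
    attr(mosaic, "pixel_pitch_um") <- c(pitch_row_um, pitch_col_um)
    return(mosaic)
  }
  fine <- min(pitch_row_um, pitch_col_um)
  if (pitch_row_um > fine) {
    n_new <- round(nrow(mosaic) * pitch_row_um / fine)
    mosaic <- resample_axis_cubic(mosaic, n_new, axis = 1L)
  } else {
    n_new <- round(ncol(mosaic) * pitch_col_um / fine)
    mosaic <- resample_axis_cubic(mosaic, n_new, axis = 2L)
  }
  attr(mosaic, "pixel_pitch_um") <- c(fine, fine)
  mosaic
}

#' Stitch tiles into a mosaic
#'
#' Row-major placement of tiles on the planned grid. With zero overlap the
#' tiles abut; with positive overlap the overlapping regions are blended by
#' linear feathering (separable ramp weights, normalized so the blending
#' weights sum to one at every pixel).
#'
#' @param tiles list of numeric matrices, row-major order, length
#'   `rows * cols`.
#' @param plan a [plan_tile_scan()].
#' @return numeric matrix mosaic.
#' @export
stitch_tiles <- function(tiles, plan) {
  stopifnot(inherits(plan, "tile_scan_plan"))
  rows <- plan$grid[1]; cols <- plan$grid[2]
  check(length(tiles) == rows * cols, "tile count does not match the plan")
  tp <- dim(tiles[[1]])
  check(all(vapply(tiles, function(t) all(dim(t) == tp), logical(1))),
        "all tiles must share shape")
  ov_px <- round(plan$overlap_fraction * tp)
  step <- tp - ov_px
  H <- step[1] * (rows - 1) + tp[1]
  W <- step[2] * (cols - 1) + tp[2]
  acc <- matrix(0, H, W)
  wacc <- matrix(0, H, W)
  ramp <- function(n, ov) {
    w <- rep(1, n)
    if (ov > 0) {
      e <- seq_len(ov) / (ov + 1)
      w[seq_len(ov)] <- e
      w[n + 1 - seq_len(ov)] <- e
    }
    w
  }
  wt <- ramp(tp[1], ov_px[1]) %o% ramp(tp[2], ov_px[2])
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      tile <- tiles[[(r - 1) * cols + c]]
      ri <- (r - 1) * step[1] + seq_len(tp[1])
      ci <- (c - 1) * step[2] + seq_len(tp[2])
      acc[ri, ci] <- acc[ri, ci] + tile * wt
      wacc[ri, ci] <- wacc[ri, ci] + wt
    }
  }
  acc / wacc
}

#' Flat-field (field-curvature) correction
#'
#' Estimates a multiplicative gain field from the average intensity pattern
#' across tiles: the across-tile mean image is fit with a low-order 2-D
#' polynomial (order 2 per axis, full tensor basis) and normalized to unit
#' mean; dividing by it flattens the repeating field-curvature vignette.
#' Gain estimation is invariant to global intensity scaling.
#'
#' @param tiles list of at least 4 nonnegative tiles of identical shape, or
#'   a single matrix plus `grid` giving the tile layout to split it by.
#' @param grid optional `c(rows, cols)` when `tiles` is a mosaic matrix.
#' @return list: `corrected` (tiles, or the reassembled mosaic if a mosaic
#'   was given), `gain` (strictly positive matrix, unit mean).
#' @export
flat_field_correct <- function(tiles, grid = NULL) {
  reassemble <- FALSE
  if (is.matrix(tiles)) {
    check(!is.null(grid) && length(grid) == 2, "grid needed to split a mosaic")
    th <- nrow(tiles) / grid[1]; tw <- ncol(tiles) / grid[2]
    check(th == round(th) && tw == round(tw), "mosaic not divisible by grid")
    mos <- tiles
    tiles <- list()
    for (r in seq_len(grid[1])) for (c in seq_len(grid[2])) {
      tiles[[length(tiles) + 1]] <-
        mos[(r - 1) * th + seq_len(th), (c - 1) * tw + seq_len(tw)]
    }
    reassemble <- TRUE
  }
  check(length(tiles) >= 4, "need at least 4 tiles to estimate the gain field")
  check(all(vapply(tiles, function(t) all(t >= 0), logical(1))),
        "input must be nonnegative")
  avg <- Reduce(`+`, tiles) / length(tiles)
  check(any(avg > 0), "degenerate all-zero input")
  h <- nrow(avg); w <- ncol(avg)
  x <- as.vector((col(avg) - (w + 1) / 2) / w)
  y <- as.vector((row(avg) - (h + 1) / 2) / h)
  X <- cbind(1, x, y, x^2, y^2, x * y, x^2 * y, x * y^2, x^2 * y^2)
  fit <- stats::lm.fit(X, as.vector(avg))
  gain <- matrix(X %*% fit$coefficients, h, w)
  gain <- gain / mean(gain)
  gain <- pmax(gain, 1e-6)
  corrected <- lapply(tiles, function(t) t / gain)
  if (reassemble) {
    rows <- grid[1]; cols <- grid[2]
    out <- matrix(0, h * rows, w * cols)
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      out[(r - 1) * h + seq_len(h), (c - 1) * w + seq_len(w)] <-
        corrected[[(r - 1) * cols + c]]
    }
    corrected <- out
  }
  list(corrected = corrected, gain = gain)
}
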