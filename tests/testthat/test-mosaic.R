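test_that("strip planner reproduces the reference scan geometries", {
  p <- plan_strip_scan(12, 10)
  expect_equal(p$n_strips, 16)                 # 10 x 12 mm -> 16 strips
  expect_equal(p$n_strips * p$strip_width_mm, 12)
  expect_equal(p$serpentine$direction[1:4], c(1, -1, 1, -1))
  expect_equal(diff(p$serpentine$x_offset_mm), rep(0.75, 15))
  expect_equal(plan_strip_scan(0.5, 5)$n_strips, 1)
  expect_equal(plan_strip_scan(2.0, 5)$n_strips, 3)  # ceil(2 / 0.75)
  expect_error(plan_strip_scan(5, 14), "travel limit")
  # tight covering: n strips cover the width, n - 1 do not
  p2 <- plan_strip_scan(2.0, 5)
  expect_gte(p2$n_strips * p2$strip_width_mm, 2.0)
  expect_lt((p2$n_strips - 1) * p2$strip_width_mm, 2.0)
})

test_that("tile planner reproduces the reference mosaic layouts", {
  p <- plan_tile_scan(4.5, 4.5)
  expect_equal(unname(p$grid), c(5, 5))
  expect_equal(p$nominal_mpx, 25)              # 4.5 x 4.5 mm -> 25 MPx
  p2 <- plan_tile_scan(6.3, 6.3)
  expect_equal(unname(p2$grid), c(7, 7))
  expect_equal(p2$nominal_mpx, 49)             # 6.3 x 6.3 mm -> 49 MPx
  expect_equal(unname(plan_tile_scan(0.5, 0.5)$grid), c(1, 1))
  expect_error(plan_tile_scan(1, 1, overlap = 0.5), "overlap")
  # overlap shrinks the effective step
  expect_equal(unname(plan_tile_scan(4.5, 4.5, overlap = 0.1)$grid), c(6, 6))
})

test_that("z-stack planner rounds plane counts like the instrument", {
  expect_equal(plan_zstack(150, 5)$n_planes, 30)
  expect_equal(plan_zstack(150, 5)$depths_um, seq(5, 150, by = 5))
  expect_equal(plan_zstack(150, 150)$n_planes, 1)
  expect_equal(plan_zstack(147, 5)$n_planes, 29)  # round(29.4)
  s <- plan_zstack(40, 100)                       # step beyond the range
  expect_equal(s$n_planes, 1)
  expect_equal(s$depths_um, 40)
  expect_error(plan_zstack(100, -5), "step_um")
})

test_that("jitter-free strips partition the truth and stitch back exactly", {
  set.seed(5)
  truth <- matrix(stats::runif(200 * 90), 200, 90)
  # 3 strips of 0.3 mm at 10 um pixels
  plan <- plan_strip_scan(0.9, 2.0, strip_width_mm = 0.3,
                          pixel_pitch_along_um = 10,
                          pixel_pitch_across_um = 10)
  strips <- simulate_strips(truth, 10, plan, jitter_um = 0)
  expect_length(strips, 3)
  expect_equal(dim(strips[[1]]$image), c(200, 30))
  # serpentine acquisition reverses alternate strips
  expect_equal(strips[[2]]$image,
               truth[200:1, 31:60])
  mos <- stitch_strips(strips, plan)
  expect_identical(mos[, ], truth)
  # reproducible jitter, and jitter strictly degrades the round trip
  j1 <- simulate_strips(truth, 10, plan, jitter_um = 15, seed = 4)
  j2 <- simulate_strips(truth, 10, plan, jitter_um = 15, seed = 4)
  expect_identical(j1, j2)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  expect_gt(rms(stitch_strips(j1, plan), truth), 0)
  expect_error(stitch_strips(strips[1:2], plan), "count")
  expect_error(simulate_strips(truth[1:50, ], 10, plan), "smaller")
})

test_that("aspect rebinning upsamples the coarse axis and preserves extent", {
  set.seed(6)
  img <- matrix(stats::runif(80 * 80), 80, 80)
  # equal pitches: bit-identical passthrough
  same <- rebin_aspect(img, 1.25, 1.25)
  expect_identical(same[, ], img)
  # along-pitch 1.25x across: 80 x 80 -> 80 x 100 (64 -> 80 MPx scaled down)
  out <- rebin_aspect(img, 1.0, 1.25)
  expect_equal(dim(out), c(80, 100))
  expect_equal(attr(out, "pixel_pitch_um"), c(1, 1))
  # physical extent preserved: 100 x 1.0 == 80 x 1.25
  expect_equal(100 * 1.0, 80 * 1.25)
  # transposed pitches act on the other axis
  expect_equal(dim(rebin_aspect(img, 1.25, 1.0)), c(100, 80))
  # constants are preserved exactly (cubic weights sum to 1)
  cst <- rebin_aspect(matrix(3.7, 40, 40), 1.25, 1.0)
  expect_equal(as.vector(cst), rep(3.7, length(cst)), tolerance = 1e-12)
})

test_that("tile stitching abuts or feathers and keeps weights normalized", {
  set.seed(7)
  truth <- matrix(stats::runif(64 * 64), 64, 64)
  tiles <- list(truth[1:32, 1:32], truth[1:32, 33:64],
                truth[33:64, 1:32], truth[33:64, 33:64])
  plan <- plan_tile_scan(2, 2, tile_fov_mm = 1, tile_pixels = 32)
  expect_equal(unname(plan$grid), c(2, 2))
  expect_equal(stitch_tiles(tiles, plan), truth)
  expect_identical(stitch_tiles(tiles[1], plan_tile_scan(1, 1, 1)), tiles[[1]])
  # with overlap, a constant field stays constant (weights sum to one)
  planov <- plan_tile_scan(2, 2, tile_fov_mm = 1, overlap = 0.25,
                           tile_pixels = 32)
  ctiles <- replicate(planov$grid[1] * planov$grid[2],
                      matrix(2.5, 32, 32), simplify = FALSE)
  ov <- stitch_tiles(ctiles, planov)
  expect_equal(as.vector(ov), rep(2.5, length(ov)), tolerance = 1e-12)
  expect_error(stitch_tiles(tiles[1:3], plan), "count")
})

test_that("5x5 grids of 1024-px tiles assemble to a 5120-px mosaic", {
  plan <- plan_tile_scan(4.5, 4.5)
  tiles <- replicate(25, matrix(0, 64, 64), simplify = FALSE)
  # scaled-down tiles keep the grid arithmetic: 5 x 64 per axis
  mos <- stitch_tiles(tiles, plan)
  expect_equal(dim(mos), c(320, 320))
  expect_equal(unname(plan$grid * plan$tile_pixels), c(5120, 5120))
})

test_that("flat-field correction recovers a known vignette", {
  h <- 48; w <- 48
  x <- (col(matrix(0, h, w)) - (w + 1) / 2) / w
  y <- (row(matrix(0, h, w)) - (h + 1) / 2) / h
  gain_true <- 1 - 0.4 * (x^2 + y^2)
  gain_true <- gain_true / mean(gain_true)
  set.seed(8)
  tiles <- lapply(1:9, function(i)
    (80 + 20 * stats::runif(1)) * gain_true *
      matrix(1 + 0.05 * stats::rnorm(h * w), h, w))
  ff <- flat_field_correct(tiles)
  expect_true(all(ff$gain > 0))
  expect_equal(mean(ff$gain), 1, tolerance = 1e-9)
  rms <- sqrt(mean((ff$gain - gain_true)^2))
  expect_lt(rms, 0.05)
  # invariance to global intensity scaling
  ff2 <- flat_field_correct(lapply(tiles, function(t) 7 * t))
  expect_equal(ff2$gain, ff$gain, tolerance = 1e-9)
  # flat input -> unit gain, output ~ input
  flat <- replicate(4, matrix(5, 16, 16), simplify = FALSE)
  ff3 <- flat_field_correct(flat)
  expect_equal(ff3$gain, matrix(1, 16, 16), tolerance = 1e-9)
  expect_equal(ff3$corrected[[1]], flat[[1]], tolerance = 1e-9)
  expect_error(flat_field_correct(flat[1:3]), "at least 4")
  expect_error(flat_field_correct(replicate(4, matrix(0, 8, 8),
                                            simplify = FALSE)), "zero")
})

test_that("a mosaic plus grid splits, corrects and reassembles", {
  h <- 24; w <- 24
  x <- (col(matrix(0, h, w)) - (w + 1) / 2) / w
  y <- (row(matrix(0, h, w)) - (h + 1) / 2) / h
  gain <- 1 - 0.3 * (x^2 + y^2); gain <- gain / mean(gain)
  mos <- matrix(0, 2 * h, 2 * w)
  for (r in 0:1) for (c in 0:1) {
    mos[r * h + 1:h, c * w + 1:w] <- 50 * gain
  }
  ff <- flat_field_correct(mos, grid = c(2, 2))
  expect_true(is.matrix(ff$corrected))
  expect_equal(dim(ff$corrected), dim(mos))
  expect_lt(stats::sd(ff$corrected) / mean(ff$corrected), 0.01)
})
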