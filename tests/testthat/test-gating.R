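make_frame <- function(counts) {
  structure(list(counts = counts, n_accum = 1L, dwell_us_per_frame = NA_real_,
                 depth_um = NA_real_, pulse_cfg = pulse_train_config(),
                 provenance = NULL), class = "time_binned_frame")
}

test_that("channel integration follows the window-to-bin mapping", {
  counts <- array(0L, dim = c(4, 4, 16))
  # all counts in bin 1: red only (bin 1 is outside the green window)
  counts[, , 1] <- 7L
  ch <- integrate_channels(make_frame(counts))
  expect_equal(ch$red, matrix(7, 4, 4))
  expect_equal(ch$green, matrix(0, 4, 4))
  # all counts in the shared bin 2: both channels see the total
  counts[, , 1] <- 0L; counts[, , 2] <- 5L
  ch <- integrate_channels(make_frame(counts))
  expect_equal(ch$red, matrix(5, 4, 4))
  expect_equal(ch$green, matrix(5, 4, 4))
  # zero frame -> zero channels
  ch0 <- integrate_channels(make_frame(array(0L, dim = c(4, 4, 16))))
  expect_true(all(ch0$red == 0) && all(ch0$green == 0))
})

test_that("corrected red subtracts and clips at zero", {
  expect_equal(corrected_red(matrix(5), matrix(8)), matrix(0))
  expect_equal(corrected_red(matrix(10), matrix(4)), matrix(6))
  m <- matrix(1:9, 3)
  expect_equal(corrected_red(m, m), matrix(0, 3, 3))
  expect_error(corrected_red(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  # channel_image invariants: 0 <= corrected_red <= red
  fr <- simulate_frame(expected_bin_rates(tiny_phantom(), 25), 15, seed = 5)
  ci <- channel_image(fr)
  expect_true(all(ci$corrected_red >= 0))
  expect_true(all(ci$corrected_red <= ci$red))
})

test_that("color composition maps channels to RGB deterministically", {
  fr0 <- make_frame(array(0L, dim = c(8, 8, 16)))
  ci0 <- channel_image(fr0, shg = matrix(0, 8, 8))
  expect_true(all(compose_color(ci0) == 0))
  # only SHG -> pure blue
  ci_shg <- channel_image(fr0, shg = matrix(stats::rpois(64, 50), 8, 8))
  rgb <- compose_color(ci_shg)
  expect_true(all(rgb[, , 1] == 0) && all(rgb[, , 2] == 0))
  expect_gt(max(rgb[, , 3]), 200)
  # a melanin pixel in long-lifetime surroundings comes out red-dominant
  probs_mel <- decay_bin_probs(data.frame(tau = 0.2, fraction = 1), irf_config())
  probs_bg <- decay_bin_probs(data.frame(tau = 2.5, fraction = 1), irf_config())
  counts <- array(0L, dim = c(8, 8, 16))
  for (b in 1:16) counts[, , b] <- as.integer(round(2000 * probs_bg[b]))
  counts[4, 4, ] <- as.integer(round(2000 * probs_mel))
  ci_mel <- channel_image(make_frame(counts), shg = matrix(0L, 8, 8))
  rgb <- compose_color(ci_mel)
  expect_gt(rgb[4, 4, 1], rgb[4, 4, 2])
  expect_gt(rgb[4, 4, 1], rgb[4, 4, 3])
})

test_that("long-lifetime emitters vanish from corrected red at high counts", {
  probs <- decay_bin_probs(data.frame(tau = 2.5, fraction = 1), irf_config())
  mu <- 1e4
  counts <- array(0L, dim = c(50, 50, 16))
  set.seed(61)
  for (b in 1:16) counts[, , b] <- stats::rpois(2500, mu * probs[b])
  ci <- channel_image(make_frame(counts))
  expect_lt(mean(ci$corrected_red) / mu, 0.01)
})

test_that("pure melanin corrected red matches its analytic expectation", {
  cfg <- pulse_train_config()
  probs <- decay_bin_probs(data.frame(tau = 0.2, fraction = 1), irf_config(), cfg)
  red_m <- sum(probs[window_to_bins(c(-0.4, 1.2), cfg)])
  green_m <- sum(probs[window_to_bins(c(0.4, 12), cfg)])
  expect_gt(red_m - green_m, 0)  # melanin survives the subtraction
  mu <- 2000
  npx <- 2500
  counts <- array(0L, dim = c(50, 50, 16))
  set.seed(62)
  for (b in 1:16) counts[, , b] <- stats::rpois(npx, mu * probs[b])
  ci <- channel_image(make_frame(counts))
  observed <- mean(ci$corrected_red) / mu
  # E[max(R - G, 0)] ~ E[R] - E[G] at high counts; 3 SE tolerance.
  # R - G sums the disjoint bin variances (shared bin 2 cancels).
  rb <- setdiff(window_to_bins(c(-0.4, 1.2), cfg), window_to_bins(c(0.4, 12), cfg))
  gb <- setdiff(window_to_bins(c(0.4, 12), cfg), window_to_bins(c(-0.4, 1.2), cfg))
  se <- sqrt(mu * (sum(probs[rb]) + sum(probs[gb])) / npx) / mu
  expect_lt(abs(observed - (red_m - green_m)), 3 * se)
})

test_that("expected corrected red is monotone in melanin concentration", {
  cfg <- pulse_train_config()
  irf <- irf_config()
  p_mel <- decay_bin_probs(data.frame(tau = 0.2, fraction = 1), irf, cfg)
  p_bg <- decay_bin_probs(data.frame(tau = c(0.4, 2.5),
                                     fraction = c(0.75, 0.25)), irf, cfg)
  rb <- window_to_bins(c(-0.4, 1.2), cfg)
  gb <- window_to_bins(c(0.4, 12), cfg)
  contrast <- function(mel) {
    mu <- 50 * p_bg + mel * p_mel
    sum(mu[rb]) - sum(mu[gb])
  }
  vals <- vapply(seq(0, 100, by = 10), contrast, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("3D virtual staining thresholds a stack and reports fractions", {
  ph <- tiny_phantom()
  depths <- c(15, 25, 35)
  stack <- lapply(seq_along(depths), function(k)
    simulate_channel_image(ph, depths[k], n_accum = 15, seed = 70 + k,
                           shg = FALSE))
  st <- melanin_stain_3d(stack, depths)
  expect_equal(dim(st$mask), c(3, 96, 96))
  expect_equal(st$fraction_by_depth$depth_um, depths)
  expect_true(all(st$fraction_by_depth$fraction >= 0 &
                    st$fraction_by_depth$fraction <= 1))
  expect_true(is.finite(st$threshold) && st$threshold > 0)
  expect_error(melanin_stain_3d(list(), numeric(0)), "empty")
  expect_error(melanin_stain_3d(stack, c(1, 1, 2)), "increasing")
  # empty counts -> all-negative mask
  fr0 <- make_frame(array(0L, dim = c(8, 8, 16)))
  st0 <- melanin_stain_3d(list(channel_image(fr0)), 10)
  expect_false(any(st0$mask))
})

test_that("a melanin-free stack stains almost nothing, a melanin slab stains out", {
  # long-lifetime-only tissue at high counts: clipping bias keeps the
  # stain fraction below 1%
  probs_bg <- decay_bin_probs(data.frame(tau = 2.5, fraction = 1), irf_config())
  mk_stack <- function(probs, mu, n = 2, px = 40, seed = 80) {
    set.seed(seed)
    lapply(seq_len(n), function(k) {
      counts <- array(0L, dim = c(px, px, 16))
      for (b in 1:16) counts[, , b] <- stats::rpois(px * px, mu * probs[b])
      channel_image(make_frame(counts))
    })
  }
  st_bg <- melanin_stain_3d(mk_stack(probs_bg, 200), c(10, 20))
  expect_lt(mean(st_bg$mask), 0.01)
  # all-melanin slab: stain positive nearly everywhere
  probs_mel <- decay_bin_probs(data.frame(tau = 0.2, fraction = 1), irf_config())
  st_mel <- melanin_stain_3d(mk_stack(probs_mel, 200, seed = 81), c(10, 20))
  expect_gt(mean(st_mel$mask), 0.9)
})

test_that("recovery scores match their definitions and the brute-force AUC", {
  truth <- array(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), dim = c(1, 2, 3))
  expect_equal(melanin_recovery_score(truth, truth)$dice, 1)
  expect_equal(melanin_recovery_score(!truth, truth)$dice, 0)
  expect_error(melanin_recovery_score(truth, truth & FALSE), "one class")
  set.seed(91)
  score <- array(stats::runif(60), dim = c(3, 4, 5))
  truth <- score + array(stats::rnorm(60, 0, 0.5), dim = dim(score)) > 0.5
  if (any(truth) && !all(truth)) {
    got <- melanin_recovery_score(score > 0.5, truth, score = score)
    expect_equal(got$auc, auc_bruteforce(score, truth), tolerance = 1e-12)
    expect_gte(got$dice, 0)
  }
})
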