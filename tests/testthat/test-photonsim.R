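test_that("scan timing reproduces the documented dwell arithmetic", {
  tm <- scan_timing_config()
  expect_equal(tm$line_rate, 8000)
  expect_equal(tm$frame_time_s, 0.128)
  # 70 accumulations ~ 9 us, 15 ~ 2 us, 7 ~ 1 us effective dwell
  expect_equal(round(effective_dwell_us(tm, 70)), 9)
  expect_equal(round(effective_dwell_us(tm, 15)), 2)
  expect_equal(round(effective_dwell_us(tm, 7)), 1)
  expect_equal(effective_dwell_us(tm, 0), 0)
  # unidirectional halves the line rate
  expect_equal(scan_timing_config(bidirectional = FALSE)$line_rate, 4000)
})

test_that("expected bin rates follow the forward model", {
  ph <- tiny_phantom()
  ef <- expected_bin_rates(ph, 25)
  expect_s3_class(ef, "expected_frame")
  expect_equal(dim(ef$means), c(96, 96, 16))
  expect_true(all(ef$means >= 0))
  # per-bin means of a single-fluorophore phantom factorize through the
  # decay histogram
  ph1 <- ph
  for (nm in setdiff(names(ph1$concentration), "nadh")) {
    ph1$concentration[[nm]][] <- 0
  }
  ef1 <- expected_bin_rates(ph1, 25)
  tot <- rowSums(ef1$means, dims = 2)
  probs <- decay_bin_probs(ph$fluorophores$nadh$lifetimes, irf_config())
  px <- which(tot == max(tot))[1]
  for (b in c(1, 5, 16)) {
    expect_equal(ef1$means[, , b][px], tot[px] * probs[b], tolerance = 1e-9)
  }
  # exponential depth attenuation
  ef_att <- expected_bin_rates(ph1, 25, attenuation_length = 25)
  expect_equal(ef_att$means, ef1$means * exp(-1) / exp(-25 / 100),
               tolerance = 1e-9)
  # empty phantom, zero dark rate -> zero expectation
  ph0 <- ph1
  ph0$concentration$nadh[] <- 0
  expect_true(all(expected_bin_rates(ph0, 25)$means == 0))
  # dark counts spread uniformly over bins
  efd <- expected_bin_rates(ph0, 25, dark_rate = 2)
  expect_equal(unique(as.vector(efd$means)),
               2 * scan_timing_config()$dwell_us_per_frame / 16)
})

test_that("simulated frames are Poisson with the accumulated mean", {
  means <- array(100 / 16, dim = c(100, 100, 16))
  fr <- simulate_frame(means, n_accum = 1, seed = 11)
  expect_true(all(fr$counts >= 0))
  expect_identical(fr$counts, simulate_frame(means, 1, seed = 11)$counts)
  # mean 100 per pixel over 10,000 pixels: within 3 standard errors
  tot <- rowSums(fr$counts, dims = 2)
  expect_lt(abs(mean(tot) - 100), 3 * sqrt(100 / 1e4))
  # variance consistent with Poisson
  expect_lt(abs(var(as.vector(tot)) / 100 - 1), 0.1)
  expect_true(all(simulate_frame(means * 0, 5, seed = 1)$counts == 0))
  expect_error(simulate_frame(means, 0), "n_accum")
  expect_error(simulate_frame(means - 10, 1), "nonnegative")
})

test_that("one accumulated draw matches the sum of single frames in distribution", {
  mu <- array(3.7, dim = c(100, 100, 1))
  acc <- as.vector(simulate_frame(mu, n_accum = 70, seed = 21)$counts)
  summed <- Reduce(`+`, lapply(1:70, function(i)
    as.vector(simulate_frame(mu, 1, seed = 100 + i)$counts)))
  ks <- suppressWarnings(stats::ks.test(acc, summed))
  expect_gt(ks$p.value, 0.01)
})

test_that("photon conservation and sqrt(n) SNR scaling hold", {
  ph <- tiny_phantom()
  ef <- expected_bin_rates(ph, 25)
  rate <- rowSums(ef$means, dims = 2)  # expected counts per frame
  fr <- simulate_frame(ef, 70, seed = 31)
  tot <- total_counts(fr)
  # summing over bins and dividing by n_accum recovers the emission rate
  expect_lt(abs(sum(tot) / 70 - sum(rate)) / sqrt(sum(rate) / 70), 3)
  # empirical per-pixel SNR ratio between 70 and 15 accumulations ~ sqrt(70/15)
  reps <- 40
  px <- which(rate > quantile(rate, 0.95))[1:50]
  sim_px <- function(n_acc) sapply(1:reps, function(i)
    total_counts(simulate_frame(ef, n_acc, seed = 500 + n_acc + i * 7))[px])
  s70 <- sim_px(70); s15 <- sim_px(15)
  snr70 <- apply(s70, 1, mean) / apply(s70, 1, sd)
  snr15 <- apply(s15, 1, mean) / apply(s15, 1, sd)
  expect_lt(abs(median(snr70 / snr15) / sqrt(70 / 15) - 1), 0.1)
})

test_that("training pairs are registered, counted and degenerate-safe", {
  ph <- tiny_phantom()
  pairs <- make_training_pairs(ph, depths = c(20, 30), seed = 3)
  # |sections| x |input_accums| pairs
  expect_length(pairs, 2 * 2)
  expect_equal(vapply(pairs, `[[`, numeric(1), "input_accum"),
               c(7, 15, 7, 15))
  expect_true(all(vapply(pairs, function(p)
    all(dim(p$input) == dim(p$gt)), logical(1))))
  # both accumulation levels of one section share the same ground truth
  expect_identical(pairs[[1]]$gt, pairs[[2]]$gt)
  # degenerate pairing: gt_accum as input with the same seed is identical
  dg <- make_training_pairs(ph, depths = 20, input_accums = 70L,
                            gt_accum = 70L, seed = 3)
  expect_identical(dg[[1]]$input, dg[[1]]$gt)
  expect_error(make_training_pairs(list(), depths = 20), "at least one")
})
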