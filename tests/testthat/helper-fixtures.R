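# Shared small fixtures, built once per test run.

# tiny phantom: fast to generate, still contains all tissue features
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(seed = 42, shape = c(24, 96, 96),
                                 pitch = c(2.5, 0.9, 0.9))
    }
    cache
  }
})

# Monte-Carlo oracle for wrapped decay histograms: sample exponential arrival
# times (mixture), add Gaussian IRF jitter, wrap modulo the period, histogram
# into the configured bins.
mc_bin_probs <- function(n, lifetimes, sigma, cfg, prompt = FALSE) {
  comp <- sample.int(nrow(lifetimes), n, replace = TRUE,
                     prob = lifetimes$fraction)
  t <- if (prompt) numeric(n) else stats::rexp(n, 1 / lifetimes$tau[comp])
  if (sigma > 0) t <- t + stats::rnorm(n, 0, sigma)
  t <- (t - cfg$bin_phase) %% cfg$period_ns + cfg$bin_phase
  graphics::hist(t, breaks = bin_edges(cfg), plot = FALSE)$counts / n
}

# brute-force ROC AUC oracle: enumerate all score thresholds
auc_bruteforce <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  gr <- outer(pos, neg, `>`)
  eq <- outer(pos, neg, `==`)
  mean(gr + 0.5 * eq)
}
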