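#' Pulse-train configuration
#'
#' Describes the excitation pulse train and the arrival-time binning of the
#' single-photon-counting detection: an 80 MHz laser gives a 12.5 ns period
#' which the timing electronics divide into `n_bins` equal arrival-time bins
#' (16 bins of ~780 ps by default). `bin_phase` places the leading edge of
#' bin 1 relative to the excitation pulse; the default of -0.4 ns makes the
#' conventional red gate \[-0.4, 1.2\] ns start exactly on a bin edge, so the
#' documented red/green windows map onto whole bins (see [window_to_bins()]).
#'
#' @param rep_rate laser repetition rate in Hz.
#' @param n_bins number of arrival-time bins per period.
#' @param bin_phase offset (ns) of bin 1's leading edge relative to the
#'   excitation pulse; must lie in `(-period, 0]`. Photons at negative times
#'   are late photons from the previous pulse, folded in by the periodic wrap.
#' @return an object of class `pulse_train_config` with derived fields
#'   `period_ns` and `bin_width_ns`.
#' @export
#' @examples
#' cfg <- pulse_train_config()
#' cfg$period_ns     # 12.5
#' cfg$bin_width_ns  # 0.78125 ~ 780 ps
pulse_train_config <- function(rep_rate = 8e7, n_bins = 16L, bin_phase = -0.4) {
  check(is.numeric(rep_rate) && rep_rate > 0, "rep_rate must be > 0")
  n_bins <- as.integer(n_bins)
  check(n_bins >= 1L, "n_bins must be >= 1")
  period_ns <- 1e9 / rep_rate
  check(is.numeric(bin_phase) && bin_phase > -period_ns && bin_phase <= 0,
        "bin_phase must lie in (-period_ns, 0]")
  structure(
    list(rep_rate = rep_rate, n_bins = n_bins, bin_phase = bin_phase,
         period_ns = period_ns, bin_width_ns = period_ns / n_bins),
    class = "pulse_train_config"
  )
}

#' @export
print.pulse_train_config <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %.1f MHz (period %.4g ns), %d bins of %.5g ns, phase %.3g ns\n",
    x$rep_rate / 1e6, x$period_ns, x$n_bins, x$bin_width_ns, x$bin_phase))
  invisible(x)
}

#' Red/green lifetime gate windows
#'
#' Arrival-time windows (ns, relative to the excitation pulse) used for the
#' virtual short-lifetime ("red") and long-lifetime ("green") detection
#' channels. The defaults, \[-0.4, 1.2\] and \[0.4, 12\] ns, deliberately
#' overlap: with the default binning both windows contain bin 2, which is why
#' a subtraction (see [corrected_red()]) is needed to isolate the
#' short-lifetime melanin signature.
#'
#' @param red,green numeric length-2 intervals in ns.
#' @return an object of class `gate_windows`.
#' @export
gate_windows <- function(red = c(-0.4, 1.2), green = c(0.4, 12.0)) {
  for (w in list(red, green)) {
    check(is.numeric(w) && length(w) == 2 && w[1] < w[2],
          "each window must be a numeric interval c(lo, hi) with lo < hi")
  }
  structure(list(red = red, green = green), class = "gate_windows")
}

#' @export
print.gate_windows <- function(x, ...) {
  cat(sprintf("Gate windows (ns): red [%g, %g], green [%g, %g]\n",
              x$red[1], x$red[2], x$green[1], x$green[2]))
  invisible(x)
}

#' Instrument response function
#'
#' Gaussian temporal instrument response of the detection chain. The default
#' standard deviation derives from a 570 ps detector rise time treated as an
#' effective FWHM: `sigma = 0.57 / (2 sqrt(2 log 2)) ~ 0.242 ns`, safely below
#' the 780 ps bin width, consistent with a sampling-limited system.
#' `sigma = 0` selects an ideal prompt response.
#'
#' @param sigma Gaussian standard deviation in ns, `>= 0`.
#' @return an object of class `irf_config`.
#' @export
irf_config <- function(sigma = 0.57 / (2 * sqrt(2 * log(2)))) {
  check(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
        "sigma must be a single number >= 0")
  structure(list(sigma = sigma), class = "irf_config")
}

#' Arrival-time bin edges
#'
#' @param cfg a [pulse_train_config()].
#' @return numeric vector of `n_bins + 1` strictly increasing, equally spaced
#'   edge times (ns) starting at `bin_phase` and spanning one period.
#' @export
#' @examples
#' bin_edges(pulse_train_config())  # -0.4 to 12.1 ns in 0.78125 ns steps
bin_edges <- function(cfg = pulse_train_config()) {
  stopifnot(inherits(cfg, "pulse_train_config"))
  cfg$bin_phase + (0:cfg$n_bins) * cfg$bin_width_ns
}

#' Map a gate window to arrival-time bins
#'
#' A bin belongs to a window iff its center lies inside the window (closed
#' interval). This center-snapping rule mirrors what integer-bin hardware can
#' do: no fractional-bin weighting. With the default configuration the red
#' window maps to bins `{1, 2}` and the green window to `{2, ..., 16}`; the
#' shared bin 2 realizes the documented overlap of the two channels.
#'
#' @param window numeric interval (ns) within the aligned period
#'   `[bin_phase, bin_phase + period]`.
#' @param cfg a [pulse_train_config()].
#' @return integer vector of 1-based bin indices.
#' @export
#' @examples
#' window_to_bins(c(-0.4, 1.2))  # 1 2
#' window_to_bins(c(0.4, 12))    # 2 ... 16
window_to_bins <- function(window, cfg = pulse_train_config()) {
  stopifnot(inherits(cfg, "pulse_train_config"))
  check(is.numeric(window) && length(window) == 2 && window[1] < window[2],
        "window must be c(lo, hi) with lo < hi")
  lo <- cfg$bin_phase
  hi <- cfg$bin_phase + cfg$period_ns
  tol <- 1e-9
  if (window[1] < lo - tol || window[2] > hi + tol) {
    stop(sprintf(
      "window [%g, %g] ns lies outside the aligned period [%g, %g] ns; check bin_phase",
      window[1], window[2], lo, hi))
  }
  centers <- cfg$bin_phase + (seq_len(cfg$n_bins) - 0.5) * cfg$bin_width_ns
  idx <- which(centers >= window[1] - tol & centers <= window[2] + tol)
  if (length(idx) == 0) stop("window contains no bin center; widen the window")
  idx
}

# Wrapped-exponential CDF on [0, T): steady-state decay under a pulse train.
# Density e^(-t/tau) / (tau (1 - e^(-T/tau))).
wrapped_exp_cdf <- function(u, tau, period) {
  expm1(-u / tau) / expm1(-period / tau)
}

# Mass of the wrapped exponential over an arbitrary interval [a, b] of width
# <= period; a, b are arbitrary reals, interpreted modulo the period.
wrapped_exp_mass <- function(a, b, tau, period) {
  width <- b - a
  a0 <- a %% period
  b0 <- a0 + width
  ifelse(
    b0 <= period,
    wrapped_exp_cdf(b0, tau, period) - wrapped_exp_cdf(a0, tau, period),
    1 - wrapped_exp_cdf(a0, tau, period) + wrapped_exp_cdf(b0 - period, tau, period)
  )
}

# Mass of the wrapped Gaussian (prompt/SHG emitter with IRF jitter) over
# [a, b]; exact wrap sum truncated where terms are < 1e-12.
wrapped_gauss_mass <- function(a, b, sigma, period) {
  if (sigma == 0) stop("internal: sigma 0 handled by caller")
  kmax <- ceiling((8 * sigma + max(abs(a), abs(b))) / period) + 1
  s <- 0
  for (k in -kmax:kmax) {
    term <- stats::pnorm((b + k * period) / sigma) -
      stats::pnorm((a + k * period) / sigma)
    s <- s + term
  }
  s
}

# Shared engine for decay masses over arbitrary intervals. `edges` is a
# vector of interval boundaries (ns); returns the mass in each interval.
decay_interval_mass <- function(edges, lifetimes, irf, cfg, prompt) {
  period <- cfg$period_ns
  sigma <- irf$sigma
  nint <- length(edges) - 1L
  a <- edges[-length(edges)]
  b <- edges[-1]
  if (prompt) {
    if (sigma == 0) {
      # all mass at t = 0 (mod period): locate the interval containing 0
      z <- 0
      u <- (z - edges[1]) %% period + edges[1]
      hit <- which(a <= u & u < b)
      out <- numeric(nint)
      out[hit] <- 1
      return(out)
    }
    return(vapply(seq_len(nint), function(i)
      wrapped_gauss_mass(a[i], b[i], sigma, period), numeric(1)))
  }
  taus <- lifetimes$tau
  fracs <- lifetimes$fraction
  check(all(taus > 0), "lifetimes must be positive")
  check(abs(sum(fracs) - 1) < 1e-9, "lifetime fractions must sum to 1")
  one_comp <- function(tau) {
    if (sigma == 0) return(wrapped_exp_mass(a, b, tau, period))
    # Convolve with the Gaussian IRF by quadrature over the jitter z:
    # mass(a,b) = E_z[ wrapped_exp_mass(a - z, b - z) ], z ~ N(0, sigma).
    # The integrand varies on the lifetime scale, so the node count is
    # generous; the omitted Gaussian tail beyond 8 sigma is < 1e-15.
    gl <- pracma::gaussLegendre(512, -8 * sigma, 8 * sigma)
    m <- numeric(nint)
    for (j in seq_along(gl$x)) {
      z <- gl$x[j]
      w <- gl$w[j] * stats::dnorm(z, sd = sigma)
      m <- m + w * wrapped_exp_mass(a - z, b - z, tau, period)
    }
    m
  }
  out <- numeric(nint)
  for (i in seq_along(taus)) out <- out + fracs[i] * one_comp(taus[i])
  out
}

#' Analytic per-bin arrival-time probabilities of a fluorescence decay
#'
#' Computes the steady-state wrapped exponential decay
#' `p(t) = e^(-t/tau) / (tau (1 - e^(-T/tau)))` on one pulse period
#' `t in [0, T)`, integrates it over each (phase-shifted) arrival-time bin,
#' and convolves with the Gaussian instrument response when `sigma > 0`
#' (numerically, by Gauss-Legendre quadrature over the jitter). Multi-
#' exponential decays are fraction-weighted mixtures. A prompt emitter
#' (second-harmonic generation, effectively zero lifetime) is requested with
#' `prompt = TRUE`, in which case `lifetimes` is ignored.
#'
#' @param lifetimes data.frame (or list coercible to one) with columns `tau`
#'   (ns, > 0) and `fraction` (summing to 1).
#' @param irf an [irf_config()].
#' @param cfg a [pulse_train_config()].
#' @param prompt logical; `TRUE` models an instantaneous emitter.
#' @return numeric vector of length `n_bins`, nonnegative, summing to 1.
#' @export
#' @examples
#' p <- decay_bin_probs(data.frame(tau = 0.2, fraction = 1), irf_config(0))
#' sum(p)  # 1
decay_bin_probs <- function(lifetimes = data.frame(tau = 2.5, fraction = 1),
                            irf = irf_config(), cfg = pulse_train_config(),
                            prompt = FALSE) {
  stopifnot(inherits(irf, "irf_config"), inherits(cfg, "pulse_train_config"))
  if (!prompt) lifetimes <- as.data.frame(lifetimes)
  p <- decay_interval_mass(bin_edges(cfg), lifetimes, irf, cfg, prompt)
  p <- pmax(p, 0)
  p / sum(p)
}

#' Analytic decay mass in an arbitrary time window
#'
#' Window-exact (not bin-snapped) probability that a photon's wrapped arrival
#' time falls inside `window`. Useful for closed-form expectations of the
#' gated channels, e.g. the expected corrected-red fraction of a pure
#' short-lifetime emitter.
#'
#' @inheritParams decay_bin_probs
#' @param window numeric interval (ns) of width at most one period.
#' @return scalar probability in `[0, 1]`.
#' @export
#' @examples
#' # short-lifetime emitter, mass in the default green window:
#' decay_window_mass(c(0.4, 12), data.frame(tau = 0.2, fraction = 1),
#'                   irf_config(0))
decay_window_mass <- function(window, lifetimes, irf = irf_config(),
                              cfg = pulse_train_config(), prompt = FALSE) {
  check(is.numeric(window) && length(window) == 2 && window[1] < window[2] &&
          (window[2] - window[1]) <= cfg$period_ns + 1e-9,
        "window must be an interval no wider than one period")
  if (!prompt) lifetimes <- as.data.frame(lifetimes)
  m <- decay_interval_mass(window, lifetimes, irf, cfg, prompt)
  min(max(m, 0), 1)
}
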