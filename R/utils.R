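#' @keywords internal
#' @importFrom stats rnorm rpois runif rexp quantile dnorm pnorm sd lm.fit
#' @importFrom utils tail packageVersion
#' @importFrom grDevices gray
"_PACKAGE"

# Run `expr` under a private RNG stream, restoring the caller's .Random.seed.
# All stochastic operations in the package funnel through this, so a seed
# argument makes the operation reproducible without disturbing global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global run seed
#'
#' A single run-level seed fans out to independent per-stage seeds through a
#' fixed counter scheme, so any pipeline stage can be re-run in isolation and
#' still reproduce its stream. Stages are indexed by name from a fixed table.
#'
#' @param seed global integer seed.
#' @param stage stage name, one of `"phantom"`, `"simulate"`, `"gate"`,
#'   `"stitch"`, `"zstack"`, `"pairs"`, `"train"`, `"restore"`, `"eval"`,
#'   or an integer offset.
#' @param index optional extra index (e.g. phantom number) folded in.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "phantom")
#' derive_seed(1, "train", index = 3)
derive_seed <- function(seed, stage, index = 0L) {
  stages <- c(
    phantom = 1L, simulate = 2L, gate = 3L, stitch = 4L, zstack = 5L,
    pairs = 6L, train = 7L, restore = 8L, eval = 9L
  )
  off <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else as.integer(stage)
  as.integer((as.double(seed) * 1009 + off * 101 + as.double(index)) %% 2147483647)
}

# Stop unless all conditions hold, with the failing expression in the message.
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Separable valid-region convolution of a matrix with a 1-D kernel applied
# along both axes; used by the SSIM local statistics.
sep_conv_valid <- function(a, k) {
  win <- length(k)
  r <- (win - 1L) %/% 2L
  H <- nrow(a); W <- ncol(a)
  out <- matrix(0, H, W - 2L * r)
  for (i in seq_len(win)) out <- out + k[i] * a[, i:(W - win + i), drop = FALSE]
  out2 <- matrix(0, H - 2L * r, ncol(out))
  for (i in seq_len(win)) out2 <- out2 + k[i] * out[i:(H - win + i), , drop = FALSE]
  out2
}

# Catmull-Rom (bicubic) resampling of one axis of a matrix from n to n_new
# samples, preserving physical extent (pixel-center alignment convention
# u = (j - 0.5) * n / n_new + 0.5). Constants are preserved exactly because
# the kernel weights sum to 1.
resample_axis_cubic <- function(img, n_new, axis = 2L) {
  if (axis == 1L) return(t(resample_axis_cubic(t(img), n_new, axis = 2L)))
  n <- ncol(img)
  if (n_new == n) return(img)
  u <- (seq_len(n_new) - 0.5) * n / n_new + 0.5
  i0 <- floor(u)
  t_ <- u - i0
  # Catmull-Rom weights for the four taps at i0-1 .. i0+2
  w1 <- ((-t_ + 2) * t_ - 1) * t_ / 2
  w2 <- (((3 * t_ - 5) * t_) * t_ + 2) / 2
  w3 <- ((-3 * t_ + 4) * t_ + 1) * t_ / 2
  w4 <- ((t_ - 1) * t_ * t_) / 2
  clampi <- function(i) pmin(pmax(i, 1L), n)
  img[, clampi(i0 - 1)] * rep(w1, each = nrow(img)) +
    img[, clampi(i0)] * rep(w2, each = nrow(img)) +
    img[, clampi(i0 + 1)] * rep(w3, each = nrow(img)) +
    img[, clampi(i0 + 2)] * rep(w4, each = nrow(img))
}

# Gaussian blur of a matrix, sigma in pixels; thin wrapper over EBImage.
gblur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # EBImage's kernel must fit inside the image; cap sigma accordingly
  sigma <- min(sigma, (min(dim(m)) - 1) / 7)
  if (sigma <= 0) return(m)
  # replicate boundary keeps the blur local to the window it is computed
  # on (a circular wrap would leak the opposite border in)
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}
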