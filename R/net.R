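# Minimal trainable convolutional regressor for paired image restoration.
#
# Layout convention: activations are 4-D arrays [H, W, C, N]. A convolution
# is evaluated as a sum over kernel offsets of shifted-input GEMMs
# (Y = sum_o shift_o(X) %*% W_o + b), which keeps every hot loop inside
# BLAS. Zero padding at the borders; gradients are exact.

.conv_cache <- new.env(parent = emptyenv())

# per-(H, W, N) gather tables for a 3x3 same-padded convolution expressed as
# im2col + one GEMM. `pad_rows` scatters the (H*W*N) x C activation matrix
# into the zero-padded layout; `colidx` gathers the 9 neighbour rows of
# every output pixel (column-major layout: offset varies fastest within a
# channel, matching `matrix(w, 9 * Cin, Cout)`).
conv_meta <- function(H, W, N) {
  key <- paste(H, W, N, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  h <- rep.int(seq_len(H), W)
  w_ <- rep(seq_len(W), each = H)
  base0 <- (h + 1L) + w_ * Hp            # padded row of (h, w), sample 1
  blocks <- (0:(N - 1)) * (Hp * Wp)
  pad_rows <- as.vector(outer(base0, blocks, `+`))
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  colidx <- matrix(0L, H * W * N, 9L)
  for (o in seq_len(9L)) {
    colidx[, o] <- pad_rows + offs$dy[o] + offs$dx[o] * Hp
  }
  meta <- list(H = H, W = W, N = N, n_pad = Hp * Wp * N,
               pad_rows = pad_rows, gather = as.vector(colidx))
  .conv_cache[[key]] <- meta
  meta
}

to_mat <- function(X) {
  d <- dim(X)  # H W C N
  m <- aperm(X, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

from_mat <- function(M, H, W, C, N) {
  dim(M) <- c(H, W, N, C)
  aperm(M, c(1, 2, 4, 3))
}

# im2col: (H*W*N) x C -> (H*W*N) x 9C with zero padding at borders
im2col3 <- function(M, meta) {
  C <- ncol(M)
  n <- nrow(M)
  Xp <- matrix(0, meta$n_pad, C)
  Xp[meta$pad_rows, ] <- M
  G <- Xp[meta$gather, , drop = FALSE]
  dim(G) <- c(n, 9L * C)
  G
}

conv3_fwd <- function(M, w, b, meta) {
  d <- dim(w)  # 9, Cin, Cout
  G <- im2col3(M, meta)
  wm <- w
  dim(wm) <- c(9L * d[2], d[3])
  Y <- G %*% wm
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, G = G)
}

conv3_bwd <- function(dY, w, G, meta) {
  d <- dim(w)
  dw <- array(crossprod(G, dY), dim = d)
  # input gradient = convolution of dY with the flipped, transposed kernel
  wf <- aperm(w[9:1, , , drop = FALSE], c(1, 3, 2))  # (9, Cout, Cin)
  dim(wf) <- c(9L * d[3], d[2])
  dM <- im2col3(dY, meta) %*% wf
  list(dM = dM, dw = dw, db = colSums(dY))
}

relu <- function(x) x * (x > 0)

pool2 <- function(X) {
  d <- dim(X)
  (X[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
     X[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
     X[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
     X[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]) / 4
}

pool2_bwd <- function(dP, H, W) {
  up2(dP) / 4
}

up2 <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

up2_bwd <- function(dU) {
  pool2(dU) * 4
}

he_init <- function(k2, cin, cout) {
  array(stats::rnorm(k2 * cin * cout, sd = sqrt(2 / (k2 * cin))),
        dim = c(k2, cin, cout))
}

net_init <- function(base = 8L, seed = 1L, cin = 1L, residual = FALSE) {
  p <- with_seed(seed, {
    list(
      c1 = list(w = he_init(9, cin, base), b = numeric(base)),
      c2 = list(w = he_init(9, base, base), b = numeric(base)),
      c3 = list(w = he_init(9, base, 2 * base), b = numeric(2 * base)),
      c4 = list(w = he_init(9, 2 * base, 2 * base), b = numeric(2 * base)),
      c4b = list(w = he_init(9, 2 * base, 2 * base), b = numeric(2 * base)),
      c4c = list(w = he_init(9, 2 * base, 2 * base), b = numeric(2 * base)),
      c5 = list(w = he_init(9, 3 * base, base), b = numeric(base)),
      c6 = list(w = matrix(stats::rnorm(base, sd = sqrt(2 / base)), base, 1),
                b = 0)
    )
  })
  attr(p, "residual") <- residual
  p
}

# Forward pass; returns prediction and (optionally) the cache for backprop.
net_fwd <- function(params, X, keep = FALSE) {
  d <- dim(X)  # H W 1 N
  H <- d[1]; W <- d[2]; N <- d[4]
  check(H %% 2 == 0 && W %% 2 == 0, "activations must have even height/width")
  mF <- conv_meta(H, W, N)
  mH <- conv_meta(H / 2, W / 2, N)
  m0 <- to_mat(X)
  f1 <- conv3_fwd(m0, params$c1$w, params$c1$b, mF); a1 <- relu(f1$Y)
  f2 <- conv3_fwd(a1, params$c2$w, params$c2$b, mF); a2 <- relu(f2$Y)
  A2 <- from_mat(a2, H, W, ncol(a2), N)
  P <- pool2(A2)
  mp <- to_mat(P)
  f3 <- conv3_fwd(mp, params$c3$w, params$c3$b, mH); a3 <- relu(f3$Y)
  f4 <- conv3_fwd(a3, params$c4$w, params$c4$b, mH); a4 <- relu(f4$Y)
  f4b <- conv3_fwd(a4, params$c4b$w, params$c4b$b, mH); a4b <- relu(f4b$Y)
  f4c <- conv3_fwd(a4b, params$c4c$w, params$c4c$b, mH); a4 <- relu(f4c$Y)
  A4 <- from_mat(a4, H / 2, W / 2, ncol(a4), N)
  U <- up2(A4)
  mu <- to_mat(U)
  mc <- cbind(a2, mu)
  f5 <- conv3_fwd(mc, params$c5$w, params$c5$b, mF); a5 <- relu(f5$Y)
  r <- a5 %*% params$c6$w
  r <- r + params$c6$b
  pred <- from_mat(r, H, W, 1, N)
  if (isTRUE(attr(params, "residual"))) {
    pred <- pred + X[, , 1, , drop = FALSE]
  }
  if (!keep) return(pred)
  list(pred = pred, z1 = f1$Y, G1 = f1$G, z2 = f2$Y, G2 = f2$G,
       z3 = f3$Y, G3 = f3$G, z4 = f4$Y, G4 = f4$G,
       z4b = f4b$Y, G4b = f4b$G, z4c = f4c$Y, G4c = f4c$G,
       z5 = f5$Y, G5 = f5$G,
       a5 = a5, H = H, W = W, N = N, mF = mF, mH = mH)
}

net_bwd <- function(params, cache, dPred) {
  H <- cache$H; W <- cache$W; N <- cache$N
  dr <- to_mat(dPred)                      # residual head: dL/dr = dL/dpred
  g6w <- crossprod(cache$a5, dr)
  g6b <- sum(dr)
  da5 <- dr %*% t(params$c6$w)
  dz5 <- da5 * (cache$z5 > 0)
  b5 <- conv3_bwd(dz5, params$c5$w, cache$G5, cache$mF)
  base <- dim(params$c2$w)[3]
  da2_skip <- b5$dM[, seq_len(base), drop = FALSE]
  dmu <- b5$dM[, base + seq_len(2 * base), drop = FALSE]
  dU <- from_mat(dmu, H, W, 2 * base, N)
  dA4 <- up2_bwd(dU)
  dz4c <- to_mat(dA4) * (cache$z4c > 0)
  b4c <- conv3_bwd(dz4c, params$c4c$w, cache$G4c, cache$mH)
  dz4b <- b4c$dM * (cache$z4b > 0)
  b4b <- conv3_bwd(dz4b, params$c4b$w, cache$G4b, cache$mH)
  dz4 <- b4b$dM * (cache$z4 > 0)
  b4 <- conv3_bwd(dz4, params$c4$w, cache$G4, cache$mH)
  dz3 <- b4$dM * (cache$z3 > 0)
  b3 <- conv3_bwd(dz3, params$c3$w, cache$G3, cache$mH)
  dP <- from_mat(b3$dM, H / 2, W / 2, base, N)
  dA2 <- pool2_bwd(dP, H, W)
  da2 <- to_mat(dA2) + da2_skip
  dz2 <- da2 * (cache$z2 > 0)
  b2 <- conv3_bwd(dz2, params$c2$w, cache$G2, cache$mF)
  dz1 <- b2$dM * (cache$z1 > 0)
  b1 <- conv3_bwd(dz1, params$c1$w, cache$G1, cache$mF)
  list(c1 = list(w = b1$dw, b = b1$db), c2 = list(w = b2$dw, b = b2$db),
       c3 = list(w = b3$dw, b = b3$db), c4 = list(w = b4$dw, b = b4$db),
       c4b = list(w = b4b$dw, b = b4b$db), c4c = list(w = b4c$dw, b = b4c$db),
       c5 = list(w = b5$dw, b = b5$db), c6 = list(w = g6w, b = g6b))
}

adam_init <- function(params) {
  lapply(params, function(layer) lapply(layer, function(x)
    list(m = x * 0, v = x * 0)))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in names(params)) {
    for (p in names(params[[l]])) {
      g <- grads[[l]][[p]]
      st <- state[[l]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[l]][[p]] <- params[[l]][[p]] - lr * mh / (sqrt(vh) + eps)
      state[[l]][[p]] <- st
    }
  }
  list(params = params, state = state)
}

# multi-scale input features: the raw image plus Gaussian-blurred copies,
# which hand the network pre-aggregated photon counts at several scales —
# valuable when the raw input carries ~1 photon per pixel.
net_input <- function(img, sigmas) {
  if (length(sigmas) == 0) {
    return(array(img, dim = c(dim(img), 1)))
  }
  ch <- c(list(img), lapply(sigmas, function(s) gblur_mat(img, s)))
  array(unlist(ch, use.names = FALSE), dim = c(dim(img), length(ch)))
}

# stack a list of matrices (or H x W x C arrays) into an [H, W, C, N] batch
stack_batch <- function(imgs) {
  d1 <- dim(imgs[[1]])
  C <- if (length(d1) == 3) d1[3] else 1L
  array(unlist(imgs, use.names = FALSE), dim = c(d1[1], d1[2], C, length(imgs)))
}

net_eval_metrics <- function(params, patches, sigmas, batch = 16L,
                             ssim_cap = 128L) {
  n <- length(patches)
  se <- 0; ae <- 0; npx <- 0
  ssims <- numeric(0)
  i <- 1L
  while (i <= n) {
    ids <- i:min(n, i + batch - 1L)
    X <- stack_batch(lapply(patches[ids], function(p)
      net_input(p$input, sigmas)))
    Y <- stack_batch(lapply(patches[ids], `[[`, "gt"))
    P <- net_fwd(params, X)
    se <- se + sum((P - Y)^2)
    ae <- ae + sum(abs(P - Y))
    npx <- npx + length(Y)
    for (j in seq_along(ids)) {
      if (length(ssims) < ssim_cap) {
        ssims <- c(ssims, ssim(P[, , 1, j], Y[, , 1, j], data_range = 1))
      }
    }
    i <- i + batch
  }
  c(mse = se / npx, mae = ae / npx, ssim = mean(ssims))
}

#' Train the paired low/high-SNR image restorer
#'
#' Trains a small two-scale convolutional encoder-decoder (3x3 convolutions,
#' 2x2 mean pool, nearest-neighbour upsampling with a skip connection, and a
#' residual output head) to regress high-SNR ground-truth patches from
#' low-SNR input patches, minimizing mean-square error with Adam. Both input
#' accumulation levels are pooled into one model. Training is deterministic
#' under a fixed seed up to floating-point reduction order.
#'
#' Patches are expected on the normalized intensity scale (see
#' [normalize_percentile()]); [prepare_restoration_data()] produces them.
#'
#' Model selection keeps the weights of the epoch with the best validation
#' SSIM: with a noisy acquired ground truth, prolonged MSE training starts
#' reproducing the ground truth's noise texture, which keeps lowering the
#' MSE while degrading structural similarity.
#'
#' @param train,val lists of `list(input, gt)` normalized patch pairs.
#' @param config a [restoration_config()].
#' @return object of class `restorer`: selected weights (`params`), config,
#'   a per-epoch history data.frame (`epoch`, `train_mse`, `val_mse`,
#'   `val_mae`, `val_ssim`), the selected `best_epoch`, and the last-epoch
#'   weights (`final_params`).
#' @export
train_restorer <- function(train, val, config = restoration_config()) {
  stopifnot(inherits(config, "restoration_config"))
  check(length(train) >= 1 && length(val) >= 1, "empty train or validation set")
  sigmas <- config$input_sigmas
  params <- net_init(config$base_features, seed = config$seed,
                     cin = 1L + length(sigmas),
                     residual = isTRUE(config$residual))
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(0), train_mse = numeric(0),
                     val_mse = numeric(0), val_mae = numeric(0),
                     val_ssim = numeric(0))
  best <- list(ssim = -Inf, params = params, epoch = 0L)
  t_step <- 0L
  with_seed(derive_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      lr_ep <- config$learning_rate * config$lr_decay^(ep - 1)
      for (s in seq_len(config$steps_per_epoch)) {
        ids <- sample.int(length(train), config$batch_size, replace = TRUE)
        # geometric augmentation: random flips/transposition per patch
        aug <- matrix(stats::runif(3 * length(ids)) < 0.5, ncol = 3)
        pick <- lapply(seq_along(ids), function(j) {
          p <- train[[ids[j]]]
          a <- p$input; b <- p$gt
          if (isTRUE(config$augment)) {
            if (aug[j, 1]) { a <- a[nrow(a):1, ]; b <- b[nrow(b):1, ] }
            if (aug[j, 2]) { a <- a[, ncol(a):1]; b <- b[, ncol(b):1] }
            if (aug[j, 3] && nrow(a) == ncol(a)) { a <- t(a); b <- t(b) }
          }
          list(input = a, gt = b)
        })
        X <- stack_batch(lapply(pick, function(p) net_input(p$input, sigmas)))
        Y <- stack_batch(lapply(pick, `[[`, "gt"))
        cache <- net_fwd(params, X, keep = TRUE)
        diff <- cache$pred - Y
        ep_loss <- ep_loss + mean(diff^2)
        grads <- net_bwd(params, cache, 2 * diff / length(diff))
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, lr_ep, t_step)
        params <- upd$params; state <- upd$state
      }
      vm <- net_eval_metrics(params, val, sigmas)
      if (!all(is.finite(vm))) {
        stop("training diverged: validation loss is not finite at epoch ", ep)
      }
      if (vm[["ssim"]] > best$ssim) {
        best <- list(ssim = vm[["ssim"]], params = params, epoch = ep)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, train_mse = ep_loss / config$steps_per_epoch,
        val_mse = vm[["mse"]], val_mae = vm[["mae"]],
        val_ssim = vm[["ssim"]]))
    }
  })
  # model selection: keep the epoch with the best validation SSIM (the
  # study's quality metric); late epochs can overfit the noisy ground
  # truth's texture while still lowering the MSE
  structure(list(params = best$params, config = config, history = hist,
                 best_epoch = best$epoch, final_params = params),
            class = "restorer")
}

#' @export
print.restorer <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "Restorer: %d base features, trained %d epochs x %d steps\n  selected epoch %d (val SSIM %.3f); final val MSE %.4g, MAE %.4g\n",
    x$config$base_features, nrow(h), x$config$steps_per_epoch,
    x$best_epoch, max(h$val_ssim),
    h$val_mse[nrow(h)], h$val_mae[nrow(h)]))
  invisible(x)
}

#' @export
summary.restorer <- function(object, ...) {
  print(object)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.restorer <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_mse, type = "l", xlab = "epoch",
                 ylab = "MSE", log = "y", ...)
  graphics::lines(h$epoch, h$train_mse, lty = 2)
  graphics::legend("topright", c("validation", "training"), lty = c(1, 2))
  invisible(h)
}

#' Restore an image with a trained model
#'
#' Tiled inference: the image is processed in overlapping tiles, a margin of
#' each interior tile edge (wider than the network's receptive field) is
#' trimmed, and the kept regions are blended with weights normalized to sum
#' to one at every pixel, so tiling introduces no seams: tiled and whole-
#' image inference agree to floating-point precision.
#'
#' @param model a trained [train_restorer()] object.
#' @param image numeric matrix (counts or normalized intensities).
#' @param tile_px tile side used for inference.
#' @param tile_overlap_px overlap between neighbouring tiles; `NULL` uses
#'   twice the trim margin.
#' @param normalize normalize the input by the model's percentiles first
#'   (output stays on the normalized scale, as the model was trained).
#' @return restored matrix, same shape as the input.
#' @export
restore_image <- function(model, image, tile_px = 128L,
                          tile_overlap_px = NULL, normalize = TRUE) {
  stopifnot(inherits(model, "restorer"))
  if (normalize) {
    image <- normalize_percentile(image, model$config$p_low,
                                  model$config$p_high)$image
  }
  H <- nrow(image); W <- ncol(image)
  # trim margin: the network's receptive-field radius (~14 px) plus the
  # kernel radius of the widest blurred input channel
  sig_max <- if (length(model$config$input_sigmas)) {
    max(model$config$input_sigmas)
  } else 0
  margin <- 16L + as.integer(ceiling(3 * sig_max))
  sigmas <- model$config$input_sigmas
  run <- function(img) {
    d <- dim(img)
    padH <- d[1] %% 2; padW <- d[2] %% 2
    if (padH || padW) {
      img <- rbind(img, if (padH) img[d[1], , drop = FALSE])
      img <- cbind(img, if (padW) img[, ncol(img), drop = FALSE])
    }
    X <- net_input(img, sigmas)
    dim(X) <- c(dim(X), 1L)
    out <- net_fwd(model$params, X)[, , 1, 1]
    out[seq_len(d[1]), seq_len(d[2])]
  }
  if (H <= tile_px && W <= tile_px) return(run(image))
  if (is.null(tile_overlap_px)) tile_overlap_px <- 2L * margin
  check(tile_overlap_px >= 2L * margin,
        "tile_overlap_px must be at least twice the trim margin")
  check(tile_px > tile_overlap_px, "tile_px must exceed the overlap")
  starts <- function(n) {
    if (n <= tile_px) return(1L)
    s <- seq(1L, n - tile_px + 1L, by = tile_px - tile_overlap_px)
    s <- unique(c(s, n - tile_px + 1L))
    # odd starts keep the 2x2 pooling grid aligned with whole-image
    # inference; shifting left only increases overlap
    as.integer(ifelse(s %% 2L == 0L, s - 1L, s))
  }
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rT <- min(tile_px, H); cT <- min(tile_px, W)
      ri <- r0 + seq_len(rT) - 1L
      ci <- c0 + seq_len(cT) - 1L
      tile <- run(image[ri, ci, drop = FALSE])
      keep_r <- seq_len(rT)
      keep_c <- seq_len(cT)
      if (r0 > 1) keep_r <- keep_r[-seq_len(margin)]
      if (max(ri) < H) keep_r <- keep_r[seq_len(length(keep_r) - margin)]
      if (c0 > 1) keep_c <- keep_c[-seq_len(margin)]
      if (max(ci) < W) keep_c <- keep_c[seq_len(length(keep_c) - margin)]
      acc[ri[keep_r], ci[keep_c]] <- acc[ri[keep_r], ci[keep_c]] +
        tile[keep_r, keep_c]
      wacc[ri[keep_r], ci[keep_c]] <- wacc[ri[keep_r], ci[keep_c]] + 1
    }
  }
  check(all(wacc > 0), "internal: tiling left uncovered pixels")
  acc / wacc
}

#' @export
predict.restorer <- function(object, newdata, ...) {
  restore_image(object, newdata, ...)
}
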