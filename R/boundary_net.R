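# 2D UNet boundary-confidence predictor, implemented from scratch on base
# matrix operations (im2col convolutions, manual backprop, Adam). The
# architecture is a configurable-depth encoder/decoder with skip
# connections; the default used for synthetic training is deliberately
# small so that CPU training on phantom crops converges in minutes.
# A classical fallback predictor (gradient magnitude + ridge response) is
# provided behind the same interface so the downstream pipeline is testable
# without training.

#' Training configuration for the boundary UNet
#'
#' @param crop_size square crop side in pixels (the original protocol used
#'   448 px corner crops of 900 px slices).
#' @param target_train_size augmented training-set size (crops are
#'   replicated `target_train_size / n_base` times with random rotation,
#'   shift, shear-like flips and zoom).
#' @param val_fraction fraction held out for validation (0.2).
#' @param loss_threshold training stops once the epoch training BCE falls
#'   below this (0.001 in the original recipe).
#' @param max_epochs epoch cap.
#' @param dropout_rate dropout probability on encoder features.
#' @param lr Adam learning rate.
#' @param base_channels channels of the first encoder level.
#' @param depth number of encoder levels (>= 1).
#' @param batch_size minibatch size.
#' @param rng_seed integer seed controlling augmentation, split, init and
#'   batching.
#' @return a `training_config` list.
#' @export
training_config <- function(crop_size = 448L, target_train_size = 4960L,
                            val_fraction = 0.2, loss_threshold = 0.001,
                            max_epochs = 30L, dropout_rate = 0.1,
                            lr = 5e-3, base_channels = 8L, depth = 2L,
                            batch_size = 8L, rng_seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, crop_size >= 8,
            max_epochs >= 0, depth >= 1)
  structure(as.list(environment()), class = "training_config")
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y*log(p) + (1-y)*log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]`.
#'
#' @param y 0/1 targets.
#' @param yhat predicted probabilities, same shape.
#' @param eps clamp value.
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stop("shape mismatch between y and yhat")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- augmentation helpers (k*90 deg rotations, flips, integer shifts, zoom)
rot90m <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

shift2d <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)) - dy
  xs <- seq_len(ncol(m)) - dx
  ok_y <- ys >= 1 & ys <= nrow(m)
  ok_x <- xs >= 1 & xs <= ncol(m)
  out[which(ok_y), which(ok_x)] <- m[ys[ok_y], xs[ok_x]]
  out
}

zoom2d <- function(m, factor) {
  # nearest-neighbour resample about the centre, same output size
  n <- nrow(m); p <- ncol(m)
  yi <- pmin(pmax(round((seq_len(n) - n / 2) / factor + n / 2), 1), n)
  xi <- pmin(pmax(round((seq_len(p) - p / 2) / factor + p / 2), 1), p)
  m[yi, xi, drop = FALSE]
}

augment_pair <- function(img, mask) {
  k <- sample(0:3, 1)
  img <- rot90m(img, k); mask <- rot90m(mask, k)
  if (runif(1) < 0.5) { img <- img[nrow(img):1, ]; mask <- mask[nrow(mask):1, ] }
  dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
  img <- shift2d(img, dy, dx); mask <- shift2d(mask, dy, dx)
  if (runif(1) < 0.3) {
    f <- runif(1, 0.9, 1.1)
    img <- zoom2d(img, f); mask <- zoom2d(mask, f)
  }
  list(image = img, mask = mask)
}

#' Prepare the training and validation sets
#'
#' Crops each annotated image into the four `crop_size` corner crops,
#' normalises by dividing by 255 and subtracting the per-crop mean, then
#' augments the base crops up to `target_train_size` and splits
#' deterministically into train/validation.
#'
#' @param images list of 2D image matrices (8-bit scale).
#' @param masks list of matching 0/1 boundary masks.
#' @param cfg a [training_config()].
#' @return list with `train` and `val`, each a list of
#'   `list(image, mask)` pairs (images normalised, masks 0/1).
#' @export
prepare_training_set <- function(images, masks, cfg) {
  stopifnot(length(images) >= 1L, length(images) == length(masks))
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == dim(masks[[i]]))) {
      stop("image/mask shape mismatch at item ", i)
    }
    if (any(dim(images[[i]]) < cfg$crop_size)) {
      stop("crop_size exceeds image size at item ", i)
    }
  }
  cs <- cfg$crop_size
  base <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]; mk <- masks[[i]]
    ny <- nrow(im); nx <- ncol(im)
    corners <- list(c(1L, 1L), c(1L, nx - cs + 1L),
                    c(ny - cs + 1L, 1L), c(ny - cs + 1L, nx - cs + 1L))
    for (cn in corners) {
      ys <- cn[1L]:(cn[1L] + cs - 1L); xs <- cn[2L]:(cn[2L] + cs - 1L)
      base[[length(base) + 1L]] <- list(image = im[ys, xs],
                                        mask = (mk[ys, xs] > 0) * 1)
    }
  }
  with_seed(cfg$rng_seed, {
    n_target <- max(cfg$target_train_size, length(base))
    aug <- vector("list", n_target)
    for (j in seq_len(n_target)) {
      src <- base[[((j - 1L) %% length(base)) + 1L]]
      pr <- if (j <= length(base)) src else augment_pair(src$image, src$mask)
      img <- pr$image / 255
      img <- img - mean(img)
      aug[[j]] <- list(image = img, mask = pr$mask)
    }
    perm <- sample.int(n_target)
    n_val <- round(cfg$val_fraction * n_target)
    list(val = aug[perm[seq_len(n_val)]],
         train = aug[perm[(n_val + 1L):n_target]])
  })
}

# --- minimal conv net machinery --------------------------------------------
# Feature maps are (H*W) x C matrices; im2col gives (H*W) x (9*C) patch
# matrices so a 3x3 convolution is a single matrix multiply.

im2col3 <- function(feat, H, W) {
  C <- ncol(feat)
  out <- matrix(0, H * W, 9L * C)
  col <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    # shifted copy with zero padding; feat rows indexed y + H*(x-1)
    sh <- matrix(0, H * W, C)
    ys <- seq_len(H) - dy
    xs <- seq_len(W) - dx
    ok_y <- ys >= 1 & ys <= H
    ok_x <- xs >= 1 & xs <= W
    dst <- as.vector(outer(which(ok_y), (which(ok_x) - 1L) * H, "+"))
    src <- as.vector(outer(ys[ok_y], (xs[ok_x] - 1L) * H, "+"))
    sh[dst, ] <- feat[src, , drop = FALSE]
    out[, (col * C + 1L):((col + 1L) * C)] <- sh
    col <- col + 1L
  }
  out
}

col2im3 <- function(grad_cols, H, W, C) {
  # adjoint of im2col3: scatter-add the 9 shifted blocks back
  out <- matrix(0, H * W, C)
  col <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    blk <- grad_cols[, (col * C + 1L):((col + 1L) * C), drop = FALSE]
    ys <- seq_len(H) - dy
    xs <- seq_len(W) - dx
    ok_y <- ys >= 1 & ys <= H
    ok_x <- xs >= 1 & xs <= W
    dst <- as.vector(outer(which(ok_y), (which(ok_x) - 1L) * H, "+"))
    src <- as.vector(outer(ys[ok_y], (xs[ok_x] - 1L) * H, "+"))
    out[src, ] <- out[src, ] + blk[dst, , drop = FALSE]
    col <- col + 1L
  }
  out
}

pool2 <- function(feat, H, W) {
  # 2x2 mean pooling; returns (H/2*W/2) x C
  C <- ncol(feat)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  a <- array(feat, dim = c(H, W, C))
  a <- (a[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
        a[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
        a[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE] +
        a[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE]) / 4
  matrix(a, H2 * W2, C)
}

unpool2 <- function(feat, H2, W2) {
  # nearest-neighbour 2x upsampling; adjoint of itself up to the 1/4 factor
  C <- ncol(feat)
  a <- array(feat, dim = c(H2, W2, C))
  idx_y <- rep(seq_len(H2), each = 2L)
  idx_x <- rep(seq_len(W2), each = 2L)
  matrix(a[idx_y, idx_x, , drop = FALSE], 4L * H2 * W2, C)
}

pool2_back <- function(grad, H, W) {
  C <- ncol(grad)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  up <- unpool2(grad, H2, W2) / 4
  # embed into full H x W if odd sizes (not used: sizes kept even)
  up
}

unpool2_back <- function(grad, H2, W2) {
  C <- ncol(grad)
  a <- array(grad, dim = c(2L * H2, 2L * W2, C))
  s <- a[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
       a[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , drop = FALSE] +
       a[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE] +
       a[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , drop = FALSE]
  matrix(s, H2 * W2, C)
}

init_weights <- function(cfg) {
  c0 <- cfg$base_channels
  he <- function(fan_in, n_out) {
    matrix(rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
  }
  list(
    enc1_W = he(9L * 1L, c0), enc1_b = rep(0, c0),
    enc2_W = he(9L * c0, 2L * c0), enc2_b = rep(0, 2L * c0),
    dec1_W = he(9L * 3L * c0, c0), dec1_b = rep(0, c0),
    out_W = he(c0, 1L), out_b = 0
  )
}

# forward pass for one image; returns activations for backprop
net_forward <- function(w, img, H, W, dropout_rate = 0, training = FALSE) {
  x0 <- matrix(as.vector(img), H * W, 1L)
  c1_cols <- im2col3(x0, H, W)
  a1 <- c1_cols %*% w$enc1_W
  a1 <- sweep(a1, 2L, w$enc1_b, "+")
  r1 <- pmax(a1, 0)
  drop_mask <- NULL
  if (training && dropout_rate > 0) {
    drop_mask <- matrix(rbinom(length(r1), 1, 1 - dropout_rate),
                        nrow(r1), ncol(r1)) / (1 - dropout_rate)
    r1 <- r1 * drop_mask
  }
  p1 <- pool2(r1, H, W)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  c2_cols <- im2col3(p1, H2, W2)
  a2 <- sweep(c2_cols %*% w$enc2_W, 2L, w$enc2_b, "+")
  r2 <- pmax(a2, 0)
  u2 <- unpool2(r2, H2, W2)
  cat12 <- cbind(r1, u2)
  d1_cols <- im2col3(cat12, H, W)
  a3 <- sweep(d1_cols %*% w$dec1_W, 2L, w$dec1_b, "+")
  r3 <- pmax(a3, 0)
  logit <- as.vector(r3 %*% w$out_W) + w$out_b
  p <- 1 / (1 + exp(-logit))
  list(x0 = x0, c1_cols = c1_cols, a1 = a1, r1 = r1, p1 = p1,
       c2_cols = c2_cols, a2 = a2, r2 = r2, u2 = u2, cat12 = cat12,
       d1_cols = d1_cols, a3 = a3, r3 = r3, p = p, H = H, W = W,
       drop_mask = drop_mask)
}

net_backward <- function(w, fw, y) {
  n <- length(fw$p)
  H <- fw$H; W <- fw$W
  H2 <- H %/% 2L; W2 <- W %/% 2L
  c0 <- length(w$enc1_b)
  dlogit <- (fw$p - y) / n                       # BCE + sigmoid
  g_outW <- t(fw$r3) %*% dlogit
  g_outb <- sum(dlogit)
  dr3 <- dlogit %*% t(w$out_W)
  da3 <- dr3 * (fw$a3 > 0)
  g_dec1W <- t(fw$d1_cols) %*% da3
  g_dec1b <- colSums(da3)
  dcat_cols <- da3 %*% t(w$dec1_W)
  dcat <- col2im3(dcat_cols, H, W, 3L * c0)
  dr1_skip <- dcat[, seq_len(c0), drop = FALSE]
  du2 <- dcat[, c0 + seq_len(2L * c0), drop = FALSE]
  dr2 <- unpool2_back(du2, H2, W2)
  da2 <- dr2 * (fw$a2 > 0)
  g_enc2W <- t(fw$c2_cols) %*% da2
  g_enc2b <- colSums(da2)
  dp1_cols <- da2 %*% t(w$enc2_W)
  dp1 <- col2im3(dp1_cols, H2, W2, c0)
  dr1_pool <- pool2_back(dp1, H, W)
  dr1 <- dr1_skip + dr1_pool
  if (!is.null(fw$drop_mask)) dr1 <- dr1 * fw$drop_mask
  da1 <- dr1 * (fw$a1 > 0)
  g_enc1W <- t(fw$c1_cols) %*% da1
  g_enc1b <- colSums(da1)
  list(enc1_W = g_enc1W, enc1_b = g_enc1b, enc2_W = g_enc2W,
       enc2_b = g_enc2b, dec1_W = g_dec1W, dec1_b = g_dec1b,
       out_W = g_outW, out_b = g_outb)
}

#' Train the boundary UNet
#'
#' Minibatch Adam on binary cross-entropy. Training stops when the epoch
#' mean training loss drops below `cfg$loss_threshold` or after
#' `cfg$max_epochs` epochs; validation loss is logged each epoch but not
#' used for stopping. With `max_epochs = 0` an untrained (randomly
#' initialised) model is returned, flagged as such.
#'
#' @param cfg a [training_config()].
#' @param train,val lists of `list(image, mask)` pairs from
#'   [prepare_training_set()].
#' @return a `boundary_model` with weights, config and loss history.
#' @export
train_boundary_net <- function(cfg, train, val = list()) {
  stopifnot(inherits(cfg, "training_config"), length(train) >= 1L)
  H <- nrow(train[[1L]]$image); W <- ncol(train[[1L]]$image)
  if (H %% 2L || W %% 2L) stop("crop sides must be even")
  with_seed(cfg$rng_seed + 1L, {
    w <- init_weights(cfg)
    m <- lapply(w, function(x) x * 0)
    v <- lapply(w, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    hist_train <- numeric(0)
    hist_val <- numeric(0)
    epoch <- 0L
    while (epoch < cfg$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample.int(length(train))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        grads <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- net_forward(w, train[[i]]$image, H, W,
                            dropout_rate = cfg$dropout_rate, training = TRUE)
          y <- as.vector(train[[i]]$mask)
          bloss <- bloss + bce_loss(y, fw$p)
          g <- net_backward(w, fw, y)
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        bloss <- bloss / length(idx)
        if (!is.finite(bloss)) {
          stop(sprintf("training diverged (loss is not finite) at epoch %d", epoch))
        }
        step <- step + 1L
        for (nm in names(w)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          w[[nm]] <- w[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + bloss
        nb <- nb + 1L
      }
      hist_train <- c(hist_train, ep_loss / nb)
      if (length(val) > 0) {
        vl <- mean(vapply(val, function(pr) {
          fw <- net_forward(w, pr$image, H, W)
          bce_loss(as.vector(pr$mask), fw$p)
        }, 1))
        hist_val <- c(hist_val, vl)
      }
      if (hist_train[length(hist_train)] < cfg$loss_threshold) break
    }
    structure(list(weights = w, config = cfg, input_size = c(H, W),
                   train_loss = hist_train, val_loss = hist_val,
                   trained = cfg$max_epochs > 0L),
              class = "boundary_model")
  })
}

#' Predict a 3D boundary-confidence volume
#'
#' Runs the trained 2D network slice by slice on the CK7 channel and
#' assembles a 3D confidence volume in `[0, 1]`. Slices larger than the
#' network input are tiled with 32-px overlap and linear blending.
#'
#' @param model a `boundary_model` from [train_boundary_net()].
#' @param stack an [image_stack()].
#' @param channel channel role to use (default CK7).
#' @return 3D array of boundary confidence, same shape as the stack.
#' @export
predict_boundaries <- function(model, stack, channel = "CK7") {
  stopifnot(inherits(model, "boundary_model"))
  if (!isTRUE(model$trained)) stop("model is untrained (max_epochs was 0)")
  a <- get_channel(stack, channel)
  d <- dim(a)
  out <- array(0, dim = d)
  for (z in seq_len(d[1L])) {
    out[z, , ] <- predict_slice(model, matrix(a[z, , ], nrow = d[2L]))
  }
  out
}

predict_slice <- function(model, sl, overlap = 32L) {
  H <- model$input_size[1L]; W <- model$input_size[2L]
  ny <- nrow(sl); nx <- ncol(sl)
  norm_tile <- function(t0) {
    t0 <- t0 / 255
    t0 - mean(t0)
  }
  run <- function(t0) {
    fw <- net_forward(model$weights, norm_tile(t0), nrow(t0), ncol(t0))
    matrix(fw$p, nrow(t0), ncol(t0))
  }
  if (ny == H && nx == W) return(run(sl))
  acc <- matrix(0, ny, nx)
  wts <- matrix(0, ny, nx)
  ramp <- function(n, lo_edge, hi_edge) {
    w <- rep(1, n)
    if (lo_edge) w[seq_len(min(overlap, n))] <- seq(0.05, 1, length.out = min(overlap, n))
    if (hi_edge) w[n + 1L - seq_len(min(overlap, n))] <-
        seq(0.05, 1, length.out = min(overlap, n))
    w
  }
  ys <- tile_starts(ny, H, overlap)
  xs <- tile_starts(nx, W, overlap)
  for (y0 in ys) for (x0 in xs) {
    yy <- y0:min(y0 + H - 1L, ny)
    xx <- x0:min(x0 + W - 1L, nx)
    tile <- matrix(0, H, W)
    tile[seq_along(yy), seq_along(xx)] <- sl[yy, xx]
    p <- run(tile)[seq_along(yy), seq_along(xx), drop = FALSE]
    wy <- ramp(length(yy), y0 > 1L, max(yy) < ny)
    wx <- ramp(length(xx), x0 > 1L, max(xx) < nx)
    wm <- outer(wy, wx)
    acc[yy, xx] <- acc[yy, xx] + p * wm
    wts[yy, xx] <- wts[yy, xx] + wm
  }
  acc / pmax(wts, 1e-12)
}

tile_starts <- function(n, size, overlap) {
  if (size >= n) return(1L)
  st <- seq(1L, n - size + 1L, by = size - overlap)
  if (st[length(st)] + size - 1L < n) st <- c(st, n - size + 1L)
  unique(st)
}

#' Classical fallback boundary predictor
#'
#' Normalised gradient-magnitude ridge response of the CK7 channel,
#' smoothed and rescaled to `[0, 1]`. Exposes the same output contract as
#' [predict_boundaries()] so the downstream watershed can run without a
#' trained network.
#'
#' @param stack an [image_stack()].
#' @param channel channel role (default CK7).
#' @param smooth_um Gaussian pre-smoothing in micrometres.
#' @return 3D confidence array in `[0, 1]`.
#' @export
ridge_boundary_confidence <- function(stack, channel = "CK7", smooth_um = 0.3) {
  a <- get_channel(stack, channel)
  a <- gauss3d(a, stack$voxel_size, smooth_um)
  rng <- range(a)
  if (diff(rng) < 1e-12) return(array(0, dim = dim(a)))
  (a - rng[1L]) / diff(rng)
}
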