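# Independent reference implementations used as test oracles. Everything here
# is deliberately scalar/loop-based (or a direct eigendecomposition) so it
# shares no code path with the vectorized implementations under test.

# central-difference numerical gradient of a scalar function
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  dim(g) <- dim(x)
  g
}

# scalar-loop reference of the multi-scale token fusion equations
ref_mstd_fuse <- function(z1, z2) {
  n <- nrow(z1); D <- ncol(z1); h <- D / 2
  out <- matrix(0, n, D)
  A <- function(v) tanh(v) + 1
  for (i in seq_len(n)) {
    for (d in seq_len(h)) {
      z1a <- z1[i, d]; z1b <- z1[i, h + d]
      z2a <- z2[i, d]; z2b <- z2[i, h + d]
      f0 <- z1b + z2a
      F1 <- A(f0 * z1a) + z1a
      F2 <- A(f0 * z2b) + z2b
      F0 <- A(f0 * F1 * F2) + f0
      out[i, d] <- F0
      out[i, h + d] <- F1 + F2
    }
  }
  out
}

# scalar-loop reference of the cross-attention fusion gate
ref_caf <- function(F1, F2, Fp) {
  out <- F1
  for (i in seq_along(F1)) {
    s <- F1[i] * F2[i] + F1[i] * Fp[i] + F2[i] * Fp[i]
    out[i] <- tanh(s) + 1
  }
  out
}

# brute-force loop over the modulated deformable convolution definition:
# y(p) = sum_k w_k * x(p + p_k + dp_k(p)) * m_k(p), bilinear, zero outside
ref_deform_conv <- function(x, w, b, off, modl) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  kd <- dim(w); k <- kd[1]; cout <- kd[4]
  K <- k * k
  half <- (k - 1) %/% 2
  sample_bilinear <- function(c, sy, sx) {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    val <- 0
    for (cy in 0:1) for (cx in 0:1) {
      iy <- y0 + cy; ix <- x0 + cx
      wgt <- (if (cy == 0) 1 - fy else fy) * (if (cx == 0) 1 - fx else fx)
      if (iy >= 1 && iy <= H && ix >= 1 && ix <= W) {
        val <- val + wgt * x[iy, ix, c]
      }
    }
    val
  }
  out <- array(0, c(H, W, cout))
  for (i in seq_len(H)) for (j in seq_len(W)) for (o in seq_len(cout)) {
    acc <- b[o]
    kk <- 0
    for (kj in seq_len(k)) for (ki in seq_len(k)) {
      kk <- kk + 1
      dy <- off[i, j, kk]; dx <- off[i, j, K + kk]
      m <- modl[i, j, kk]
      sy <- i + (ki - 1 - half) + dy
      sx <- j + (kj - 1 - half) + dx
      for (c in seq_len(cin)) {
        acc <- acc + w[ki, kj, c, o] * sample_bilinear(c, sy, sx) * m
      }
    }
    out[i, j, o] <- acc
  }
  out
}

# plain zero-padded convolution by loops (for the zero-offset reduction check)
ref_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  d <- dim(x); kd <- dim(w)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  ho <- (dim(xp)[1] - kd[1]) %/% stride + 1
  wo <- (dim(xp)[2] - kd[2]) %/% stride + 1
  out <- array(0, c(ho, wo, kd[4]))
  for (i in seq_len(ho)) for (j in seq_len(wo)) for (o in seq_len(kd[4])) {
    acc <- b[o]
    for (ki in seq_len(kd[1])) for (kj in seq_len(kd[2])) for (c in seq_len(kd[3])) {
      acc <- acc + w[ki, kj, c, o] * xp[(i - 1) * stride + ki, (j - 1) * stride + kj, c]
    }
    out[i, j, o] <- acc
  }
  out
}

# PCA oracle: eigendecomposition of the pixel covariance matrix, sign fixed
# by largest-magnitude loading positive
ref_pca <- function(X, k) {
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen(S, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) V[, i] <- -V[, i]
  }
  list(rotation = V, evr = eig$values / sum(eig$values))
}

# pixel-loop confusion counts
ref_confusion <- function(pred, true, fg = 1) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == fg; t <- true[i] == fg
    if (p && t) tp <- tp + 1 else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1 else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, total = length(pred))
}

# small reusable model/data builders
tiny_model_config <- function(input_size = 32L, scale_pair = c(2L, 4L),
                              embed_dim = 16L) {
  model_config(in_channels = 3L, n_classes = 2L, input_size = input_size,
               cnn_widths = c(4L, 8L, 8L), scale_pair = scale_pair,
               embed_dim = embed_dim, n_heads = 2L,
               decoder_widths = c(8L, 8L, 8L, 4L))
}

tiny_dataset <- function(n, size = 32L, seed = 5L, contrast = 1, k = 3L) {
  cfg <- synth_config(height = size, width = size, lesion_smoothness = 6,
                      noise_sigma = 0.01, contrast = contrast, seed = seed)
  lapply(gen_dataset(n, cfg), function(it) {
    list(x = pca_reduce(it$cube, k)$data, y = it$mask$labels)
  })
}
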