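# Spatial tape ops on [H, W, C] feature maps: reflection padding, strided
# convolution (im2col), bilinear resampling, and modulated deformable
# convolution. All backward passes are hand-derived and checked against
# numerical gradients in the test suite.

# Reflection index into 1..n for positions 1-p .. n+p; the edge sample is not
# duplicated ("reflect", not "symmetric"). Valid for any p when n > 1.
reflect_index <- function(n, p) {
  if (n == 1L) return(rep(1L, n + 2L * p))
  t <- seq.int(1L - p, n + p)
  period <- 2L * (n - 1L)
  m <- (t - 1L) %% period
  ifelse(m < n, m + 1L, period - m + 1L)
}

# pad [H, W, C] by pr rows / pc cols per side, reflecting the interior
tn_pad_reflect <- function(x, pr, pc = pr) {
  xv <- x$v
  d <- dim(xv)
  ri <- reflect_index(d[1L], pr)
  ci <- reflect_index(d[2L], pc)
  y <- xv[ri, ci, , drop = FALSE]
  tn_op(y, list(x), function(g) {
    gx <- array(0, d)
    # scatter-add: accumulate duplicated source positions
    hw_out <- length(ri) * length(ci)
    src <- as.vector(outer(ri, ci, function(i, j) i + (j - 1L) * d[1L]))
    gm <- matrix(g, hw_out, d[3L])
    acc <- rowsum(gm, src)
    gxm <- matrix(gx, d[1L] * d[2L], d[3L])
    gxm[as.integer(rownames(acc)), ] <- acc
    dim(gxm) <- d
    list(gxm)
  })
}

pad_zero <- function(xv, p) {
  if (p == 0L) return(xv)
  d <- dim(xv)
  out <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  out[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), ] <- xv
  out
}

# weight array [kh, kw, Cin, Cout] -> im2col matrix [kh*kw*Cin, Cout] whose row
# order matches the column order built by conv loops below (c fastest, ki, kj)
conv_weight_mat <- function(w) {
  d <- dim(w)
  wm <- aperm(w, c(3L, 1L, 2L, 4L))
  dim(wm) <- c(d[1L] * d[2L] * d[3L], d[4L])
  wm
}

# x: [H, W, Cin]; w: [kh, kw, Cin, Cout]; zero padding p; stride s.
# Returns [Ho, Wo, Cout].
tn_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- x$v
  wv <- w$v
  d <- dim(xv)
  kd <- dim(wv)
  kh <- kd[1L]; kw <- kd[2L]; cin <- kd[3L]; cout <- kd[4L]
  stopifnot(d[3L] == cin)
  xp <- pad_zero(xv, pad)
  hp <- dim(xp)[1L]; wp <- dim(xp)[2L]
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  if (ho < 1L || wo < 1L) {
    stop(sprintf("conv2d: spatial dims (%d,%d) too small for kernel %d stride %d",
                 d[1L], d[2L], kh, stride))
  }
  rows <- lapply(seq_len(kh), function(ki) seq.int(ki, by = stride, length.out = ho))
  cols <- lapply(seq_len(kw), function(kj) seq.int(kj, by = stride, length.out = wo))
  M <- matrix(0, ho * wo, kh * kw * cin)
  blk <- 0L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      piece <- xp[rows[[ki]], cols[[kj]], , drop = FALSE]
      M[, blk + seq_len(cin)] <- matrix(piece, ho * wo, cin)
      blk <- blk + cin
    }
  }
  Wm <- conv_weight_mat(wv)
  Y <- M %*% Wm
  if (!is.null(b)) Y <- sweep(Y, 2L, b$v, "+")
  dim(Y) <- c(ho, wo, cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tn_op(Y, parents, function(g) {
    gm <- matrix(g, ho * wo, cout)
    dWm <- crossprod(M, gm)
    dW <- array(dWm, c(cin, kh, kw, cout))
    dW <- aperm(dW, c(2L, 3L, 1L, 4L))
    dM <- gm %*% t(Wm)
    gxp <- array(0, dim(xp))
    blk <- 0L
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        piece <- dM[, blk + seq_len(cin)]
        dim(piece) <- c(ho, wo, cin)
        gxp[rows[[ki]], cols[[kj]], ] <- gxp[rows[[ki]], cols[[kj]], , drop = FALSE] + piece
        blk <- blk + cin
      }
    }
    gx <- if (pad > 0L) {
      gxp[(pad + 1L):(pad + d[1L]), (pad + 1L):(pad + d[2L]), , drop = FALSE]
    } else gxp
    if (is.null(b)) list(gx, dW) else list(gx, dW, colSums(gm))
  })
}

# 1-D bilinear interpolation matrix from n -> m samples (align-corners false,
# edge clamped); resize is separable so 2-D resampling is Wr %*% X %*% t(Wc)
interp_matrix <- function(n, m) {
  W <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) * (n / m) + 0.5
  i0 <- floor(src)
  f <- src - i0
  i0c <- pmin(pmax(i0, 1L), n)
  i1c <- pmin(pmax(i0 + 1L, 1L), n)
  for (i in seq_len(m)) {
    W[i, i0c[i]] <- W[i, i0c[i]] + (1 - f[i])
    W[i, i1c[i]] <- W[i, i1c[i]] + f[i]
  }
  W
}

# bilinear resize of [H, W, C] to (ho, wo); used with ho = 2H for decoding
tn_upsample_bilinear <- function(x, ho, wo) {
  xv <- x$v
  d <- dim(xv)
  Wr <- interp_matrix(d[1L], ho)
  Wc <- interp_matrix(d[2L], wo)
  y <- array(0, c(ho, wo, d[3L]))
  for (c in seq_len(d[3L])) y[, , c] <- Wr %*% xv[, , c] %*% t(Wc)
  tn_op(y, list(x), function(g) {
    gx <- array(0, d)
    for (c in seq_len(d[3L])) gx[, , c] <- t(Wr) %*% g[, , c] %*% Wc
    list(gx)
  })
}

# Modulated deformable convolution, kernel k x k, stride 1, zero pad (k-1)/2.
#   y(p) = sum_k w_k * x(p + p_k + dp_k(p)) * m_k(p)          (bilinear sampling)
# x [H,W,Cin]; w [k,k,Cin,Cout]; off [H,W,2K] (dy planes then dx planes);
# modl [H,W,K]; out-of-bounds samples contribute zero. All K sampling points
# are processed as one [n, K*Cin] gather + matmul (im2col-style) for speed.
tn_deform_conv <- function(x, w, b, off, modl) {
  xv <- x$v
  wv <- w$v
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; cin <- d[3L]
  kd <- dim(wv)
  k <- kd[1L]
  stopifnot(kd[2L] == k, kd[3L] == cin)
  cout <- kd[4L]
  K <- k * k
  ov <- matrix(off$v, H * W, 2L * K)
  mv <- matrix(modl$v, H * W, K)
  half <- (k - 1L) %/% 2L
  n <- H * W
  ii <- rep(seq_len(H), times = W)       # output coords, column-major order
  jj <- rep(seq_len(W), each = H)
  xmat <- matrix(xv, n, cin)
  # kernel point order matches conv_weight_mat: ki fastest within kj
  di <- rep(seq_len(k) - 1L - half, times = k)
  dj <- rep(seq_len(k) - 1L - half, each = k)
  SY <- ii + ov[, 1:K, drop = FALSE] + rep(di, each = n)            # [n, K]
  SX <- jj + ov[, (K + 1L):(2L * K), drop = FALSE] + rep(dj, each = n)
  Y0 <- floor(SY); X0 <- floor(SX)
  FY <- SY - Y0; FX <- SX - X0
  corner_spec <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  corner_wgt <- function(cs) {
    wy <- if (cs[1] == 0) 1 - FY else FY
    wx <- if (cs[2] == 0) 1 - FX else FX
    wy * wx
  }
  # gather the sample matrix for one corner: [n*K, cin], invalid rows zero
  gather_corner <- function(cs) {
    IY <- Y0 + cs[1]; IX <- X0 + cs[2]
    valid <- IY >= 1 & IY <= H & IX >= 1 & IX <= W
    lin <- pmin(pmax(IY, 1), H) + (pmin(pmax(IX, 1), W) - 1) * H
    V <- xmat[as.integer(lin), , drop = FALSE]
    V[!valid] <- 0                       # recycles over channel columns
    list(V = V, valid = valid, lin = lin)
  }
  # bilinear-sampled values, laid out [n, K*cin] with cin fastest per k —
  # but grouped per k for the matmul we order columns (k block) x cin, i.e.
  # column ((kk-1)*cin + c): matches conv_weight_mat row order (c, ki, kj)
  # after the per-k interleave below.
  S <- matrix(0, n * K, cin)
  for (ci in seq_along(corner_spec)) {
    cs <- corner_spec[[ci]]
    gc <- gather_corner(cs)
    S <- S + gc$V * as.vector(corner_wgt(cs))
  }
  # reorder [n*K, cin] -> [n, K*cin] with c fastest within each k block
  to_blocks <- function(M) {
    dim(M) <- c(n, K, cin)
    M <- aperm(M, c(1L, 3L, 2L))         # [n, cin, K]
    dim(M) <- c(n, cin * K)
    M
  }
  from_blocks <- function(M) {
    dim(M) <- c(n, cin, K)
    M <- aperm(M, c(1L, 3L, 2L))
    dim(M) <- c(n * K, cin)
    M
  }
  # conv_weight_mat rows are ordered c fastest, then ki, then kj == per-k
  # blocks of cin with k ordered (ki, kj) — matching to_blocks with the di/dj
  # enumeration above. Columns of Sb: block kk holds channels of point kk.
  modrep <- matrix(0, n, cin * K)
  for (kk in seq_len(K)) modrep[, ((kk - 1L) * cin + 1L):(kk * cin)] <- mv[, kk]
  Sb <- to_blocks(S)
  M <- Sb * modrep
  Wm <- conv_weight_mat(wv)
  Y <- M %*% Wm
  Y <- sweep(Y, 2L, b$v, "+")
  dim(Y) <- c(H, W, cout)
  tn_op(Y, list(x, w, b, off, modl), function(g) {
    gm <- matrix(g, n, cout)
    dWm <- crossprod(M, gm)
    gw <- aperm(array(dWm, c(cin, k, k, cout)), c(2L, 3L, 1L, 4L))
    dM <- gm %*% t(Wm)                              # [n, K*cin]
    # modulation grad: per k, sum over channels of dM * S
    prod_ms <- dM * Sb
    dim(prod_ms) <- c(n, cin, K)
    gmod <- array(colSums(aperm(prod_ms, c(2L, 1L, 3L))), c(n, K))
    dS <- from_blocks(dM * modrep)                  # [n*K, cin]
    # offset + input grads need the corner samples again
    goy <- matrix(0, n, K); gox <- matrix(0, n, K)
    all_lin <- vector("list", length(corner_spec))
    all_contrib <- vector("list", length(corner_spec))
    for (ci in seq_along(corner_spec)) {
      cs <- corner_spec[[ci]]
      gc <- gather_corner(cs)
      dwy <- if (cs[1] == 0) -1 else 1
      dwx <- if (cs[2] == 0) -1 else 1
      wy <- if (cs[1] == 0) 1 - FY else FY
      wx <- if (cs[2] == 0) 1 - FX else FX
      rs <- rowSums(dS * gc$V)                      # [n*K]
      dim(rs) <- c(n, K)
      goy <- goy + rs * dwy * wx
      gox <- gox + rs * dwx * wy
      wgt <- as.vector(wy * wx)
      wgt[!gc$valid] <- 0
      all_lin[[ci]] <- as.integer(gc$lin)
      all_contrib[[ci]] <- dS * wgt
    }
    contrib <- do.call(rbind, all_contrib)
    grp <- unlist(all_lin)
    acc <- rowsum(contrib, grp)
    gx <- matrix(0, n, cin)
    gx[as.integer(rownames(acc)), ] <- acc
    dim(gx) <- d
    goff <- array(cbind(goy, gox), dim(off$v))
    list(gx, gw, colSums(gm), goff, array(gmod, dim(modl$v)))
  })
}
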