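# Multi-scale token division (MSTD). The CNN feature map is tokenized twice:
# once with an a x a / stride-a patch convolution, and once with a b x b /
# stride-b patch convolution applied to a mirror-padded copy whose side length
# is scaled by b/a, so both token sets share one (H/a) x (W/a) grid. The two
# sets are split channelwise and fused through Tanh+1-gated products with
# residual paths, yielding one token matrix that carries both receptive-field
# scales.

#' Tanh+1 activation
#'
#' Elementwise `tanh(x) + 1`, the gating nonlinearity used by the token-fusion
#' and cross-attention-fusion blocks. Maps any real input into the open
#' interval (0, 2), so gated products can amplify (towards 2) or suppress
#' (towards 0) a feature while the identity value 1 leaves it unchanged.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape with values in (0, 2).
#' @examples
#' tanh_plus_one(0)    # exactly 1
#' tanh_plus_one(c(-50, 50))
#' @export
tanh_plus_one <- function(x) tanh(x) + 1

#' Mirror-pad a feature map to double its spatial size
#'
#' Reflection-pads an `[H, W, C]` feature map by H/2 rows and W/2 columns per
#' side (edge sample not duplicated), producing the `[2H, 2W, C]` map that the
#' coarse-scale tokenizer of the multi-scale token division consumes. The
#' central H x W crop of the result equals the input exactly.
#'
#' @param z numeric array `[H, W, C]` with even H and W.
#' @return numeric array `[2H, 2W, C]`.
#' @export
mirror_pad_double <- function(z) {
  d <- dim(z)
  if (length(d) != 3L) stop("z must be an [H, W, C] array")
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop("mirror_pad_double: H and W must be even")
  }
  tn_val(tn_pad_reflect(as_tn(z), d[1L] %/% 2L, d[2L] %/% 2L))
}

# generalized mirror padding for scale pair (a, b): target side length H*b/a
mstd_pad_amount <- function(h, a, b) {
  target <- h * b / a
  if (target != round(target)) {
    stop(sprintf("scale pair (%d,%d): padded size %.2f is fractional for H=%d", a, b, target, h))
  }
  p <- (target - h) / 2
  if (p != round(p)) {
    stop(sprintf("scale pair (%d,%d): per-side padding %.2f is fractional for H=%d", a, b, p, h))
  }
  if (p > h - 1) {
    stop(sprintf("scale pair (%d,%d): padding %d exceeds single-reflection range for H=%d", a, b, as.integer(p), h))
  }
  as.integer(p)
}

#' Tokenize a feature map with a patch convolution
#'
#' Applies a k x k convolution with stride k (patch embedding) and flattens the
#' resulting grid to an `[N, D]` token matrix (column-major over the grid).
#'
#' @param z numeric array `[H, W, C]`.
#' @param weights convolution kernel `[k, k, C, D]`.
#' @param bias length-D numeric.
#' @param stride patch stride (defaults to the kernel size).
#' @return list with `tokens` (`[N, D]` matrix), `grid_h`, `grid_w`.
#' @export
tokenize <- function(z, weights, bias = NULL, stride = dim(weights)[1L]) {
  d <- dim(z)
  k <- dim(weights)[1L]
  if (d[1L] %% stride != 0L || d[2L] %% stride != 0L) {
    stop(sprintf("tokenize: spatial dims (%d,%d) not divisible by stride %d", d[1L], d[2L], stride))
  }
  b <- as_tn(if (is.null(bias)) numeric(dim(weights)[4L]) else bias)
  y <- tn_conv2d(as_tn(z), as_tn(weights), b, stride = stride, pad = 0L)
  gd <- dim(y$v)
  tok <- y$v
  dim(tok) <- c(gd[1L] * gd[2L], gd[3L])
  list(tokens = tok, grid_h = gd[1L], grid_w = gd[2L])
}

#' Split a token matrix into channel halves
#'
#' @param tokens `[N, D]` matrix with even D.
#' @return list of two `[N, D/2]` matrices (first and second channel half).
#' @export
channel_split <- function(tokens) {
  D <- ncol(tokens)
  if (D %% 2L != 0L) stop("channel_split: token dimension must be even")
  list(tokens[, 1:(D %/% 2L), drop = FALSE],
       tokens[, (D %/% 2L + 1L):D, drop = FALSE])
}

# Tape version of the gated fusion. z1, z2: [N, D] nodes, D even. Returns the
# fused [N, D] node:
#   f0 = z1[1] + z2[0]
#   F1 = A(f0 * z1[0]) + z1[0]
#   F2 = A(f0 * z2[1]) + z2[1]
#   F0 = A(f0 * F1 * F2) + f0
#   out = [F0, F1 + F2]
tn_mstd_fuse <- function(z1, z2) {
  D <- ncol(z1$v)
  if (D %% 2L != 0L || !identical(dim(z1$v), dim(z2$v))) {
    stop("mstd_fuse: token sets must share shape with even channel count")
  }
  h <- D %/% 2L
  z1a <- tn_slice_last(z1, 1:h);       z1b <- tn_slice_last(z1, (h + 1L):D)
  z2a <- tn_slice_last(z2, 1:h);       z2b <- tn_slice_last(z2, (h + 1L):D)
  f0 <- tn_add(z1b, z2a)
  F1 <- tn_add(tn_tanh1(tn_mul(f0, z1a)), z1a)
  F2 <- tn_add(tn_tanh1(tn_mul(f0, z2b)), z2b)
  F0 <- tn_add(tn_tanh1(tn_mul(tn_mul(f0, F1), F2)), f0)
  tn_concat_last(list(F0, tn_add(F1, F2)))
}

#' Fuse two token sets divided at different scales
#'
#' Gated interaction and fusion of a fine-scale and a coarse-scale token set
#' sharing one grid. Each set is split channelwise; the cross-scale sum of the
#' inner halves forms a shared carrier which gates (via Tanh+1-mapped products,
#' with residual paths) the remaining halves; the fused carrier and the summed
#' gated halves are concatenated back to D channels.
#'
#' @param z1,z2 `[N, D]` token matrices (fine and coarse scale), equal shape,
#'   even D.
#' @return `[N, D]` fused token matrix.
#' @export
mstd_fuse <- function(z1, z2) {
  tn_val(tn_mstd_fuse(as_tn(z1), as_tn(z2)))
}

## ---- module ---------------------------------------------------------------

mstd_init <- function(cin, embed_dim, scale_pair = c(2L, 4L)) {
  a <- as.integer(scale_pair[1L]); b <- as.integer(scale_pair[2L])
  if (a < 2L || b <= a) stop("scale_pair must be increasing integers >= 2")
  if (embed_dim %% 2L != 0L) stop("embed_dim must be even")
  list(
    scale_pair = c(a, b),
    fine = layer_conv(a, a, cin, embed_dim),
    coarse = layer_conv(b, b, cin, embed_dim)
  )
}

# x: [H, W, C] node. Returns list(tokens = [N, D] node, grid_h, grid_w).
mstd_forward <- function(mod, x) {
  a <- mod$scale_pair[1L]; b <- mod$scale_pair[2L]
  d <- dim(x$v)
  if (d[1L] %% a != 0L || d[2L] %% a != 0L) {
    stop(sprintf("MSTD: feature map %dx%d not divisible by fine scale %d", d[1L], d[2L], a))
  }
  pr <- mstd_pad_amount(d[1L], a, b)
  pc <- mstd_pad_amount(d[2L], a, b)
  fine <- conv_fwd(mod$fine, x, stride = a)
  coarse <- conv_fwd(mod$coarse, tn_pad_reflect(x, pr, pc), stride = b)
  gh <- dim(fine$v)[1L]; gw <- dim(fine$v)[2L]
  if (!identical(dim(fine$v)[1:2], dim(coarse$v)[1:2])) {
    stop("MSTD: token grids of the two scales disagree")   # guarded at build, belt and braces
  }
  D <- dim(fine$v)[3L]
  z1 <- tn_reshape(fine, c(gh * gw, D))
  z2 <- tn_reshape(coarse, c(gh * gw, D))
  list(tokens = tn_mstd_fuse(z1, z2), grid_h = gh, grid_w = gw)
}
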