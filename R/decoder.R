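# Decoder: cascaded 2x bilinear upsampling with encoder skip connections,
# each stage refined by a modulated deformable 3x3 convolution whose
# per-position offsets and modulation are predicted by a zero-initialized
# standard convolution, so training starts at (a rescaled multiple of) the
# plain-convolution limit.

#' Modulated deformable convolution (functional form)
#'
#' Computes `y(p) = sum_k w_k * x(p + p_k + dp_k(p)) * m_k(p)` with bilinear
#' sampling at the displaced positions, stride 1 and zero padding so the
#' output grid matches the input. Out-of-bounds samples contribute zero.
#' With all offsets zero and all modulation one this reduces exactly to a
#' standard convolution.
#'
#' @param x numeric array `[H, W, Cin]`.
#' @param weights kernel `[k, k, Cin, Cout]` (odd k).
#' @param bias length-Cout numeric.
#' @param offsets `[H, W, 2K]` array (K = k^2): planes 1..K are row (y)
#'   displacements per sampling point, planes K+1..2K column (x) displacements.
#' @param modulation `[H, W, K]` array of per-point scalars.
#' @return numeric array `[H, W, Cout]`.
#' @export
deform_conv <- function(x, weights, bias = NULL, offsets = NULL, modulation = NULL) {
  d <- dim(x); kd <- dim(weights)
  K <- kd[1L] * kd[2L]
  if (is.null(bias)) bias <- numeric(kd[4L])
  if (is.null(offsets)) offsets <- array(0, c(d[1L], d[2L], 2L * K))
  if (is.null(modulation)) modulation <- array(1, c(d[1L], d[2L], K))
  tn_val(tn_deform_conv(as_tn(x), as_tn(weights), as_tn(bias),
                        as_tn(offsets), as_tn(modulation)))
}

# offset/modulation predictor: one standard k x k conv emitting 3K planes
# (2K raw offsets, K modulation logits), zero-initialized
offset_predictor_init <- function(cin, k = 3L) {
  layer_conv(k, k, cin, 3L * k * k, zero = TRUE)
}

# returns list(off = [H,W,2K] node, modl = [H,W,K] node in (0, scale))
tn_predict_offsets <- function(pred, x, k = 3L, modulation_scale = 2) {
  K <- k * k
  raw <- conv_fwd(pred, x, stride = 1L, pad = (k - 1L) %/% 2L)
  off <- tn_slice_last(raw, 1:(2L * K))
  modl <- tn_scale(tn_sigmoid(tn_slice_last(raw, (2L * K + 1L):(3L * K))), modulation_scale)
  list(off = off, modl = modl)
}

#' Predict deformable-convolution offsets and modulation
#'
#' A zero-initialized standard convolution emits `3K` planes per position:
#' `2K` raw offsets and `K` modulation logits squashed by a sigmoid and
#' rescaled by `modulation_scale` (default 2, so an untrained predictor gives
#' modulation exactly 1 — the plain-convolution limit).
#'
#' @param x numeric array `[H, W, C]`.
#' @param weights predictor kernel `[k, k, C, 3K]`; `bias` its length-3K bias.
#' @param bias predictor bias.
#' @param modulation_scale multiplier applied after the sigmoid.
#' @return list with `offsets` (`[H, W, 2K]`) and `modulation` (`[H, W, K]`).
#' @export
predict_offsets <- function(x, weights, bias = NULL, modulation_scale = 2) {
  k <- dim(weights)[1L]
  if (is.null(bias)) bias <- numeric(dim(weights)[4L])
  pred <- list(w = as_tn(weights), b = as_tn(bias))
  res <- tn_predict_offsets(pred, as_tn(x), k = k, modulation_scale = modulation_scale)
  list(offsets = tn_val(res$off), modulation = tn_val(res$modl))
}

## ---- decoder module -------------------------------------------------------

up_block_init <- function(cin, cout, deformable = TRUE) {
  blk <- list(conv = layer_conv(3L, 3L, cin, cout), norm = layer_norm_affine(cout),
              deformable = deformable)
  if (deformable) blk$offsets <- offset_predictor_init(cin)
  blk
}

# x: [h, w, C] node; skip: NULL or a finer [sh, sw, Cs] node. The block
# upsamples to the skip's resolution when one is present (2x otherwise,
# matching the doubling cascade), concatenates and refines.
tn_up_block <- function(blk, x, skip, modulation_scale = 2) {
  d <- dim(x$v)
  if (!is.null(skip)) {
    sd <- dim(skip$v)
    if (sd[1L] < d[1L] || sd[2L] < d[2L]) {
      stop(sprintf("up_block: skip %dx%d is coarser than input %dx%d",
                   sd[1L], sd[2L], d[1L], d[2L]))
    }
    up <- tn_upsample_bilinear(x, sd[1L], sd[2L])
    up <- tn_concat_last(list(up, skip))
  } else {
    up <- tn_upsample_bilinear(x, 2L * d[1L], 2L * d[2L])
  }
  y <- if (isTRUE(blk$deformable)) {
    pm <- tn_predict_offsets(blk$offsets, up, k = 3L, modulation_scale = modulation_scale)
    tn_deform_conv(up, blk$conv$w, blk$conv$b, pm$off, pm$modl)
  } else {
    conv_fwd(blk$conv, up, stride = 1L, pad = 1L)
  }
  tn_relu(cn_fwd(blk$norm, y))
}

decoder_init <- function(token_dim, skip_widths, widths, n_classes,
                         deformable = TRUE) {
  # skip_widths: channel counts of the encoder skips consumed coarse -> fine,
  # padded with NA where a stage has no skip (the final stages)
  stopifnot(length(widths) == length(skip_widths))
  blocks <- vector("list", length(widths))
  cin <- token_dim
  for (i in seq_along(widths)) {
    extra <- if (is.na(skip_widths[i])) 0L else skip_widths[i]
    blocks[[i]] <- up_block_init(cin + extra, widths[i], deformable = deformable)
    cin <- widths[i]
  }
  list(blocks = blocks, head = layer_conv(1L, 1L, cin, n_classes),
       skip_widths = skip_widths)
}

# tokens: [N, D] node with grid (gh, gw); skips: list coarse -> fine of
# [h, w, C] nodes or NULL entries. Returns [H, W, n_classes] logits node.
tn_decode <- function(dec, tokens, gh, gw, skips, modulation_scale = 2) {
  N <- nrow(tokens$v)
  if (N != gh * gw) stop("decode: token count is not a full grid")
  x <- tn_reshape(tokens, c(gh, gw, ncol(tokens$v)))
  for (i in seq_along(dec$blocks)) {
    skip <- if (i <= length(skips)) skips[[i]] else NULL
    x <- tn_up_block(dec$blocks[[i]], x, skip, modulation_scale)
  }
  conv_fwd(dec$head, x, stride = 1L, pad = 0L)
}
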