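# Full network assembly: a three-stage residual CNN stem (strides 2/2/2,
# skip features at 1/2, 1/4 and 1/8 resolution), multi-scale token division
# on the 1/8 map, a learned positional embedding, the 3-block spatial-channel
# fusion transformer stack, and a deformable-convolution decoder that climbs
# back to full resolution through the skips, ending in a 1x1 class head.

#' Model configuration
#'
#' The default values are the frozen reference configuration: 3 input
#' channels (the PCA-reduced cube), 512x512 input, token scale pair (2,4),
#' embed dimension and stage widths calibrated once so the trainable
#' parameter count reproduces the published 34.59M budget.
#'
#' @param in_channels input channels (PCA components k).
#' @param n_classes output classes.
#' @param input_size square input side length; must be divisible by
#'   `8 * scale_pair[1]`.
#' @param cnn_widths channel widths of the three CNN stages.
#' @param scale_pair MSTD token scales `(a, b)`, `a < b`.
#' @param embed_dim transformer token dimension D (even, divisible by
#'   `n_heads`).
#' @param n_heads,n_blocks,mlp_ratio,dropout,prenorm SCFormer settings.
#' @param pos_embed add a learned positional embedding to the tokens.
#' @param decoder_widths channel widths of the up-blocks (coarse to fine).
#' @param deformable use deformable 3x3 convolutions in the decoder.
#' @param modulation_rescale multiply the sigmoid modulation by 2 so an
#'   untrained offset predictor starts at the plain-convolution limit.
#' @return list of class `ModelConfig`.
#' @export
model_config <- function(in_channels = 3L, n_classes = 2L, input_size = 512L,
                         cnn_widths = c(64L, 128L, 256L),
                         scale_pair = c(2L, 4L), embed_dim = 720L,
                         n_heads = 8L, n_blocks = 3L, mlp_ratio = 4,
                         dropout = 0, prenorm = TRUE, pos_embed = TRUE,
                         decoder_widths = c(236L, 128L, 64L, 24L),
                         deformable = TRUE, modulation_rescale = TRUE) {
  a <- as.integer(scale_pair[1L])
  if (length(cnn_widths) != 3L) stop("cnn_widths must give the three stage widths")
  if (input_size %% (8L * a) != 0L) {
    stop(sprintf("input_size %d must be divisible by the total downsampling factor %d (CNN 8 x fine scale %d)",
                 input_size, 8L * a, a))
  }
  if (embed_dim %% n_heads != 0L) {
    stop(sprintf("embed_dim %d not divisible by n_heads %d", embed_dim, n_heads))
  }
  if (embed_dim %% 2L != 0L) stop("embed_dim must be even (channel split)")
  # validate the generalized mirror-padding rule at build time
  mstd_pad_amount(input_size %/% 8L, a, as.integer(scale_pair[2L]))
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 cnn_widths = as.integer(cnn_widths),
                 scale_pair = as.integer(scale_pair),
                 embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks), mlp_ratio = mlp_ratio,
                 dropout = dropout, prenorm = prenorm, pos_embed = pos_embed,
                 decoder_widths = as.integer(decoder_widths),
                 deformable = deformable,
                 modulation_rescale = modulation_rescale),
            class = "ModelConfig")
}

# residual CNN stage: 3x3 stride-s conv + norm + relu + 3x3 conv + norm,
# 1x1 stride-s shortcut, relu(sum)
cnn_stage_init <- function(cin, cout) {
  list(conv1 = layer_conv(3L, 3L, cin, cout), n1 = layer_norm_affine(cout),
       conv2 = layer_conv(3L, 3L, cout, cout), n2 = layer_norm_affine(cout),
       short = layer_conv(1L, 1L, cin, cout))
}

tn_cnn_stage <- function(st, x) {
  h <- tn_relu(cn_fwd(st$n1, conv_fwd(st$conv1, x, stride = 2L, pad = 1L)))
  h <- cn_fwd(st$n2, conv_fwd(st$conv2, h, stride = 1L, pad = 1L))
  s <- conv_fwd(st$short, x, stride = 2L)
  tn_relu(tn_add(h, s))
}

#' Build the segmentation network
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization; the same config and seed
#'   give bit-identical initial weights.
#' @return list of class `SegModel`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "ModelConfig"))
  set.seed(seed)
  w <- config$cnn_widths
  a <- config$scale_pair[1L]
  grid <- config$input_size %/% (8L * a)
  scf_cfg <- scf_config(config$embed_dim, config$n_heads, config$n_blocks,
                        config$mlp_ratio, config$dropout, config$prenorm)
  modules <- list(
    stem = list(
      s1 = cnn_stage_init(config$in_channels, w[1L]),
      s2 = cnn_stage_init(w[1L], w[2L]),
      s3 = cnn_stage_init(w[2L], w[3L])
    ),
    mstd = mstd_init(w[3L], config$embed_dim, config$scale_pair),
    scf = scf_init(scf_cfg),
    decoder = decoder_init(config$embed_dim,
                           skip_widths = c(w[3L], w[2L], w[1L], NA),
                           widths = config$decoder_widths,
                           n_classes = config$n_classes,
                           deformable = config$deformable)
  )
  if (config$pos_embed) {
    modules$pos <- tn_param(rnorm_array(c(grid * grid, config$embed_dim), 0.02))
  }
  structure(list(config = config, modules = modules, seed = as.integer(seed)),
            class = "SegModel")
}

#' @export
print.SegModel <- function(x, ...) {
  cat(sprintf("SegModel: %d -> %d classes, input %dx%d, scales (%d,%d), D=%d, %.2fM parameters\n",
              x$config$in_channels, x$config$n_classes, x$config$input_size,
              x$config$input_size, x$config$scale_pair[1L], x$config$scale_pair[2L],
              x$config$embed_dim, count_parameters(x) / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] result (or any nested module list).
#' @return integer count of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  mods <- if (inherits(model, "SegModel")) model$modules else model
  n_params(mods)
}

# forward pass; x: [H, W, Cin] numeric array or node. Returns logits node.
model_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  m <- model$modules
  x <- as_tn(x)
  d <- dim(x$v)
  if (d[3L] != cfg$in_channels) {
    stop(sprintf("input has %d channels, model expects %d", d[3L], cfg$in_channels))
  }
  s1 <- tn_cnn_stage(m$stem$s1, x)     # 1/2
  s2 <- tn_cnn_stage(m$stem$s2, s1)    # 1/4
  s3 <- tn_cnn_stage(m$stem$s3, s2)    # 1/8
  tok <- mstd_forward(m$mstd, s3)
  t <- tok$tokens
  if (!is.null(m$pos)) {
    if (nrow(m$pos$v) != nrow(t$v)) {
      stop(sprintf("positional embedding built for %d tokens, got %d (input size mismatch)",
                   nrow(m$pos$v), nrow(t$v)))
    }
    t <- tn_add(t, m$pos)
  }
  t <- tn_scf_stack(m$scf, t, train = train)
  mod_scale <- if (cfg$modulation_rescale) 2 else 1
  tn_decode(m$decoder, t, tok$grid_h, tok$grid_w,
            skips = list(s3, s2, s1, NULL), modulation_scale = mod_scale)
}

#' Predict a label mask for one input
#'
#' Runs the network in inference mode and takes the per-pixel argmax over
#' class logits.
#'
#' @param model a trained [build_model()].
#' @param x `[H, W, Cin]` array (e.g. `pca_reduce(...)$data`) or a
#'   `ReducedCube`.
#' @return a [label_mask()].
#' @export
predict_mask <- function(model, x) {
  if (inherits(x, "ReducedCube")) x <- x$data
  logits <- tn_no_grad(model_forward(model, x, train = FALSE))$v
  d <- dim(logits)
  cls <- max.col(matrix(logits, d[1L] * d[2L], d[3L]), ties.method = "first") - 1L
  label_mask(array(cls, d[1:2]), model$config$n_classes)
}
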