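# Spatial-channel fusion transformer (SCFormer). Each block runs multi-head
# spatial self-attention (similarity over token positions) and multi-head
# channel attention (similarity over feature channels, i.e. transposed
# attention) in parallel, fuses the two streams with a Tanh+1 cross-attention
# gate against the previous block's output, and finishes with a standard
# GELU MLP under a residual connection. Channel attention additionally
# receives a dense connection: the sum of all previous block outputs enters
# its query/key path.

# multi-head scaled-dot-product attention on [N, D] nodes.
# transposed = TRUE attends over channels (per-head d_k x d_k similarity).
tn_mh_attention <- function(q, k, v, n_heads, transposed = FALSE,
                            out_proj = NULL) {
  D <- ncol(q$v)
  if (D %% n_heads != 0L) stop("embed dim not divisible by n_heads")
  dk <- D %/% n_heads
  scale <- 1 / sqrt(dk)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- tn_slice_last(q, idx)
    kh <- tn_slice_last(k, idx)
    vh <- tn_slice_last(v, idx)
    if (transposed) {
      # channels as attention rows: similarity is dk x dk, independent of N
      s <- tn_softmax_rows(tn_scale(tn_matmul(tn_t(qh), kh), scale))
      heads[[h]] <- tn_t(tn_matmul(s, tn_t(vh)))
    } else {
      s <- tn_softmax_rows(tn_scale(tn_matmul(qh, tn_t(kh)), scale))
      heads[[h]] <- tn_matmul(s, vh)
    }
  }
  out <- tn_concat_last(heads)
  if (!is.null(out_proj)) out <- linear_fwd(out_proj, out)
  out
}

#' Multi-head scaled dot-product attention
#'
#' The shared attention kernel of the spatial (MSA) and channel (MCA)
#' attention paths: per head, `softmax(Q K' / sqrt(d_k)) V`, heads
#' concatenated. With `transposed = TRUE` the similarity is computed between
#' feature channels (a d_k x d_k matrix per head, independent of the token
#' count), the construction used for channel attention.
#'
#' @param Q,K,V `[N, D]` matrices with conforming shapes.
#' @param n_heads number of attention heads; must divide D.
#' @param transposed attend over channels instead of token positions.
#' @return `[N, D]` matrix (identity output projection).
#' @export
scaled_dot_attention <- function(Q, K, V, n_heads, transposed = FALSE) {
  tn_val(tn_mh_attention(as_tn(Q), as_tn(K), as_tn(V), n_heads,
                         transposed = transposed))
}

# attention row-probability matrices (for diagnostics/tests): list per head
attention_rows <- function(Q, K, n_heads, transposed = FALSE) {
  D <- ncol(Q)
  dk <- D %/% n_heads
  lapply(seq_len(n_heads), function(h) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    qh <- Q[, idx, drop = FALSE]; kh <- K[, idx, drop = FALSE]
    s <- if (transposed) t(qh) %*% kh / sqrt(dk) else qh %*% t(kh) / sqrt(dk)
    e <- exp(s - apply(s, 1L, max))
    e / rowSums(e)
  })
}

#' Dense aggregation of previous block outputs
#'
#' Sums the outputs of all completed blocks (the dense connection feeding
#' channel attention); an empty history yields zeros.
#'
#' @param history list of `[N, D]` matrices (previous block outputs).
#' @param shape dimensions to use when `history` is empty.
#' @return `[N, D]` matrix.
#' @export
dense_aggregate <- function(history, shape = NULL) {
  if (length(history) == 0L) {
    if (is.null(shape)) stop("dense_aggregate: empty history needs an explicit shape")
    return(matrix(0, shape[1L], shape[2L]))
  }
  Reduce(`+`, history)
}

tn_dense_sum <- function(history_nodes, shape) {
  if (length(history_nodes) == 0L) return(tn_new(matrix(0, shape[1L], shape[2L])))
  Reduce(tn_add, history_nodes)
}

#' Cross-attention fusion gate
#'
#' Fuses a channel-attention stream `F1`, a spatial-attention stream `F2` and
#' the previous block output `F_prev` by emphasizing their pairwise
#' commonalities: `A(F1*F2 + F1*F_prev + F2*F_prev)` elementwise, with `A` the
#' Tanh+1 map, so the output lies in (0, 2).
#'
#' @param F1,F2,F_prev equal-shape numeric arrays.
#' @return array of the same shape with entries in (0, 2).
#' @export
caf <- function(F1, F2, F_prev) {
  if (!identical(dim(F1), dim(F2)) || !identical(dim(F1), dim(F_prev))) {
    stop("caf: inputs must share shape")
  }
  tanh_plus_one(F1 * F2 + F1 * F_prev + F2 * F_prev)
}

tn_caf <- function(f1, f2, fprev) {
  tn_tanh1(tn_add(tn_add(tn_mul(f1, f2), tn_mul(f1, fprev)), tn_mul(f2, fprev)))
}

## ---- module ---------------------------------------------------------------

scf_config <- function(embed_dim, n_heads = 4L, n_blocks = 3L, mlp_ratio = 4,
                       dropout = 0, prenorm = TRUE) {
  if (embed_dim %% n_heads != 0L) stop("embed_dim must be divisible by n_heads")
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  list(embed_dim = embed_dim, n_heads = n_heads, n_blocks = n_blocks,
       mlp_ratio = mlp_ratio, dropout = dropout, prenorm = prenorm)
}

# block 1 has no predecessors, so only later blocks own a dense projection
scf_block_init <- function(cfg, has_dense) {
  D <- cfg$embed_dim
  hid <- round(cfg$mlp_ratio * D)
  blk <- list(
    mca = list(
      ln_qk = layer_norm_affine(D), ln_v = layer_norm_affine(D),
      wq = layer_linear(D, D), wk = layer_linear(D, D), wv = layer_linear(D, D),
      wo = layer_linear(D, D)
    ),
    msa = list(
      ln = layer_norm_affine(D),
      wq = layer_linear(D, D), wk = layer_linear(D, D), wv = layer_linear(D, D),
      wo = layer_linear(D, D)
    ),
    mlp = list(ln = layer_norm_affine(D),
               fc1 = layer_linear(D, hid), fc2 = layer_linear(hid, D))
  )
  if (has_dense) blk$dense <- list(ln = layer_norm_affine(D), proj = layer_linear(D, D))
  blk
}

scf_init <- function(cfg) {
  list(cfg = cfg,
       blocks = lapply(seq_len(cfg$n_blocks), function(i) scf_block_init(cfg, i > 1L)))
}

# "LN" projection: layer norm then learned linear (pre-norm reading); with
# prenorm = FALSE the pure-linear reading of the paper's wording is used.
scf_ln_proj <- function(ln, lin, x, prenorm) {
  if (prenorm) linear_fwd(lin, ln_fwd(ln, x)) else linear_fwd(lin, x)
}

# channel attention with dense connection: Q,K from x + d(z), V from x alone
tn_mca <- function(blk, x, history_nodes, cfg) {
  shape <- dim(x$v)
  dz <- if (length(history_nodes) > 0L && !is.null(blk$dense)) {
    scf_ln_proj(blk$dense$ln, blk$dense$proj,
                tn_dense_sum(history_nodes, shape), cfg$prenorm)
  } else {
    tn_new(matrix(0, shape[1L], shape[2L]))
  }
  qk_in <- tn_add(x, dz)
  qk_src <- if (cfg$prenorm) ln_fwd(blk$mca$ln_qk, qk_in) else qk_in
  v_src <- if (cfg$prenorm) ln_fwd(blk$mca$ln_v, x) else x
  q <- linear_fwd(blk$mca$wq, qk_src)
  k <- linear_fwd(blk$mca$wk, qk_src)
  v <- linear_fwd(blk$mca$wv, v_src)
  tn_mh_attention(q, k, v, cfg$n_heads, transposed = TRUE, out_proj = blk$mca$wo)
}

tn_msa <- function(blk, x, cfg) {
  src <- if (cfg$prenorm) ln_fwd(blk$msa$ln, x) else x
  q <- linear_fwd(blk$msa$wq, src)
  k <- linear_fwd(blk$msa$wk, src)
  v <- linear_fwd(blk$msa$wv, src)
  tn_mh_attention(q, k, v, cfg$n_heads, transposed = FALSE, out_proj = blk$msa$wo)
}

tn_mlp <- function(blk, x, cfg, train) {
  h <- tn_gelu(linear_fwd(blk$mlp$fc1, x))
  h <- tn_dropout(h, cfg$dropout, train)
  h <- linear_fwd(blk$mlp$fc2, h)
  tn_dropout(h, cfg$dropout, train)
}

# one SCFormer block; returns list(out, history) with history extended
tn_scf_block <- function(blk, x, history_nodes, f_prev, cfg, train = FALSE) {
  f1 <- tn_mca(blk, x, history_nodes, cfg)
  f2 <- tn_msa(blk, x, cfg)
  fout <- tn_caf(f1, f2, f_prev)
  mlp_in <- if (cfg$prenorm) ln_fwd(blk$mlp$ln, fout) else fout
  y <- tn_add(tn_mlp(blk, mlp_in, cfg, train), fout)
  list(out = y, history = c(history_nodes, list(y)))
}

# the 3-block stack; f_prev of block 1 is the stack input (the MSTD output)
tn_scf_stack <- function(mod, x, train = FALSE) {
  cfg <- mod$cfg
  history <- list()
  f_prev <- x
  out <- x
  for (j in seq_len(cfg$n_blocks)) {
    res <- tn_scf_block(mod$blocks[[j]], out, history, f_prev, cfg, train)
    f_prev <- res$out
    out <- res$out
    history <- res$history
  }
  out
}
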