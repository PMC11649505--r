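# Layer parameter containers and the SGD-with-momentum optimizer. A "module"
# is a plain nested named list whose leaves are hs_tensor parameters; forward
# functions take the module and input node explicitly (no hidden state except
# the parameter values themselves).

rnorm_array <- function(dims, sd) {
  array(stats::rnorm(prod(dims), sd = sd), dims)
}

# He-style fan-in init for convolutions
layer_conv <- function(k_h, k_w, cin, cout, sd = NULL, zero = FALSE) {
  if (zero) {
    w <- array(0, c(k_h, k_w, cin, cout))
  } else {
    if (is.null(sd)) sd <- sqrt(2 / (k_h * k_w * cin))
    w <- rnorm_array(c(k_h, k_w, cin, cout), sd)
  }
  list(w = tn_param(w), b = tn_param(numeric(cout)))
}

layer_linear <- function(din, dout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (din + dout))
  list(w = tn_param(rnorm_array(c(din, dout), sd)), b = tn_param(numeric(dout)))
}

layer_norm_affine <- function(d) {
  list(gamma = tn_param(rep(1, d)), beta = tn_param(numeric(d)))
}

linear_fwd <- function(layer, x) tn_linear(x, layer$w, layer$b)

ln_fwd <- function(layer, x) tn_layernorm_rows(x, layer$gamma, layer$beta)

cn_fwd <- function(layer, x) tn_chan_norm(x, layer$gamma, layer$beta)

conv_fwd <- function(layer, x, stride = 1L, pad = 0L) {
  tn_conv2d(x, layer$w, layer$b, stride = stride, pad = pad)
}

# Flatten a nested module into a named list of parameter tensors.
collect_params <- function(module, prefix = "") {
  if (is_tn(module)) {
    out <- list(module)
    names(out) <- prefix
    return(out)
  }
  if (!is.list(module)) return(list())
  out <- list()
  nm <- names(module)
  for (i in seq_along(module)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    sub <- collect_params(module[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", key))
    out <- c(out, sub)
  }
  out
}

n_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$v), numeric(1)))
}

# deep copy / restore of parameter values (for best-epoch checkpointing)
params_snapshot <- function(params) lapply(params, function(p) p$v)

params_restore <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$v <- snap[[i]]
  invisible(NULL)
}

## ---- SGD with momentum + weight decay -------------------------------------

sgd_init <- function(params) {
  list(vel = lapply(params, function(p) {
    z <- numeric(length(p$v)); dim(z) <- dim(p$v); z
  }))
}

sgd_step <- function(opt, params, lr, momentum = 0.9, weight_decay = 0) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$v
    opt$vel[[i]] <- momentum * opt$vel[[i]] + g
    p$v <- p$v - lr * opt$vel[[i]]
  }
  opt
}
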