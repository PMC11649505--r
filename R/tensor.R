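# Reverse-mode automatic differentiation on dense arrays.
#
# A node ("hs_tensor") is an environment holding a value, an optional gradient,
# its parent nodes and a vector-Jacobian closure. Graphs are built eagerly by
# the tn_* ops below and freed after tn_backward(); only nodes that
# (transitively) depend on a parameter carry a tape. Feature maps are [H, W, C]
# arrays, token matrices are [N, D]; flattening is R-native column-major
# throughout.

.hs_state <- new.env(parent = emptyenv())
.hs_state$next_id <- 1L

tn_new <- function(v, req = FALSE, parents = list(), vjp = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$grad <- NULL
  node$req <- req
  node$parents <- parents
  node$vjp <- vjp
  node$id <- .hs_state$next_id
  .hs_state$next_id <- .hs_state$next_id + 1L
  class(node) <- "hs_tensor"
  node
}

#' @noRd
tn <- function(v, req = FALSE) tn_new(v, req = req)

tn_param <- function(v) tn_new(v, req = TRUE)

is_tn <- function(x) inherits(x, "hs_tensor")

as_tn <- function(x) if (is_tn(x)) x else tn_new(x)

tn_val <- function(x) if (is_tn(x)) x$v else x

# Create a derived node; the tape is dropped when no parent needs gradients
# or when evaluation runs inside tn_no_grad() (inference mode).
tn_op <- function(v, parents, vjp) {
  if (isTRUE(.hs_state$no_grad)) return(tn_new(v))
  req <- any(vapply(parents, function(p) p$req, logical(1)))
  if (!req) return(tn_new(v))
  tn_new(v, req = TRUE, parents = parents, vjp = vjp)
}

tn_no_grad <- function(expr) {
  old <- isTRUE(.hs_state$no_grad)
  .hs_state$no_grad <- TRUE
  on.exit(.hs_state$no_grad <- old)
  force(expr)
}

# Topological order by depth-first search (iterative; recursion would overflow
# on deep training graphs).
tn_topo <- function(root) {
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$req && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  order[seq_len(n_ord)]
}

# Accumulate g into node$grad (shape of node$v).
tn_accum <- function(node, g) {
  if (is.null(node$grad)) {
    gv <- as.numeric(g)
    if (!is.null(dim(node$v))) dim(gv) <- dim(node$v)
    node$grad <- gv
  } else {
    node$grad <- node$grad + as.numeric(g)
  }
  invisible(node)
}

#' @noRd
tn_backward <- function(root, grad = NULL) {
  if (!root$req) return(invisible(NULL))
  if (is.null(grad)) {
    if (length(root$v) != 1L) stop("backward from a non-scalar needs an explicit gradient")
    grad <- 1
  }
  order <- tn_topo(root)
  tn_accum(root, grad)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$vjp) || is.null(node$grad)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p$req && !is.null(gs[[j]])) tn_accum(p, gs[[j]])
    }
    # free intermediate grads/tape so big training graphs do not accumulate
    if (!is.null(node$vjp)) {
      node$grad <- NULL
      node$parents <- list()
      node$vjp <- NULL
    }
  }
  invisible(NULL)
}

tn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

tn_add <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  av <- a$v; bv <- b$v
  tn_op(av + bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) sum(g) else g
    list(ga, gb)
  })
}

tn_sub <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  av <- a$v; bv <- b$v
  tn_op(av - bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) -sum(g) else -g
    list(ga, gb)
  })
}

tn_mul <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  av <- a$v; bv <- b$v
  tn_op(av * bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g * bv) else g * bv
    gb <- if (length(bv) == 1L) sum(g * av) else g * av
    list(ga, gb)
  })
}

tn_scale <- function(a, s) {
  a <- as_tn(a)
  tn_op(a$v * s, list(a), function(g) list(g * s))
}

# x: [N, D] plus length-D bias
tn_add_bias_cols <- function(x, b) {
  xv <- x$v; bv <- b$v
  tn_op(sweep(xv, 2L, bv, "+"), list(x, b),
        function(g) list(g, colSums(g)))
}

# x: [H, W, C] plus length-C bias
tn_add_bias_chan <- function(x, b) {
  xv <- x$v; bv <- b$v
  d <- dim(xv)
  tn_op(xv + rep(bv, each = d[1L] * d[2L]), list(x, b),
        function(g) list(g, colSums(matrix(g, d[1L] * d[2L], d[3L]))))
}

tn_tanh1 <- function(x) {
  x <- as_tn(x)
  y <- tanh(x$v) + 1
  tn_op(y, list(x), function(g) list(g * (1 - (y - 1)^2)))
}

tn_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  tn_op(y, list(x), function(g) list(g * y * (1 - y)))
}

tn_relu <- function(x) {
  xv <- x$v
  m <- xv > 0
  tn_op(xv * m, list(x), function(g) list(g * m))
}

# GELU, exact (Gaussian CDF) form
tn_gelu <- function(x) {
  xv <- x$v
  ph <- stats::pnorm(xv)
  tn_op(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

tn_dropout <- function(x, p, train) {
  if (!train || p <= 0) return(x)
  keep <- (stats::runif(length(x$v)) >= p) / (1 - p)
  dim(keep) <- dim(x$v)
  tn_op(x$v * keep, list(x), function(g) list(g * keep))
}

## ---- linear algebra -------------------------------------------------------

tn_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  tn_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

tn_t <- function(a) {
  tn_op(t(a$v), list(a), function(g) list(t(g)))
}

tn_reshape <- function(a, d) {
  v <- a$v
  od <- dim(v)
  dim(v) <- d
  tn_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

# linear layer on token rows: x [N, D] %*% W [D, M] + b [M]
tn_linear <- function(x, W, b = NULL) {
  y <- tn_matmul(x, W)
  if (!is.null(b)) y <- tn_add_bias_cols(y, b) else y
}

# concatenate along the last axis (channels of [H,W,C] or columns of [N,D])
tn_concat_last <- function(xs) {
  vals <- lapply(xs, tn_val)
  d1 <- dim(vals[[1L]])
  nd <- length(d1)
  sizes <- vapply(vals, function(v) dim(v)[nd], numeric(1))
  lead <- prod(d1[-nd])
  mats <- lapply(vals, function(v) matrix(v, lead, dim(v)[length(dim(v))]))
  out <- do.call(cbind, mats)
  outd <- d1; outd[nd] <- sum(sizes)
  dim(out) <- outd
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  tn_op(out, xs, function(g) {
    gm <- matrix(g, lead, sum(sizes))
    lapply(seq_along(xs), function(i) {
      gi <- gm[, starts[i]:ends[i], drop = FALSE]
      di <- d1; di[nd] <- sizes[i]
      dim(gi) <- di
      gi
    })
  })
}

# slice of the last axis, keeping leading dims
tn_slice_last <- function(x, idx) {
  v <- x$v
  d <- dim(v)
  nd <- length(d)
  lead <- prod(d[-nd])
  m <- matrix(v, lead, d[nd])
  out <- m[, idx, drop = FALSE]
  outd <- d; outd[nd] <- length(idx)
  dim(out) <- outd
  tn_op(out, list(x), function(g) {
    gm <- matrix(0, lead, d[nd])
    gm[, idx] <- matrix(g, lead, length(idx))
    dim(gm) <- d
    list(gm)
  })
}

# fast rowwise maximum (apply() is slow on big pixel matrices)
row_max <- function(m) {
  r <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) r <- pmax(r, m[, j])
  r
}

tn_softmax_rows <- function(x) {
  xv <- x$v
  m <- xv - row_max(xv)
  e <- exp(m)
  y <- e / rowSums(e)
  tn_op(y, list(x), function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# layer normalization over each row of [N, D], with learned affine
tn_layernorm_rows <- function(x, gamma, beta, eps = 1e-6) {
  xv <- x$v
  D <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  gv <- gamma$v
  y <- xh * matrix(gv, nrow(xv), D, byrow = TRUE) + matrix(beta$v, nrow(xv), D, byrow = TRUE)
  tn_op(y, list(x, gamma, beta), function(g) {
    ggam <- colSums(g * xh)
    gbet <- colSums(g)
    gh <- g * matrix(gv, nrow(xv), D, byrow = TRUE)
    gx <- inv * (gh - rowMeans(gh) - xh * rowMeans(gh * xh))
    list(gx, ggam, gbet)
  })
}

# per-channel normalization over the spatial extent of [H, W, C] (instance
# norm); stabilizes the small-batch SGD regime the training protocol uses
tn_chan_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  d <- dim(xv)
  hw <- d[1L] * d[2L]
  m <- matrix(xv, hw, d[3L])
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  va <- colMeans(xc * xc)
  inv <- rep(1 / sqrt(va + eps), each = hw)
  xh <- xc * inv
  gv <- gamma$v
  y <- sweep(xh * rep(gv, each = hw), 2L, beta$v, "+")
  dim(y) <- d
  tn_op(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, hw, d[3L])
    ggam <- colSums(gm * xh)
    gbet <- colSums(gm)
    gh <- gm * rep(gv, each = hw)
    gx <- inv * (sweep(gh, 2L, colMeans(gh)) - xh * rep(colMeans(gh * xh), each = hw))
    dim(gx) <- d
    list(gx, ggam, gbet)
  })
}

tn_mean <- function(x) {
  n <- length(x$v)
  tn_op(mean(x$v), list(x), function(g) list(array(g / n, dim(x$v) %||% n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
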