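# Spectral-band reduction by principal component analysis. Hyperspectral
# pathology bands are strongly correlated, so a handful of leading components
# retains most of the variance; the network consumes the reduced cube.

#' Reduce the spectral dimension of a cube with PCA
#'
#' Treats pixels as observations (rows) and bands as variables, mean-centers,
#' projects onto the top-k principal axes ordered by decreasing explained
#' variance, fixes each axis' sign so its largest-magnitude loading is
#' positive, and min-max scales each component plane to `[0, 1]` so the
#' network stem sees a fixed input range. Fit per image by default; pass a
#' `basis` fitted elsewhere (see [pca_fit()]) for a dataset-wide projection.
#'
#' @param cube an [hsi_cube()].
#' @param k number of components, `1 <= k <= B`.
#' @param basis optional [pca_fit()] result to project with instead of
#'   fitting on this cube.
#' @return list of class `ReducedCube`: `data` `[H, W, k]` in `[0, 1]`,
#'   `explained_variance_ratio` (length k, non-increasing), `k`.
#' @export
pca_reduce <- function(cube, k, basis = NULL) {
  stopifnot(inherits(cube, "HsiCube"))
  d <- dim(cube$data)
  B <- d[3L]
  if (k < 1L || k > B) stop(sprintf("k must lie in [1, %d]", B))
  if (d[1L] * d[2L] < k) stop("fewer pixels than requested components")
  X <- matrix(cube$data, d[1L] * d[2L], B)
  if (is.null(basis)) basis <- pca_fit(X, k)
  scores <- sweep(X, 2L, basis$center) %*% basis$rotation[, seq_len(k), drop = FALSE]
  out <- array(0, c(d[1L], d[2L], k))
  for (i in seq_len(k)) {
    plane <- scores[, i]
    rng <- range(plane)
    out[, , i] <- if (rng[2L] > rng[1L]) (plane - rng[1L]) / (rng[2L] - rng[1L]) else 0
  }
  structure(list(data = out,
                 explained_variance_ratio = basis$evr[seq_len(k)],
                 k = as.integer(k)),
            class = "ReducedCube")
}

#' Fit a PCA basis on a pixel matrix
#'
#' @param X pixels-by-bands matrix (rows may pool several cubes for a
#'   dataset-wide basis).
#' @param k number of axes to keep.
#' @return list `rotation` (bands x k, sign-fixed), `center` (band means),
#'   `evr` (explained variance ratios).
#' @export
pca_fit <- function(X, k) {
  if (all(apply(X, 2L, stats::var) < .Machine$double.eps * 100)) {
    stop("degenerate input: cube has zero variance, PCA undefined")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr_all <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- unname(pc$rotation[, seq_len(min(k, ncol(pc$rotation))), drop = FALSE])
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, i]))
    if (rot[j, i] < 0) rot[, i] <- -rot[, i]
  }
  list(rotation = rot, center = colMeans(X), evr = evr_all)
}

#' Assign items to five cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ by
#' at most one and the same seed always reproduces the same split.
#'
#' @param n_items number of items (>= 5).
#' @param seed RNG seed.
#' @param n_folds number of folds (default 5).
#' @return list of class `FoldSplit`: `assignments` (length-n integer vector
#'   of fold ids `0..n_folds-1`), `seed`, `n_folds`.
#' @export
make_folds <- function(n_items, seed, n_folds = 5L) {
  if (n_items < n_folds) stop(sprintf("need at least %d items for %d folds", n_folds, n_folds))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n_items)
  assignments <- integer(n_items)
  assignments[perm] <- (seq_len(n_items) - 1L) %% n_folds
  structure(list(assignments = assignments, seed = as.integer(seed),
                 n_folds = as.integer(n_folds)), class = "FoldSplit")
}
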