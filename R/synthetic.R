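# Seeded synthetic microscopic-hyperspectral data. The generator emulates the
# statistical structure of gastric-pathology MHSI datasets: a 40-band
# 450-700 nm grid at 6.25 nm resolution, strong inter-band correlation
# (pixel spectra are convex mixtures of a few smooth endmember spectra, so
# the cube is low-rank plus noise), and binary lesion masks formed of
# contiguous irregular blobs (thresholded smoothed noise). It targets that
# structure, not histological appearance.

#' Configuration for the synthetic MHSI generator
#'
#' Defaults reproduce the stated acquisition grid: 40 bands from 450 nm at
#' 6.25 nm steps (ending at 693.75 nm, i.e. a 450-700 nm range), 512x512
#' pixels, binary lesion masks.
#'
#' @param height,width spatial size in pixels.
#' @param n_bands number of spectral bands (ignored when `lambda_end_nm` is
#'   given, in which case it is derived from the range).
#' @param lambda_start_nm,lambda_step_nm wavelength grid origin and step (nm).
#' @param lambda_end_nm optional exclusive range end; bands are then
#'   `round((end - start) / step)`.
#' @param n_classes number of label classes (2: background / lesion).
#' @param n_endmembers number of pure spectra mixed per pixel.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param lesion_smoothness correlation length (pixels) of the random field
#'   shaping lesion blobs; larger gives smoother, larger blobs.
#' @param lesion_fraction target foreground fraction in (0, 1).
#' @param contrast separation of the class mixing weights in `[0, 1]`.
#' @param abundance_jitter spatial variability of the per-pixel mixing
#'   weights (keeps spectra inside the endmember span).
#' @param brightness_sd log-scale spread of a smooth multiplicative
#'   brightness field shared by all bands; the dominant source of the strong
#'   inter-band correlation seen in real pathology cubes (also span-preserving).
#' @param seed RNG seed; every generated artefact is a pure function of the
#'   config including this seed.
#' @return list of class `SynthConfig`.
#' @export
synth_config <- function(height = 512L, width = 512L, n_bands = 40L,
                         lambda_start_nm = 450, lambda_step_nm = 6.25,
                         lambda_end_nm = NULL,
                         n_classes = 2L, n_endmembers = 3L,
                         noise_sigma = 0.01, lesion_smoothness = 12,
                         lesion_fraction = 0.3, contrast = 0.8,
                         abundance_jitter = 0.15, brightness_sd = 0.3,
                         seed = 1L) {
  if (!is.null(lambda_end_nm)) {
    n_bands <- as.integer(round((lambda_end_nm - lambda_start_nm) / lambda_step_nm))
  }
  if (lesion_fraction <= 0 || lesion_fraction >= 1) {
    stop("lesion_fraction must lie strictly inside (0, 1)")
  }
  if (lesion_smoothness <= 0) stop("lesion_smoothness must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_bands = n_bands, lambda_start_nm = lambda_start_nm,
                 lambda_step_nm = lambda_step_nm, n_classes = as.integer(n_classes),
                 n_endmembers = as.integer(n_endmembers),
                 noise_sigma = noise_sigma, lesion_smoothness = lesion_smoothness,
                 lesion_fraction = lesion_fraction, contrast = contrast,
                 abundance_jitter = abundance_jitter,
                 brightness_sd = brightness_sd, seed = as.integer(seed)),
            class = "SynthConfig")
}

synth_wavelengths <- function(config) {
  config$lambda_start_nm + config$lambda_step_nm * (seq_len(config$n_bands) - 1L)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate endmember spectra
#'
#' Each endmember is a smooth positive curve over the wavelength grid: a
#' baseline plus up to three Gaussian bumps with seeded centres, widths and
#' amplitudes. Smooth low-dimensional endmembers are what make the mixed
#' bands highly correlated, mirroring real pathology cubes.
#'
#' @param config a [synth_config()].
#' @return matrix `[n_endmembers, n_bands]`, all entries positive.
#' @export
gen_endmember_spectra <- function(config) {
  wl <- synth_wavelengths(config)
  with_seed(config$seed + 11L, {
    E <- matrix(0, config$n_endmembers, config$n_bands)
    for (e in seq_len(config$n_endmembers)) {
      spec <- rep(0.2 + 0.3 * stats::runif(1), config$n_bands)
      for (b in seq_len(sample(1:3, 1))) {
        centre <- stats::runif(1, min(wl), max(wl))
        width <- stats::runif(1, 20, 70)
        amp <- stats::runif(1, 0.3, 1)
        spec <- spec + amp * exp(-0.5 * ((wl - centre) / width)^2)
      }
      E[e, ] <- spec
    }
    E
  })
}

# separable Gaussian blur of a matrix, reflected boundary
gaussian_blur_mat <- function(n, sigma) {
  idx <- seq_len(n)
  W <- exp(-0.5 * outer(idx, idx, "-")^2 / sigma^2)
  W / rowSums(W)
}

smooth_field <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  Br <- gaussian_blur_mat(h, sigma)
  Bc <- gaussian_blur_mat(w, sigma)
  f <- Br %*% z %*% t(Bc)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a lesion mask
#'
#' A seeded Gaussian random field (low-pass-filtered white noise with
#' correlation length `lesion_smoothness`) thresholded at the quantile that
#' yields the requested foreground fraction; the foreground forms contiguous
#' irregular blobs.
#'
#' @param config a [synth_config()].
#' @return a [label_mask()] of size height x width.
#' @export
gen_mask <- function(config) {
  f <- with_seed(config$seed + 23L,
                 smooth_field(config$height, config$width, config$lesion_smoothness))
  thr <- stats::quantile(f, 1 - config$lesion_fraction, names = FALSE)
  label_mask(array(as.integer(f > thr), dim(f)), config$n_classes)
}

# class-specific convex mixing weights over endmembers
synth_class_weights <- function(config) {
  with_seed(config$seed + 31L, {
    rdirich <- function() { g <- stats::rgamma(config$n_endmembers, 1); g / sum(g) }
    w_bg <- rdirich()
    w_alt <- rdirich()
    w_fg <- (1 - config$contrast) * w_bg + config$contrast * w_alt
    rbind(bg = w_bg, fg = w_fg / sum(w_fg))
  })
}

#' Generate a synthetic hyperspectral cube and its mask
#'
#' Every pixel's spectrum is a convex mixture of the endmember spectra with
#' class-conditional weights (plus a smooth spatial jitter of the weights,
#' which stays inside the endmember span), and i.i.d. Gaussian noise of scale
#' `noise_sigma` on top. With zero noise the cube has rank at most
#' `n_endmembers`.
#'
#' @param config a [synth_config()].
#' @return list with `cube` (an [hsi_cube()]) and `mask` (a [label_mask()]).
#' @export
gen_cube <- function(config) {
  E <- gen_endmember_spectra(config)
  mask <- gen_mask(config)
  Wcls <- synth_class_weights(config)
  h <- config$height; w <- config$width
  m <- config$n_endmembers
  n <- h * w
  weights <- with_seed(config$seed + 37L, {
    A <- matrix(Wcls["bg", ], n, m, byrow = TRUE)
    fg <- as.vector(mask$labels) == 1L
    if (config$n_classes >= 2L) A[fg, ] <- matrix(Wcls["fg", ], sum(fg), m, byrow = TRUE)
    if (config$abundance_jitter > 0) {
      for (e in seq_len(m)) {
        A[, e] <- A[, e] + config$abundance_jitter *
          as.vector(smooth_field(h, w, config$lesion_smoothness))
      }
      A <- pmax(A, 0.01)
      A <- A / rowSums(A)
    }
    A
  })
  X <- weights %*% E
  if (config$brightness_sd > 0) {
    bright <- with_seed(config$seed + 43L,
                        exp(config$brightness_sd *
                              as.vector(smooth_field(h, w, config$lesion_smoothness))))
    X <- X * bright                       # scalar per pixel: stays in the span
  }
  if (config$noise_sigma > 0) {
    X <- X + with_seed(config$seed + 41L,
                       matrix(stats::rnorm(n * config$n_bands, sd = config$noise_sigma),
                              n, config$n_bands))
  }
  data <- array(X, c(h, w, config$n_bands))
  list(cube = hsi_cube(data, synth_wavelengths(config),
                       source_id = sprintf("synthetic-seed%d", config$seed)),
       mask = mask)
}

#' Generate a dataset of synthetic cube/mask pairs
#'
#' @param n number of images.
#' @param config base [synth_config()]; image i uses `seed + i - 1`.
#' @return list of `gen_cube` results.
#' @export
gen_dataset <- function(n, config) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    gen_cube(cfg)
  })
}

#' Mean absolute inter-band correlation of a cube
#'
#' Diagnostic mirroring the observation that pathology MHSI bands are highly
#' correlated; averages `|cor|` over all band pairs across pixels.
#'
#' @param cube an [hsi_cube()].
#' @return scalar in `[0, 1]`.
#' @export
interband_correlation <- function(cube) {
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1L] * d[2L], d[3L])
  cc <- abs(stats::cor(X))
  mean(cc[upper.tri(cc)])
}
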