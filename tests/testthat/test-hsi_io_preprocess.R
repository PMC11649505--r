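# Cube/mask I/O round-trips, PCA reduction against the eigendecomposition
# oracle, false-color band selection and fold construction.

test_that("container and ENVI round-trips are lossless", {
  set.seed(3)
  cube <- hsi_cube(array(rnorm(4 * 4 * 40), c(4, 4, 40)),
                   450 + 6.25 * (0:39), "unit")
  tmp <- withr::local_tempdir()

  p1 <- file.path(tmp, "cube.rds")
  write_cube(cube, p1)
  back <- read_cube(p1)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths_nm, cube$wavelengths_nm)

  p2 <- file.path(tmp, "cube.raw")
  write_cube(cube, p2, format = "envi")
  back2 <- read_cube(file.path(tmp, "cube.hdr"))
  expect_equal(back2$data, cube$data)
  expect_equal(back2$wavelengths_nm, cube$wavelengths_nm)

  # small seeded cube round-trips bit-identically through the container
  small <- hsi_cube(array(rnorm(8 * 8 * 5), c(8, 8, 5)), 1:5, "s")
  p3 <- file.path(tmp, "small.rds")
  write_cube(small, p3)
  expect_identical(read_cube(p3)$data, small$data)

  expect_error(write_cube(cube, file.path(tmp, "x.xyz"), format = "parquet"),
               "unsupported")
  expect_error(read_cube(file.path(tmp, "absent.rds")), "not found")
})

test_that("TIFF stacks round-trip within float32 rounding and synthesize wavelengths", {
  set.seed(4)
  cube <- hsi_cube(array(runif(6 * 5 * 40), c(6, 5, 40)), 450 + 6.25 * (0:39))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "stack.tif")
  write_cube(cube, p)
  back <- read_cube(p)   # no wavelength tags -> config fallback 450 + 6.25 i
  expect_equal(dim(back$data), dim(cube$data))
  expect_equal(back$data, cube$data, tolerance = 1e-6)
  expect_equal(back$wavelengths_nm, 450 + 6.25 * (0:39))
  expect_equal(back$wavelengths_nm[40], 693.75)
})

test_that("ENVI band-count mismatch raises a format error", {
  tmp <- withr::local_tempdir()
  cube <- hsi_cube(array(1.0 * (1:48), c(4, 3, 4)), 1:4)
  write_cube(cube, file.path(tmp, "c.raw"), format = "envi")
  # declare 40 bands over data that holds 4
  hdr <- readLines(file.path(tmp, "c.hdr"))
  hdr <- sub("bands = 4", "bands = 40", hdr)
  hdr <- hdr[!grepl("wavelength", hdr)]
  writeLines(hdr, file.path(tmp, "c.hdr"))
  expect_error(read_cube(file.path(tmp, "c.hdr")), "mismatch")
})

test_that("mask round-trips preserve labels and validation rejects bad labels", {
  set.seed(5)
  m <- label_mask(array(sample(0:1, 16 * 16, TRUE), c(16, 16)), 2L)
  tmp <- withr::local_tempdir()
  for (ext in c("pgm", "rds")) {
    p <- file.path(tmp, paste0("m.", ext))
    write_mask(m, p)
    back <- read_mask(p, num_classes = 2L)
    expect_identical(back$labels, m$labels)
  }
  expect_error(label_mask(array(3L, c(4, 4)), 2L), "labels")
  zeros <- label_mask(array(0L, c(4, 4)), 2L)
  expect_equal(sum(zeros$labels), 0)
  # a stored mask with labels exceeding the declared class count fails
  bad <- file.path(tmp, "bad.pgm")
  write_mask(label_mask(array(sample(0:3, 64, TRUE), c(8, 8)), 4L), bad)
  expect_error(read_mask(bad, num_classes = 2L), "labels")
})

test_that("pca_reduce matches the covariance eigendecomposition oracle", {
  set.seed(11)
  base <- matrix(rnorm(16 * 16 * 3), 16 * 16, 3)
  mix <- matrix(runif(3 * 10), 3, 10)
  X <- base %*% mix + matrix(rnorm(16 * 16 * 10, sd = 0.05), 16 * 16, 10)
  cube <- hsi_cube(array(X, c(16, 16, 10)), 1:10)
  red <- pca_reduce(cube, 3L)
  oracle <- ref_pca(X, 3L)
  fit <- pca_fit(X, 3L)
  for (i in 1:3) {
    cosine <- abs(sum(fit$rotation[, i] * oracle$rotation[, i]))
    expect_gt(cosine, 1 - 1e-6)
  }
  expect_equal(red$explained_variance_ratio, oracle$evr[1:3], tolerance = 1e-8)
  # sign convention agrees, so the axes match exactly (not only up to sign)
  expect_equal(fit$rotation, oracle$rotation, tolerance = 1e-8)
})

test_that("pca_reduce properties: rank-1 limit, monotone variance, scaling", {
  set.seed(12)
  b1 <- matrix(rnorm(64), 8, 8)
  rank1 <- array(0, c(8, 8, 5))
  for (b in 1:5) rank1[, , b] <- b1 * b
  cube1 <- hsi_cube(rank1, 1:5)
  expect_equal(pca_reduce(cube1, 1L)$explained_variance_ratio, 1, tolerance = 1e-9)

  cube <- hsi_cube(array(rnorm(12 * 12 * 6), c(12, 12, 6)), 1:6)
  red <- pca_reduce(cube, 6L)
  evr <- red$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-9)
  expect_equal(sum(evr), 1, tolerance = 1e-9)   # k = rank = B
  expect_true(all(red$data >= 0 & red$data <= 1))

  expect_error(pca_reduce(cube, 7L), "k must lie")
  flat <- hsi_cube(array(1, c(4, 4, 3)) + 0, 1:3)
  expect_error(pca_reduce(flat, 2L), "degenerate")
})

test_that("false_color picks nearest display bands and scales to 0..255", {
  set.seed(13)
  cube <- hsi_cube(array(runif(6 * 6 * 40), c(6, 6, 40)), 450 + 6.25 * (0:39))
  # 650/550/450 lie exactly on the 6.25 nm grid
  expect_equal(cube$wavelengths_nm[false_color_bands(cube)], c(650, 550, 450))
  img <- false_color(cube)
  expect_true(all(img >= 0 & img <= 255))
  const <- hsi_cube(array(2, c(4, 4, 4)) + 0, 1:4)
  expect_true(all(false_color(const) == 0))
  expect_error(false_color(hsi_cube(array(1:32 / 32, c(4, 4, 2)), 1:2)), "3 bands")
})

test_that("make_folds balances five folds deterministically", {
  for (n in c(412L, 282L)) {
    fs <- make_folds(n, seed = 9L)
    sizes <- as.vector(table(fs$assignments))
    expect_equal(length(sizes), 5L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(sum(sizes), n)
  }
  expect_equal(sort(as.vector(table(make_folds(412L, 1L)$assignments)),
                    decreasing = TRUE), c(83, 83, 82, 82, 82))
  expect_equal(sort(as.vector(table(make_folds(282L, 1L)$assignments)),
                    decreasing = TRUE), c(57, 57, 56, 56, 56))
  expect_identical(make_folds(100L, 7L)$assignments, make_folds(100L, 7L)$assignments)
  expect_error(make_folds(4L, 1L), "at least")
})
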