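# Full-network assembly, parameter accounting, end-to-end shape laws,
# gradient connectivity, and the training loop's contracts.

test_that("configuration validation reports divisibility violations", {
  expect_error(model_config(input_size = 100L), "divisible")
  expect_error(model_config(embed_dim = 30L, n_heads = 4L), "divisible")
  expect_error(model_config(input_size = 40L, scale_pair = c(3L, 5L)), "divisible")
  # (2,5) on a 48 input: 1/8 map is 6x6, padded target 15 needs 4.5 rows/side
  expect_error(model_config(input_size = 48L, scale_pair = c(2L, 5L)), "fractional")
})

test_that("a built model honours the shape laws of the architecture", {
  cfg <- tiny_model_config(input_size = 64L)
  m <- build_model(cfg, seed = 2)
  set.seed(3)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  logits <- hyperseg:::tn_no_grad(hyperseg:::model_forward(m, x))
  expect_equal(dim(logits$v), c(64L, 64L, 2L))    # resolution preserved
  # token grid at 1/16 for the (2,4) pair
  expect_equal(nrow(m$modules$pos$v), (64L / 16L)^2)
  # n_classes drives the head
  cfg3 <- tiny_model_config(input_size = 32L)
  cfg3$n_classes <- 3L
  m3 <- build_model(cfg3, seed = 2)
  l3 <- hyperseg:::tn_no_grad(hyperseg:::model_forward(m3, array(0, c(32, 32, 3))))
  expect_equal(dim(l3$v)[3], 3L)
})

test_that("identical build seeds give identical weights; predict is deterministic", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  p1 <- hyperseg:::collect_params(m1$modules)
  p2 <- hyperseg:::collect_params(m2$modules)
  expect_identical(lapply(p1, function(p) p$v), lapply(p2, function(p) p$v))
  set.seed(1)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  pr1 <- predict_mask(m1, x)
  pr2 <- predict_mask(m2, x)
  expect_identical(pr1$labels, pr2$labels)
  expect_equal(dim(pr1$labels), c(32L, 32L))
  expect_true(all(pr1$labels %in% 0:1))
  expect_error(predict_mask(m1, array(0, c(32, 32, 5))), "channels")
})

test_that("count_parameters follows the convolution parameter formula", {
  conv <- hyperseg:::layer_conv(3L, 3L, 3L, 8L)
  expect_equal(hyperseg:::n_params(conv), 3 * 3 * 3 * 8 + 8)   # 224
  m <- build_model(tiny_model_config(), seed = 1)
  total <- count_parameters(m)
  # removing a sub-module reduces the count by exactly its own size
  head_n <- hyperseg:::n_params(m$modules$decoder$head)
  m$modules$decoder$head <- NULL
  expect_equal(count_parameters(m), total - head_n)
})

test_that("one backward pass reaches every parameter group (no dead branch)", {
  cfg <- tiny_model_config(input_size = 32L)
  m <- build_model(cfg, seed = 4)
  set.seed(5)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  y <- array(sample(0:1, 32 * 32, TRUE), c(32, 32))
  logits <- hyperseg:::model_forward(m, x, train = TRUE)
  loss <- hyperseg:::tn_combined_loss(logits, y)
  hyperseg:::tn_backward(loss)
  params <- hyperseg:::collect_params(m$modules)
  dead <- names(params)[vapply(params, function(p) {
    is.null(p$grad) || all(p$grad == 0)
  }, logical(1))]
  expect_identical(dead, character(0))
})

test_that("training is seeded, monotone under lr = 0, and checkpoints the best epoch", {
  data <- tiny_dataset(4L, size = 32L, seed = 6L)
  cfg <- tiny_model_config(input_size = 32L)

  run <- function(lr, epochs = 3L) {
    m <- build_model(cfg, seed = 8)
    ck <- train(m, data, train_config(lr = lr, epochs = epochs, seed = 9L))
    ck
  }
  ck1 <- run(0.01)
  ck2 <- run(0.01)
  expect_identical(ck1$history, ck2$history)          # same seed, same trajectory
  expect_equal(ck1$loss, min(ck1$history))
  expect_equal(ck1$epoch, which.min(ck1$history))

  ck0 <- run(0)                                        # lr = 0: loss frozen
  expect_equal(diff(ck0$history), rep(0, 2), tolerance = 1e-12)

  m <- build_model(cfg, seed = 8)
  expect_error(train(m, list(), train_config(epochs = 1L)), "empty")
})

test_that("checkpoints restore into a matching configuration only", {
  data <- tiny_dataset(2L, size = 32L, seed = 10L)
  cfg <- tiny_model_config(input_size = 32L)
  m <- build_model(cfg, seed = 1)
  ck <- train(m, data, train_config(epochs = 1L, seed = 2L))
  m2 <- build_model(cfg, seed = 99)
  load_checkpoint(m2, ck)
  expect_identical(predict_mask(m2, data[[1]]$x)$labels,
                   predict_mask(m, data[[1]]$x)$labels)
  other <- build_model(tiny_model_config(input_size = 64L), seed = 1)
  expect_error(load_checkpoint(other, ck), "fingerprint")
})

test_that("five-fold cross-validation trains on 4/5 and averages fold metrics", {
  data <- tiny_dataset(5L, size = 32L, seed = 12L)
  cfg <- tiny_model_config(input_size = 32L)
  res <- cross_validate(data, cfg, train_config(epochs = 1L, seed = 3L), seed = 4L)
  expect_length(res$folds, 5L)
  for (k in names(res$summary)) {
    expect_equal(res$summary[[k]],
                 mean(vapply(res$folds, function(f) f[[k]], numeric(1))))
  }
  split <- make_folds(5L, 4L)
  expect_equal(sort(as.vector(table(split$assignments))), rep(1L, 5))
})
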