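# Training protocol: SGD with momentum 0.9, weight decay 1e-6, batch size 4
# and constant learning rate 0.01; the compound Dice + cross-entropy loss;
# the checkpoint kept is the epoch with the lowest mean training loss.
# Five-fold cross-validation trains on 4/5 and evaluates pooled pixel
# confusion counts on the held-out 1/5, averaging the fold metrics.

#' Training configuration
#'
#' Defaults follow the published protocol: SGD, learning rate 0.01, momentum
#' 0.9, weight decay 1e-6, batch size 4; 45 epochs is the intestinal
#' metaplasia profile (use 60 for the intraepithelial-neoplasia profile).
#'
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size images per SGD step.
#' @param epochs number of passes over the data.
#' @param seed seed for shuffling/dropout.
#' @param weights a [loss_weights()] list.
#' @param log_file optional path receiving one JSON line per epoch.
#' @param verbose print per-epoch losses.
#' @return list of class `TrainConfig`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-6,
                         batch_size = 4L, epochs = 45L, seed = 1L,
                         weights = loss_weights(), log_file = NULL,
                         verbose = FALSE) {
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), weights = weights,
                 log_file = log_file, verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

# dataset items are lists with $x ([H, W, Cin] array) and $y ([H, W] labels)
check_dataset <- function(data, model) {
  if (length(data) == 0L) stop("empty training dataset")
  for (it in data) {
    if (is.null(it$x) || is.null(it$y)) stop("dataset items need fields x and y")
    if (dim(it$x)[3L] != model$config$in_channels) {
      stop("dataset channel count does not match the model")
    }
  }
  invisible(TRUE)
}

#' Train the network
#'
#' @param model a [build_model()] result (updated in place; the returned
#'   checkpoint also carries the best weights).
#' @param data list of items, each `list(x = [H,W,Cin] array, y = [H,W] labels)`.
#' @param config a [train_config()].
#' @return list of class `Checkpoint`: `weights` (best-epoch values), `epoch`,
#'   `loss` (its mean training loss), `history` (per-epoch mean losses),
#'   `fingerprint` (model config digest).
#' @export
train <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "SegModel"), inherits(config, "TrainConfig"))
  check_dataset(data, model)
  params <- collect_params(model$modules)
  opt <- sgd_init(params)
  set.seed(config$seed)
  n <- length(data)
  history <- numeric(config$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, weights = NULL)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    batch_losses <- c()
    i <- 1L
    while (i <= n) {
      idx <- perm[i:min(i + config$batch_size - 1L, n)]
      tn_zero_grad(params)
      bl <- 0
      for (j in idx) {
        it <- data[[j]]
        logits <- model_forward(model, it$x, train = TRUE)
        loss <- tn_combined_loss(logits, it$y, config$weights)
        if (!is.finite(loss$v)) {
          stop(sprintf("non-finite loss at epoch %d (item %d): aborting", epoch, j))
        }
        tn_backward(loss, 1 / length(idx))
        bl <- bl + loss$v / length(idx)
      }
      if (config$lr > 0) {
        opt <- sgd_step(opt, params, config$lr, config$momentum, config$weight_decay)
      }
      batch_losses <- c(batch_losses, bl)
      i <- i + config$batch_size
    }
    history[epoch] <- mean(batch_losses)
    if (config$verbose) {
      message(sprintf("epoch %3d  mean loss %.5f", epoch, history[epoch]))
    }
    if (!is.null(config$log_file)) {
      cat(jsonlite::toJSON(list(epoch = epoch, mean_loss = history[epoch],
                                lr = config$lr), auto_unbox = TRUE),
          "\n", file = config$log_file, append = TRUE, sep = "")
    }
    if (history[epoch] < best$loss) {
      best$loss <- history[epoch]
      best$epoch <- epoch
      best$weights <- params_snapshot(params)
    }
  }
  params_restore(params, best$weights)
  structure(list(weights = best$weights, epoch = best$epoch, loss = best$loss,
                 history = history, fingerprint = config_fingerprint(model$config)),
            class = "Checkpoint")
}

config_fingerprint <- function(cfg) {
  paste(vapply(cfg, function(v) paste(format(v), collapse = ","), character(1)),
        collapse = "|")
}

#' Load checkpoint weights into a model
#'
#' @param model a [build_model()] result built from the same configuration.
#' @param checkpoint a [train()] checkpoint.
#' @export
load_checkpoint <- function(model, checkpoint) {
  if (!identical(checkpoint$fingerprint, config_fingerprint(model$config))) {
    stop("checkpoint fingerprint does not match the model configuration")
  }
  params_restore(collect_params(model$modules), checkpoint$weights)
  invisible(model)
}

#' Evaluate a model on a dataset
#'
#' Pools pixel confusion counts over every item (micro aggregation) and
#' derives the four metrics.
#'
#' @param model a trained model.
#' @param data dataset as in [train()].
#' @param foreground_class lesion class label.
#' @return list with `counts` and `metrics`.
#' @export
evaluate_model <- function(model, data, foreground_class = 1L) {
  counts <- list(tp = 0, fp = 0, fn = 0, tn = 0, total = 0)
  for (it in data) {
    pred <- predict_mask(model, it$x)
    counts <- add_confusion(counts, confusion(pred$labels, it$y, foreground_class))
  }
  list(counts = counts, metrics = metrics(counts))
}

#' Five-fold cross-validation
#'
#' @param data dataset as in [train()] (>= 5 items).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param seed seed for the fold split and per-fold model initialization.
#' @return list with `folds` (per-fold metrics) and `summary` (their mean).
#' @export
cross_validate <- function(data, model_cfg, train_cfg, seed = 1L) {
  split <- make_folds(length(data), seed)
  fold_metrics <- vector("list", split$n_folds)
  for (f in seq_len(split$n_folds) - 1L) {
    test_idx <- which(split$assignments == f)
    train_idx <- setdiff(seq_along(data), test_idx)
    model <- build_model(model_cfg, seed = seed + f)
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    train(model, data[train_idx], cfg_f)
    fold_metrics[[f + 1L]] <- evaluate_model(model, data[test_idx])$metrics
  }
  nm <- names(fold_metrics[[1L]])
  summary <- lapply(stats::setNames(nm, nm), function(k) {
    mean(vapply(fold_metrics, function(m) m[[k]], numeric(1)))
  })
  list(folds = fold_metrics, summary = summary)
}
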