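#' Training configuration
#'
#' @param n_layers,n_heads architecture of the attention stack.
#' @param activation classification-layer activation (`"none"`,
#'   `"relu"`, `"gelu"`).
#' @param batch_size minibatch size (default 16).
#' @param epochs number of epochs (default 50).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param log_base log transform used in preprocessing.
#' @param normalize_on `"train"` fits the min-max statistics on the
#'   training split only and clips val/test (leakage-free default);
#'   `"all"` fits them on the full dataset before splitting.
#' @param seed seed governing initialization and batch shuffling.
#' @return list of class `tgem_config`.
#' @export
tgem_config <- function(n_layers = 1L, n_heads = 2L,
                        activation = c("none", "relu", "gelu"),
                        batch_size = 16L, epochs = 50L,
                        learning_rate = 1e-4,
                        log_base = c("log2p1", "ln1p"),
                        normalize_on = c("train", "all"),
                        seed = 0L) {
  activation <- match.arg(activation)
  log_base <- match.arg(log_base)
  normalize_on <- match.arg(normalize_on)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 activation = activation, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 log_base = log_base, normalize_on = normalize_on,
                 seed = as.integer(seed)),
            class = "tgem_config")
}

#' Train a T-GEM model
#'
#' Minimizes the mean negative log-likelihood of the true class with
#' Adam over minibatches, recording the training loss and validation
#' accuracy after every epoch, and returns the parameters of the epoch
#' with the best validation accuracy (ties broken toward the earliest
#' epoch). Preprocessing (log + per-gene min-max) statistics are fitted
#' on the training split only by default and reused, with clipping, for
#' validation and test data.
#'
#' @param dataset a [tgem_dataset()] with raw non-negative expression.
#' @param split list of index vectors `train`, `val`, `test` as produced
#'   by [stratified_split()].
#' @param config a [tgem_config()].
#' @return object of class `tgem_fit`: list with `model` (best-epoch
#'   `tgem_model`), `log` (data.frame epoch/train_loss/val_acc),
#'   `best_epoch`, `stats` (preprocessing statistics), `config` and
#'   `split`.
#' @export
tgem_train <- function(dataset, split, config = tgem_config()) {
  stopifnot(inherits(dataset, "tgem_dataset"))
  if (length(intersect(split$train, split$val)) ||
      length(intersect(split$train, split$test)) ||
      length(intersect(split$val, split$test)))
    stop("train/val/test splits must be disjoint")

  if (config$normalize_on == "all") {
    norm_all <- log_minmax_normalize(dataset$matrix, log_base = config$log_base)
    stats <- norm_all$stats
    X_train <- norm_all$matrix[split$train, , drop = FALSE]
    X_val <- norm_all$matrix[split$val, , drop = FALSE]
  } else {
    tr <- log_minmax_normalize(dataset$matrix[split$train, , drop = FALSE],
                               log_base = config$log_base)
    stats <- tr$stats
    X_train <- tr$matrix
    X_val <- log_minmax_normalize(dataset$matrix[split$val, , drop = FALSE],
                                  stats = stats)$matrix
  }
  y_train <- dataset$labels[split$train]
  y_val <- dataset$labels[split$val]

  model <- tgem_model(dataset$gene_names, dataset$class_names,
                      n_layers = config$n_layers, n_heads = config$n_heads,
                      activation = config$activation, seed = config$seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)

  theta <- .params_get(model)
  adam <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate

  n_tr <- length(split$train)
  log_df <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_acc = numeric(0))
  best_acc <- -Inf; best_theta <- theta; best_epoch <- NA_integer_

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n_tr)
    epoch_loss <- 0
    starts <- seq(1L, n_tr, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_tr)]
      gsum <- NULL
      batch_loss <- 0
      for (i in idx) {
        r <- .nll_grad_sample(model, as.numeric(X_train[i, ]), y_train[i] + 1L)
        batch_loss <- batch_loss + r$loss
        gi <- .grads_flatten(model, r$grads)
        gsum <- if (is.null(gsum)) gi else gsum + gi
      }
      gmean <- gsum / length(idx)
      if (any(!is.finite(gmean)) || !is.finite(batch_loss))
        stop(sprintf("non-finite loss/gradient at epoch %d, batch %d", epoch, bi))
      adam$t <- adam$t + 1L
      adam$m <- b1 * adam$m + (1 - b1) * gmean
      adam$v <- b2 * adam$v + (1 - b2) * gmean^2
      mhat <- adam$m / (1 - b1^adam$t)
      vhat <- adam$v / (1 - b2^adam$t)
      theta <- theta - lr * mhat / (sqrt(vhat) + aeps)
      model <- .params_set(model, theta)
      epoch_loss <- epoch_loss + batch_loss
    }
    val_pred <- predict(model, X_val)
    val_acc <- mean(val_pred == y_val)
    log_df <- rbind(log_df, data.frame(epoch = epoch,
                                       train_loss = epoch_loss / n_tr,
                                       val_acc = val_acc))
    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_theta <- theta
      best_epoch <- epoch
    }
  }

  structure(list(model = .params_set(model, best_theta), log = log_df,
                 best_epoch = best_epoch, stats = stats, config = config,
                 split = split),
            class = "tgem_fit")
}

#' @exportS3Method base::print
print.tgem_fit <- function(x, ...) {
  cat(sprintf("tgem_fit: best epoch %d (val acc %.3f) of %d\n",
              x$best_epoch, x$log$val_acc[x$best_epoch], nrow(x$log)))
  print(x$model)
  invisible(x)
}

#' Evaluate a fit on a held-out split
#'
#' Preprocesses the requested split with the fit's training statistics
#' and reports accuracy, multi-class Matthews correlation and macro
#' one-vs-rest AUC, plus the confusion matrix.
#'
#' @param fit a `tgem_fit`.
#' @param dataset the dataset the fit was trained on.
#' @param which which split to evaluate (`"test"`, `"val"` or `"train"`).
#' @return list with `acc`, `mcc`, `auc`, `confusion`.
#' @export
tgem_evaluate <- function(fit, dataset, which = "test") {
  idx <- fit$split[[which]]
  X <- log_minmax_normalize(dataset$matrix[idx, , drop = FALSE],
                            stats = fit$stats)$matrix
  y <- dataset$labels[idx]
  scores <- predict(fit$model, X, type = "prob")
  pred <- max.col(scores, ties.method = "first") - 1L
  conf <- confusion_matrix(y, pred, n_classes = length(dataset$class_names))
  list(acc = accuracy(conf), mcc = mcc(conf),
       auc = roc_auc(scores, y), confusion = conf)
}

#' Hyperparameter grid search
#'
#' Trains one model per grid point and selects the configuration with
#' the highest validation accuracy; ties are broken toward the model
#' with fewer parameters, then toward the earlier grid row. The default
#' grid is the full layers {1..4} x heads {1..5} x activation
#' {none, relu, gelu} search space; pass a smaller `expand.grid` for
#' desk-scale runs.
#'
#' @param dataset a `tgem_dataset`.
#' @param split a split list from [stratified_split()].
#' @param grid data.frame with columns `n_layers`, `n_heads`,
#'   `activation`.
#' @param base_config a [tgem_config()] supplying the remaining settings
#'   (batch size, epochs, learning rate, seed).
#' @return list with `best_config`, `best_fit`, and `table` (the grid
#'   with validation accuracy and parameter count per row).
#' @export
tgem_grid_search <- function(dataset, split,
                             grid = expand.grid(n_layers = 1:4, n_heads = 1:5,
                                                activation = c("none", "relu", "gelu"),
                                                stringsAsFactors = FALSE),
                             base_config = tgem_config()) {
  if (nrow(grid) < 1L) stop("grid must be non-empty")
  fits <- vector("list", nrow(grid))
  tab <- grid
  tab$val_acc <- NA_real_
  tab$n_params <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$n_layers <- as.integer(grid$n_layers[i])
    cfg$n_heads <- as.integer(grid$n_heads[i])
    cfg$activation <- as.character(grid$activation[i])
    fits[[i]] <- tgem_train(dataset, split, cfg)
    tab$val_acc[i] <- max(fits[[i]]$log$val_acc)
    tab$n_params[i] <- parameter_count(fits[[i]]$model)
  }
  best <- order(-tab$val_acc, tab$n_params, seq_len(nrow(tab)))[1]
  list(best_config = fits[[best]]$config, best_fit = fits[[best]], table = tab)
}
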