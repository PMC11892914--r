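#' Prepare standardized features and stratified splits
#'
#' Shuffles subjects, makes a stratified train/validation/test split, drops
#' constant columns, and standardizes every retained column to mean 0 and
#' unit variance using statistics fit on the training split only (the
#' validation and test splits are transformed with the training statistics,
#' never refit).
#'
#' @param features numeric matrix/data.frame, subjects in rows (species
#'   abundances and clinical parameters as columns).
#' @param labels binary labels, 0 = control, 1 = case.
#' @param split fractions for train/validation/test; must sum to 1.
#' @param seed integer seed for the shuffle.
#' @return list of class `feature_splits`: `train`, `val`, `test` (each a
#'   list with matrix `x` and vector `y`), `center`, `scale`, `dropped`
#'   (names of constant columns removed).
#' @export
prepare_features <- function(features, labels, split = c(0.6, 0.2, 0.2),
                             seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(labels)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (min(table(y)) < 10)
    stop("need >= 10 subjects per class for the default split")
  set.seed(seed)
  idx_tr <- idx_va <- idx_te <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    n_tr <- round(split[1] * n)
    n_va <- round(split[2] * n)
    n_te <- n - n_tr - n_va
    if (n_te < 1) stop("test split empty for class ", cl)
    idx_tr <- c(idx_tr, idx[seq_len(n_tr)])
    idx_va <- c(idx_va, idx[n_tr + seq_len(n_va)])
    idx_te <- c(idx_te, idx[n_tr + n_va + seq_len(n_te)])
  }
  const <- apply(x[idx_tr, , drop = FALSE], 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  ctr <- colMeans(x[idx_tr, , drop = FALSE])
  scl <- apply(x[idx_tr, , drop = FALSE], 2, stats::sd)
  std <- function(idx) list(
    x = scale(x[idx, , drop = FALSE], center = ctr, scale = scl),
    y = y[idx])
  structure(list(train = std(idx_tr), val = std(idx_va), test = std(idx_te),
                 center = ctr, scale = scl,
                 dropped = colnames(features)[const]),
            class = "feature_splits")
}

mlp_forward <- function(w, b, x) {
  act <- list(x)
  pre <- list()
  nl <- length(w)
  a <- x
  for (l in seq_len(nl)) {
    z <- a %*% w[[l]] + matrix(b[[l]], nrow(a), length(b[[l]]), byrow = TRUE)
    pre[[l]] <- z
    a <- if (l < nl) pmax(z, 0) else 1 / (1 + exp(-z))
    act[[l + 1]] <- a
  }
  list(act = act, pre = pre, out = as.numeric(a))
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train a multilayer-perceptron classifier
#'
#' Feed-forward network with ReLU hidden layers and a sigmoid output unit,
#' trained on binary cross-entropy by full-batch adaptive-moment (ADAM)
#' gradient descent with early stopping on validation loss (the best
#' validation-loss weights are kept). Deterministic under a fixed seed.
#'
#' @param train,val lists with `x` (standardized matrix) and `y` (0/1), as
#'   produced by [prepare_features()].
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param max_epochs maximum training epochs.
#' @param learning_rate ADAM step size.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed for weight initialisation.
#' @return object of class `mlp_fit` with weights, feature names, training
#'   history, and `metrics` (train/val accuracy and losses).
#' @export
train_mlp <- function(train, val = NULL, hidden_sizes = 16L,
                      max_epochs = 500L, learning_rate = 0.01,
                      patience = 25L, seed = 1L) {
  x <- as.matrix(train$x); y <- as.numeric(train$y)
  if (nrow(x) == 0) stop("empty training set")
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  dims <- c(ncol(x), hidden_sizes, 1L)
  nl <- length(dims) - 1L
  set.seed(seed)
  w <- lapply(seq_len(nl), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
           dims[l], dims[l + 1]))
  b <- lapply(seq_len(nl), function(l) numeric(dims[l + 1]))
  mw <- lapply(w, function(z) z * 0); vw <- mw
  mb <- lapply(b, function(z) z * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, w = w, b = b, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  n <- nrow(x)
  for (epoch in seq_len(max_epochs)) {
    fw <- mlp_forward(w, b, x)
    delta <- matrix((fw$out - y) / n, n, 1)
    gw <- vector("list", nl); gb <- vector("list", nl)
    for (l in rev(seq_len(nl))) {
      gw[[l]] <- crossprod(fw$act[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(w[[l]])) * (fw$pre[[l - 1]] > 0)
    }
    for (l in seq_len(nl)) {
      mw[[l]] <- b1 * mw[[l]] + (1 - b1) * gw[[l]]
      vw[[l]] <- b2 * vw[[l]] + (1 - b2) * gw[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
      mhw <- mw[[l]] / (1 - b1^epoch); vhw <- vw[[l]] / (1 - b2^epoch)
      mhb <- mb[[l]] / (1 - b1^epoch); vhb <- vb[[l]] / (1 - b2^epoch)
      w[[l]] <- w[[l]] - learning_rate * mhw / (sqrt(vhw) + eps)
      b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
    }
    monitor <- if (!is.null(val) && length(val$y))
      bce_loss(mlp_forward(w, b, as.matrix(val$x))$out, val$y)
    else bce_loss(mlp_forward(w, b, x)$out, y)
    history <- c(history, monitor)
    if (monitor < best$loss - 1e-8) {
      best <- list(loss = monitor, w = w, b = b, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  fit <- structure(list(weights = best$w, biases = best$b,
                        feature_names = colnames(x),
                        hidden_sizes = hidden_sizes,
                        best_epoch = best$epoch, history = history),
                   class = "mlp_fit")
  acc <- function(s) if (is.null(s) || !length(s$y)) NA_real_ else
    mean((stats::predict(fit, s$x) > 0.5) == (s$y == 1))
  fit$metrics <- list(train_accuracy = acc(train),
                      val_accuracy = acc(val),
                      val_loss = best$loss)
  fit
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  p <- mlp_forward(object$weights, object$biases, x)$out
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat("MLP classifier:", length(x$feature_names), "features, hidden layers (",
      paste(x$hidden_sizes, collapse = ", "), "), best epoch ",
      x$best_epoch, "\n", sep = "")
  cat(sprintf("train accuracy %.3f, validation accuracy %.3f\n",
              x$metrics$train_accuracy, x$metrics$val_accuracy))
  invisible(x)
}

#' Classification accuracy on a held-out split
#'
#' @param model an `mlp_fit`.
#' @param data list with `x`, `y`.
#' @return accuracy in `[0, 1]`.
#' @export
mlp_accuracy <- function(model, data) {
  mean(stats::predict(model, data$x, type = "class") == data$y)
}

#' Permutation feature contributions
#'
#' Model-agnostic contribution of each feature to test-set accuracy: each
#' feature column is permuted `n_repeats` times, the mean drop in accuracy
#' relative to the intact test set is recorded, negative drops are floored
#' at zero, and the drops are normalized to sum to 100%. If no feature
#' changes accuracy the mass is spread uniformly (with a warning).
#'
#' @param model fitted `mlp_fit` (any object with a `predict` method giving
#'   probabilities works).
#' @param test list with `x`, `y`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `contribution_table`: `feature`,
#'   `contribution_pct`, sorted descending.
#' @export
feature_contributions <- function(model, test, n_repeats = 50L, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  x <- as.matrix(test$x); y <- test$y
  base <- mean((stats::predict(model, x) > 0.5) == (y == 1))
  set.seed(seed)
  drops <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      base - mean((stats::predict(model, xp) > 0.5) == (y == 1))
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("no feature affects accuracy; contributions set uniform")
    drops <- rep(1, ncol(x))
  }
  out <- data.frame(feature = colnames(x),
                    contribution_pct = 100 * drops / sum(drops),
                    row.names = NULL)
  out <- out[order(-out$contribution_pct, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("contribution_table", "data.frame")
  out
}
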