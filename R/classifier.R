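#' Feed-forward network specification
#'
#' Hyperparameters of the classifier: a fully connected network with ReLU
#' hidden layers and a single sigmoid output, trained by backpropagation
#' on binary cross-entropy with the RMSprop optimizer.
#'
#' @param hidden Integer vector of hidden-layer widths (default `c(64, 32)`).
#' @param learning_rate RMSprop step size (default 1e-3).
#' @param rho RMSprop moving-average decay for squared gradients (default 0.9).
#' @param epochs Maximum training epochs (default 300).
#' @param batch_size Mini-batch size (default 32).
#' @param patience Early stopping: halt after this many epochs without
#'   improvement of the training loss (default 20).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `"mlp_spec"`.
#' @examples
#' mlp_spec()
#' mlp_spec(hidden = c(16), epochs = 100, seed = 42)
#' @export
mlp_spec <- function(hidden = c(64L, 32L), learning_rate = 1e-3, rho = 0.9,
                     epochs = 300L, batch_size = 32L, patience = 20L,
                     seed = 1L) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || any(hidden < 1L)) {
    stop("mlp_spec: need at least one hidden layer of positive width", call. = FALSE)
  }
  structure(list(hidden = hidden, learning_rate = learning_rate, rho = rho,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "mlp_spec")
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat(sprintf("<mlp_spec> hidden=[%s] relu, sigmoid out; RMSprop lr=%g; bce loss; epochs<=%d batch=%d patience=%d seed=%d\n",
              paste(x$hidden, collapse = ","), x$learning_rate, x$epochs,
              x$batch_size, x$patience, x$seed))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

init_layers <- function(sizes) {
  # He-normal fan-in scaling for the ReLU stack; last layer included
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L]) * sqrt(2 / sizes[l]),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

forward_pass <- function(X, W, b) {
  L <- length(W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    A[[l + 1L]] <- pmax(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"), 0)
  }
  z <- sweep(A[[L]] %*% W[[L]], 2, b[[L]], "+")
  A[[L + 1L]] <- sigmoid(z)
  A
}

#' Train the feed-forward classifier
#'
#' Fits the network of an [mlp_spec()] to a feature table by
#' backpropagation: binary cross-entropy loss, RMSprop updates, ReLU
#' hidden activations, sigmoid output. Features are standardized to the
#' training set's per-column mean and SD; the standardization is stored
#' with the model and re-applied at prediction time.
#'
#' @param data A feature tibble (e.g. from [extract_features()]) holding a
#'   `label` column plus numeric feature columns.
#' @param spec An [mlp_spec()].
#' @param label_col Name of the label column (default `"label"`).
#' @param positive The label treated as the positive class (default
#'   `"high"`).
#' @param feature_names Which columns are features; defaults to
#'   [feature_cols()] and falls back to every numeric column except
#'   `rating`/`class`.
#' @return A fitted model of class `"mmdisten_mlp"`: weights, biases,
#'   standardization parameters, loss trace, and the spec.
#' @examples
#' set.seed(1)
#' toy <- tibble::tibble(label = rep(c("low", "high"), each = 10),
#'                       s_1 = c(rnorm(10, 0), rnorm(10, 5)))
#' fit <- fit_mlp(toy, mlp_spec(hidden = 8, epochs = 100, seed = 1))
#' predict(fit, toy, type = "class")
#' @export
fit_mlp <- function(data, spec = mlp_spec(), label_col = "label",
                    positive = "high", feature_names = NULL) {
  stopifnot(inherits(spec, "mlp_spec"), label_col %in% names(data))
  if (is.null(feature_names)) {
    feature_names <- feature_cols(data)
    if (length(feature_names) == 0L) {
      feature_names <- setdiff(
        names(data)[vapply(data, is.numeric, logical(1))],
        c("rating", "class"))
    }
  }
  X <- as.matrix(data[feature_names])
  if (!all(is.finite(X))) stop("fit_mlp: non-finite feature values", call. = FALSE)
  y <- as.numeric(data[[label_col]] == positive)
  if (length(unique(y)) < 2L) {
    stop("fit_mlp: training data contains a single class", call. = FALSE)
  }
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("fit_mlp: need >= 2 examples of each class", call. = FALSE)
  }

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")

  fit <- withr::with_seed(spec$seed, train_rmsprop(Xs, y, spec))

  structure(list(W = fit$W, b = fit$b, center = mu, scale = sdv,
                 feature_names = feature_names, positive = positive,
                 loss = fit$loss, epochs_run = fit$epochs_run, spec = spec),
            class = "mmdisten_mlp")
}

train_rmsprop <- function(X, y, spec) {
  sizes <- c(ncol(X), spec$hidden, 1L)
  L <- length(sizes) - 1L
  par <- init_layers(sizes)
  W <- par$W; b <- par$b
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(b, function(v) v * 0)
  n <- nrow(X)
  eps <- 1e-8
  loss_trace <- numeric(0)
  best <- list(loss = Inf, W = W, b = b)
  stall <- 0L

  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    for (st in starts) {
      idx <- ord[st:min(st + spec$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      A <- forward_pass(Xb, W, b)
      # output delta of sigmoid + binary cross-entropy: (p - y) / batch
      delta <- (A[[L + 1L]] - yb) / length(yb)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        }
        vW[[l]] <- spec$rho * vW[[l]] + (1 - spec$rho) * gW^2
        vb[[l]] <- spec$rho * vb[[l]] + (1 - spec$rho) * gb^2
        W[[l]] <- W[[l]] - spec$learning_rate * gW / (sqrt(vW[[l]]) + eps)
        b[[l]] <- b[[l]] - spec$learning_rate * gb / (sqrt(vb[[l]]) + eps)
      }
    }
    p <- forward_pass(X, W, b)[[L + 1L]]
    loss <- bce_loss(p, y)
    loss_trace <- c(loss_trace, loss)
    if (loss < best$loss - 1e-6) {
      best <- list(loss = loss, W = W, b = b)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= spec$patience) break
    }
  }
  list(W = best$W, b = best$b, loss = loss_trace, epochs_run = length(loss_trace))
}

#' Predict from a fitted classifier
#'
#' @param object A fitted `"mmdisten_mlp"` from [fit_mlp()].
#' @param newdata A data frame holding the model's feature columns.
#' @param type `"prob"` for positive-class probabilities, `"class"` for
#'   thresholded labels (cut at 0.5).
#' @param ... Unused.
#' @return Numeric probabilities or a character vector of labels.
#' @export
predict.mmdisten_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$feature_names])
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  p <- as.numeric(forward_pass(Xs, object$W, object$b)[[length(object$W) + 1L]])
  if (type == "prob") return(p)
  ifelse(p > 0.5, object$positive, paste0("not_", object$positive))
}

#' @export
print.mmdisten_mlp <- function(x, ...) {
  cat(sprintf("<mmdisten_mlp> %d features -> [%s] -> 1; trained %d epochs, final bce %.4f\n",
              length(x$feature_names), paste(x$spec$hidden, collapse = ","),
              x$epochs_run, utils::tail(x$loss, 1)))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Precision, recall, F1 and accuracy in percent:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 TP/(2 TP + FP + FN)`, `accuracy = (TP+TN)/(TP+FP+TN+FN)`,
#' each multiplied by 100. A metric whose denominator is zero is reported
#' as 0 with `degenerate = TRUE` and a warning, so batch reports never
#' fail on an empty class.
#'
#' @param tp,fp,tn,fn Non-negative integer counts; total must be positive.
#' @return A one-row tibble: `tp, fp, tn, fn, precision, recall, f1,
#'   accuracy, degenerate`.
#' @examples
#' classification_metrics(3, 1, 4, 2)  # precision 75, recall 60, f1 66.67
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("classification_metrics: counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("classification_metrics: total count is zero", call. = FALSE)
  degenerate <- FALSE
  safe <- function(num, den, what) {
    if (den == 0) {
      degenerate <<- TRUE
      warning("classification_metrics: ", what,
              " undefined (zero denominator); reporting 0", call. = FALSE)
      return(0)
    }
    100 * num / den
  }
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = safe(tp, tp + fp, "precision"),
    recall = safe(tp, tp + fn, "recall"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "F1"),
    accuracy = 100 * (tp + tn) / sum(counts),
    degenerate = degenerate
  )
}

#' Stratified k-fold cross-validation
#'
#' Evaluates the classifier with stratified k-fold cross-validation:
#' trials of each class are dealt into `k` folds (seeded shuffle), and for
#' each fold a fresh network is trained on the remaining folds — feature
#' standardization is fit on the training split only, so no information
#' leaks into the held-out fold. Held-out probabilities are thresholded at
#' 0.5 and confusion counts and metrics are reported per fold and as mean
#' +/- SD.
#'
#' @inheritParams fit_mlp
#' @param k Number of folds (default 10). Each class must have at least
#'   `k` members.
#' @return A list of class `"cv_report"`: `folds` (per-fold tibble of
#'   confusion counts and metrics) and `summary` (mean and SD of each
#'   metric).
#' @examples
#' set.seed(1)
#' toy <- tibble::tibble(label = rep(c("low", "high"), each = 20),
#'                       s_1 = c(rnorm(20, 0), rnorm(20, 5)))
#' cross_validate(toy, mlp_spec(hidden = 8, epochs = 100, seed = 1), k = 4)
#' @export
cross_validate <- function(data, spec = mlp_spec(), k = 10L,
                           label_col = "label", positive = "high",
                           feature_names = NULL) {
  k <- as.integer(k)
  stopifnot(inherits(spec, "mlp_spec"), label_col %in% names(data))
  y <- data[[label_col]]
  class_counts <- table(y)
  if (length(class_counts) != 2L) {
    stop("cross_validate: need exactly two classes, got ",
         length(class_counts), call. = FALSE)
  }
  if (any(class_counts < k)) {
    stop(sprintf(
      "cross_validate: smallest class has %d members < k = %d folds; use a smaller k",
      min(class_counts), k), call. = FALSE)
  }
  folds <- withr::with_seed(spec$seed, stratified_folds(y, k))

  fold_rows <- purrr::map(seq_len(k), function(f) {
    test_idx <- which(folds == f)
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f
    fit <- fit_mlp(data[-test_idx, , drop = FALSE], fold_spec,
                   label_col = label_col, positive = positive,
                   feature_names = feature_names)
    pred <- predict(fit, data[test_idx, , drop = FALSE], type = "prob")
    truth <- y[test_idx] == positive
    call <- pred > 0.5
    m <- classification_metrics(sum(call & truth), sum(call & !truth),
                                sum(!call & !truth), sum(!call & truth))
    dplyr::bind_cols(tibble::tibble(fold = f, n_test = length(test_idx)), m)
  })
  folds_tbl <- dplyr::bind_rows(fold_rows)

  metric_cols <- c("precision", "recall", "f1", "accuracy")
  summary_tbl <- tidyr::pivot_longer(folds_tbl[metric_cols],
                                     dplyr::everything(),
                                     names_to = "metric", values_to = "value")
  summary_tbl <- dplyr::summarise(dplyr::group_by(summary_tbl, metric),
                                  mean = mean(value), sd = stats::sd(value),
                                  .groups = "drop")
  summary_tbl$metric <- factor(summary_tbl$metric, levels = metric_cols)
  summary_tbl <- dplyr::arrange(summary_tbl, metric)
  summary_tbl$metric <- as.character(summary_tbl$metric)

  structure(list(folds = folds_tbl, summary = summary_tbl, k = k,
                 positive = positive, spec = spec),
            class = "cv_report")
}

# deal each class's shuffled indices round-robin into k folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified cross-validation (positive = '%s')\n",
              x$k, x$positive))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %6.2f%% +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write a cross-validation report as CSV
#'
#' One row per fold (confusion counts + metrics) followed by summary rows
#' (`mean`, `sd`).
#'
#' @param report A `"cv_report"` from [cross_validate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  folds <- as.data.frame(report$folds)
  folds$fold <- as.character(folds$fold)
  metric_cols <- c("precision", "recall", "f1", "accuracy")
  pad <- function(label, values) {
    row <- folds[1, ]
    row[] <- NA
    row$fold <- label
    row[metric_cols] <- as.list(values)
    row
  }
  s <- report$summary
  out <- rbind(folds,
               pad("mean", s$mean[match(metric_cols, s$metric)]),
               pad("sd", s$sd[match(metric_cols, s$metric)]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
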