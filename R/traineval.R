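# Training loop, evaluation metrics and confusion-matrix reports.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, batch size 32, learning
#' rate 0.0025, 100 epochs, dropout handled by the model config. The loss is
#' the negative log-likelihood on the model's log-softmax output (the only
#' loss coherent with log-probability outputs). No early stopping: training
#' always runs the configured number of epochs.
#'
#' @param batch_size Samples per gradient step (default 32).
#' @param learning_rate Adam step size (default 0.0025).
#' @param epochs Number of passes over the training set (default 100).
#' @param seed Integer seed covering shuffling and dropout.
#' @param weight_classes Apply inverse-frequency class weights to the loss
#'   (default `FALSE`; the reference protocol uses no reweighting).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32, learning_rate = 0.0025,
                         epochs = 100, seed = 1, weight_classes = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, seed = seed,
                 weight_classes = weight_classes),
            class = "train_config")
}

dataset_to_batch <- function(ds) {
  mats <- lapply(ds$tensors, function(ft) ft$values)
  t_lens <- vapply(mats, nrow, integer(1))
  if (length(unique(t_lens)) != 1) {
    abort("train: sequences have differing lengths; apply regularize_length first")
  }
  x <- array(0, unname(c(length(mats), t_lens[1], ncol(mats[[1]]))))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  list(x = x, labels = ds$items$label)
}

#' Train a TCN-ResNet18 model
#'
#' Minimizes the negative log-likelihood with Adam. Fully reproducible: the
#' weight initialization runs under the model config's seed and shuffling /
#' dropout under the training config's seed. Aborts with a diagnostic
#' naming the epoch and batch if the loss becomes non-finite.
#'
#' @param train_ds A `labeled_dataset` whose tensors all share one length.
#' @param config A [model_config()]; `n_classes` must cover the labels.
#' @param tc A [train_config()].
#' @param verbose Print per-epoch loss/accuracy (default `FALSE`).
#' @return A `kinedep_fit`: list with `model`, `history` (tibble `epoch`,
#'   `loss`, `accuracy`), and the two configs.
#' @export
train_model <- function(train_ds, config = model_config(),
                        tc = train_config(), verbose = FALSE) {
  if (nrow(train_ds$items) == 0) abort("train: empty training set")
  batch <- dataset_to_batch(train_ds)
  n <- dim(batch$x)[1]
  if (max(batch$labels) + 1 > config$n_classes) {
    abort("train: labels exceed n_classes")
  }
  model <- init_model(config)
  opt <- adam_init(model$params)
  weights <- NULL
  if (tc$weight_classes) {
    freq <- table(factor(batch$labels, levels = 0:(config$n_classes - 1)))
    w_by_class <- as.numeric(sum(freq) / (length(freq) * pmax(freq, 1)))
    weights <- w_by_class[batch$labels + 1]
  }
  history <- vector("list", tc$epochs)
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = tc$batch_size)
      ep_loss <- 0
      ep_correct <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + tc$batch_size - 1, n)]
        xb <- batch$x[idx, , , drop = FALSE]
        yb <- batch$labels[idx]
        fwd <- model_forward(model, xb, training = TRUE)
        model$bn_state <- fwd$bn_state
        ls <- nll_loss(fwd$logp, yb,
                       if (is.null(weights)) NULL else weights[idx])
        if (!is.finite(ls$loss)) {
          abort(sprintf("train: non-finite loss at epoch %d, batch %d",
                        epoch, bi))
        }
        grads <- model_backward(ls$dlogp, fwd$caches, model)
        step <- adam_step(model$params, grads, opt, tc$learning_rate)
        model$params <- step$params
        opt <- step$opt
        ep_loss <- ep_loss + ls$loss * length(idx)
        pred <- apply(fwd$logp, 1, which.max) - 1L
        ep_correct <- ep_correct + sum(pred == yb)
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                        epoch, ep_loss / n, ep_correct / n))
      }
    }
  })
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         model_config = config, train_config = tc,
         class_names = train_ds$class_names),
    class = "kinedep_fit"
  )
}

#' @export
print.kinedep_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<kinedep_fit> %d epochs; final train loss %.4f, accuracy %.3f\n",
    nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. Accuracy is
#' trace/total. For the binary task (classes ordered non-depression,
#' depression) sensitivity is the recall on the depressed class
#' TP/(TP+FN), specificity the recall on the non-depressed class
#' TN/(TN+FP), and precision TP/(TP+FP). A metric whose denominator is
#' zero (class absent) is `NA`, not 0. All rates are percentages.
#'
#' @param cm Square integer matrix of counts (rows = true).
#' @param task `"binary"` or `"multi"`.
#' @return List of `accuracy`, `sensitivity`, `specificity`, `precision`
#'   (binary only) and `per_class_recall`.
#' @export
metrics_from_confusion <- function(cm, task = c("binary", "multi")) {
  task <- match.arg(task)
  cm <- as.matrix(cm)
  total <- sum(cm)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- rate(sum(diag(cm)), total)
  supports <- rowSums(cm)
  recalls <- ifelse(supports > 0, 100 * diag(cm) / supports, NA_real_)
  names(recalls) <- rownames(cm)
  out <- list(accuracy = acc, per_class_recall = recalls)
  if (task == "binary") {
    tp <- cm[2, 2]; fn <- cm[2, 1]; tn <- cm[1, 1]; fp <- cm[1, 2]
    out$sensitivity <- rate(tp, tp + fn)
    out$specificity <- rate(tn, tn + fp)
    out$precision <- rate(tp, tp + fp)
  } else {
    out$sensitivity <- NA_real_
    out$specificity <- NA_real_
    out$precision <- NA_real_
  }
  out
}

#' Evaluate a model on a labeled dataset
#'
#' Side-effect free and deterministic (evaluation mode). Builds the
#' confusion matrix (rows = true, columns = predicted) and the metric set
#' of [metrics_from_confusion()].
#'
#' @param fit A `kinedep_fit` (or a bare `kinedep_model`).
#' @param test_ds A `labeled_dataset`.
#' @return An `eval_report`: list with `task`, `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `per_class_recall`, `n`,
#'   `predictions` (tibble).
#' @export
evaluate_model <- function(fit, test_ds) {
  model <- if (inherits(fit, "kinedep_fit")) fit$model else fit
  if (nrow(test_ds$items) == 0) abort("evaluate: empty test set")
  batch <- dataset_to_batch(test_ds)
  # batched forward in eval mode to bound memory
  n <- dim(batch$x)[1]
  preds <- integer(n)
  starts <- seq(1, n, by = 32)
  for (s in starts) {
    idx <- s:min(s + 31, n)
    out <- model_forward(model, batch$x[idx, , , drop = FALSE],
                         training = FALSE)
    preds[idx] <- apply(out$logp, 1, which.max) - 1L
  }
  k <- length(test_ds$class_names)
  cm <- table(
    factor(batch$labels, levels = 0:(k - 1)),
    factor(preds, levels = 0:(k - 1))
  )
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(true = test_ds$class_names,
                               predicted = test_ds$class_names))
  met <- metrics_from_confusion(cm, test_ds$task)
  structure(
    c(list(task = test_ds$task, confusion = cm, n = n,
           predictions = tibble::tibble(
             subject_id = test_ds$items$subject_id,
             true = batch$labels, predicted = preds)),
      met),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s task, n = %d\n", x$task, x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.1f%%", x$accuracy))
  if (x$task == "binary") {
    cat(sprintf(", sensitivity %.1f%%, specificity %.1f%%",
                x$sensitivity, x$specificity))
  }
  cat("\n")
  invisible(x)
}
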