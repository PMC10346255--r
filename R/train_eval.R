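#' Train/validation/test split specification
#'
#' Stratified splitting in the conventional 70/30 layout: `test_frac` of
#' every class goes to the test set and `val_frac_of_train` of the remaining
#' training samples to the validation set, preserving class proportions.
#'
#' @param test_frac Fraction of each class assigned to the test set.
#' @param val_frac_of_train Fraction of the training remainder assigned to
#'   validation.
#' @param stratified Preserve per-class proportions? (`FALSE` splits the
#'   pooled index set.)
#' @param seed Integer seed; identical seeds give identical index sets.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_frac = 0.3, val_frac_of_train = 0.3,
                       stratified = TRUE, seed = 0L) {
  stopifnot(test_frac > 0, test_frac < 1,
            val_frac_of_train > 0, val_frac_of_train < 1)
  structure(list(test_frac = test_frac,
                 val_frac_of_train = val_frac_of_train,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

# Per-class allocation with largest-remainder correction: per-class counts
# floor(frac * n_c), then +1 to the classes with the largest fractional
# remainders (ties broken by class order) until round(frac * n) is reached.
largest_remainder <- function(n_per_class, frac) {
  ideal <- frac * n_per_class
  base <- floor(ideal)
  add <- round(frac * sum(n_per_class)) - sum(base)
  if (add > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(add)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits sample indices by class so each split's class proportions match
#' the full set within one sample per class. Disjoint and exhaustive;
#' deterministic under the spec's seed.
#'
#' @param labels Vector (or factor) of class labels, one per sample; every
#'   class needs at least 3 members.
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 3)) {
    abort(sprintf("Class '%s' has only %d sample(s); at least 3 are needed.",
                  names(counts)[which(counts < 3)[1]],
                  min(counts)))
  }
  if (!spec$stratified) {
    labels <- factor(rep("all", length(labels)))
    counts <- table(labels)
  }
  n_test <- largest_remainder(as.numeric(counts), spec$test_frac)
  n_val <- largest_remainder(as.numeric(counts) - n_test,
                             spec$val_frac_of_train)
  with_seed(spec$seed, {
    test <- integer(); val <- integer(); train <- integer()
    for (k in seq_along(counts)) {
      idx <- which(labels == names(counts)[k])
      idx <- idx[sample.int(length(idx))]
      test <- c(test, idx[seq_len(n_test[k])])
      rest <- idx[-seq_len(n_test[k])]
      val <- c(val, rest[seq_len(n_val[k])])
      train <- c(train, rest[-seq_len(n_val[k])])
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  })
}

#' Train a network on labeled input tensors
#'
#' Minimizes categorical cross-entropy with Adam on mini-batches, recording
#' per-epoch training and validation loss/accuracy. Inputs are standardized
#' with a single mean/scale computed from the training split (stored on the
#' returned model and reapplied by [predict.irdc_net()]), which preserves
#' the relative channel-activation pattern that distinguishes gestures.
#' Fully seeded: identical inputs and seeds give identical weights and
#' history.
#'
#' @param net An `irdc_net` from [build_irdc_net()] or [build_variant()].
#' @param x Input array `n_channels x input_length x n_samples`.
#' @param y Class labels (factor or integer), one per sample.
#' @param train_idx,val_idx Disjoint index vectors into the samples of `x`.
#' @param epochs,batch_size,learning_rate Optimizer settings.
#' @param seed Integer seed for shuffling and dropout.
#' @param standardize Standardize inputs from the training split?
#' @return The model with `history` (tibble: epoch, train/val loss and
#'   accuracy), `scaler`, and `class_levels` attached. The native network is
#'   updated in place.
#' @export
fit_network <- function(net, x, y, train_idx, val_idx = integer(),
                        epochs = 30, batch_size = 32, learning_rate = 1e-3,
                        seed = 0L, standardize = TRUE) {
  stopifnot(inherits(net, "irdc_net"), length(dim(x)) == 3)
  if (length(intersect(train_idx, val_idx))) {
    abort("Training and validation indices overlap.")
  }
  if (length(train_idx) == 0) abort("Empty training split.")
  y <- as.factor(y)
  if (nlevels(y) > net$config$n_classes) {
    abort(sprintf("%d classes in labels but the network has %d outputs.",
                  nlevels(y), net$config$n_classes))
  }
  if (standardize) {
    center <- mean(x[, , train_idx])
    scale <- sd(x[, , train_idx])
    if (scale == 0) scale <- 1
  } else {
    center <- 0; scale <- 1
  }
  xs <- (x - center) / scale
  y0 <- as.integer(y) - 1L
  hist <- nn_train(net$ptr,
                   xs[, , train_idx, drop = FALSE], y0[train_idx],
                   xs[, , val_idx, drop = FALSE], y0[val_idx],
                   as.integer(epochs), as.integer(batch_size),
                   learning_rate, as.integer(seed))
  net$scaler <- list(center = center, scale = scale)
  net$class_levels <- levels(y)
  net$history <- tibble(epoch = seq_len(nrow(hist)),
                        train_loss = hist[, 1], train_acc = hist[, 2],
                        val_loss = hist[, 3], val_acc = hist[, 4])
  net
}

#' Classification metrics from predicted and true labels
#'
#' Builds the confusion matrix (rows = true classes, columns = predicted)
#' and the per-class precision, recall, and F1 with zero-denominator cases
#' reported as 0 and flagged.
#'
#' @param truth True labels (factor or values coercible to one).
#' @param pred Predicted labels on the same levels.
#' @param levels Optional explicit class levels.
#' @return An `eval_report`: list with `accuracy`, `per_class` (tibble),
#'   `macro` (one-row tibble of unweighted means), `confusion` (matrix),
#'   `n`, and `undefined` (classes with zero-denominator precision or
#'   recall).
#' @export
eval_metrics <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  if (anyNA(pred) || anyNA(truth)) {
    abort("Labels outside the declared class set.")
  }
  cm <- table(truth = truth, pred = pred)
  cm <- matrix(as.integer(cm), nrow = nlevels(truth),
               dimnames = dimnames(cm))
  tp <- diag(cm)
  prec_den <- colSums(cm); rec_den <- rowSums(cm)
  precision <- ifelse(prec_den > 0, tp / prec_den, 0)
  recall <- ifelse(rec_den > 0, tp / rec_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble(class = levels, n = as.integer(unname(rec_den)),
                      precision = unname(precision), recall = unname(recall),
                      f1 = unname(f1))
  structure(list(
    accuracy = sum(tp) / sum(cm),
    per_class = per_class,
    macro = tibble(precision = mean(precision), recall = mean(recall),
                   f1 = mean(f1)),
    confusion = cm, n = sum(cm),
    undefined = levels[prec_den == 0 | rec_den == 0]),
    class = "eval_report")
}

#' Evaluate a trained network on a test set
#'
#' Predicts class probabilities, takes the arg-max label, and scores against
#' the truth with [eval_metrics()].
#'
#' @param net A trained `irdc_net`.
#' @param x Input array `n_channels x input_length x n_samples`.
#' @param y True labels.
#' @return An `eval_report`.
#' @export
evaluate_network <- function(net, x, y) {
  stopifnot(inherits(net, "irdc_net"))
  if (length(dim(x)) != 3 || dim(x)[3] == 0) abort("Empty test set.")
  levels <- net$class_levels %||% levels(as.factor(y))
  y <- factor(as.character(as.factor(y)), levels = levels)
  if (anyNA(y)) abort("Test labels outside the model's class set.")
  p <- predict(net, x)
  pred <- factor(levels[max.col(p, ties.method = "first")], levels = levels)
  eval_metrics(y, pred, levels = levels)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d samples (%d classes)\n",
              x$accuracy, x$n, nrow(x$per_class)))
  cat(sprintf("  macro precision %.4f, recall %.4f, F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  if (length(x$undefined)) {
    cat("  zero-denominator classes:", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro$precision,
         macro_recall = x$macro$recall, macro_f1 = x$macro$f1, n = x$n)
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class")
}

#' Loss/accuracy curves of a training history
#'
#' @param history The `history` tibble of a fitted model.
#' @return A ggplot object with one panel per metric.
#' @export
plot_history <- function(history) {
  df <- tidyr::pivot_longer(history, -"epoch",
                            names_to = c("split", "metric"),
                            names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(y = NULL)
}
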