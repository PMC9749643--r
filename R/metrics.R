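#' Confusion matrix and classification metric suite
#'
#' The multipotent (\code{Positive}) class is the positive class. Accuracy,
#' sensitivity, specificity and F1 are computed from the confusion counts;
#' AUC is the area under the full ROC curve by the trapezoidal rule over the
#' positive-class scores. With single-class truth the AUC is undefined and
#' reported as \code{NA}.
#'
#' @param truth Character/factor vector of \code{"Positive"}/\code{"Negative"}.
#' @param predicted Same levels, same length.
#' @param scores Optional positive-class scores in \code{[0, 1]} for the AUC.
#' @return Object of class \code{eval_report}: \code{confusion} (named TP,
#'   FP, FN, TN), \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{f1}, \code{auc}, \code{n}.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == "Positive" & predicted == "Positive")
  fp <- sum(truth == "Negative" & predicted == "Positive")
  fn <- sum(truth == "Positive" & predicted == "Negative")
  tn <- sum(truth == "Negative" & predicted == "Negative")
  n <- length(truth)
  auc <- if (!is.null(scores) && length(unique(truth)) == 2L)
    roc_auc(truth == "Positive", scores) else NA_real_
  structure(list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    auc = auc, n = n), class = "eval_report")
}

# Trapezoidal AUC over the full ROC swept across all score thresholds.
roc_auc <- function(positive, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  # group ties so tied scores move diagonally
  runs <- rle(scores[ord])$lengths
  ends <- cumsum(runs)
  tp <- cumsum(pos)[ends]; fp <- cumsum(!pos)[ends]
  tpr <- c(0, tp / sum(positive))
  fpr <- c(0, fp / sum(!positive))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n=%d  TP=%d FP=%d FN=%d TN=%d\n", x$n, x$confusion[["TP"]],
              x$confusion[["FP"]], x$confusion[["FN"]], x$confusion[["TN"]]))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  f1 %.3f  auc %s\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Render a metric as \code{"mean ± sd"} at three decimals
#'
#' @param values Numeric vector (e.g. per-fold metric values).
#' @return Character scalar like \code{"0.838 ± 0.016"}.
#' @export
format_mean_sd <- function(values) {
  sprintf("%.3f ± %.3f", mean(values), stats::sd(values))
}

#' Stratified k-fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id in \code{1..k} per item; each class is spread as
#'   evenly as possible across folds.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  if (any(table(labels) < k)) stop("every class needs at least k items")
  folds <- integer(length(labels))
  offset <- 0L
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold between classes so remainders cancel and
      # total fold sizes stay as even as possible
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Each fold serves once as the test set; within each training fold a
#' fraction (default 1/8, keeping the overall proportions near 70/10/20) is
#' held out for early stopping. Per-fold metrics and their mean and sd are
#' reported.
#'
#' @param dataset A \code{labeled_dataset} (splits are ignored; folds are
#'   drawn fresh). Augmented items are excluded from fold assignment.
#' @param k Number of folds (>= 2).
#' @param config A [train_config()].
#' @param spec A [model_spec()] used for each fold's fresh model.
#' @param val_fraction Fraction of each training fold held out for early
#'   stopping.
#' @param augment Apply the deterministic 4-fold augmentation to each fold's
#'   training items.
#' @param seed Master seed (fold assignment, per-fold init).
#' @return List of class \code{cv_report}: \code{folds} (per-fold
#'   \code{eval_report}), \code{summary} (data frame metric / mean / sd /
#'   formatted), \code{fold_sizes}.
#' @export
crossvalidate <- function(dataset, k = 5L, config = train_config(),
                          spec = NULL, val_fraction = 1 / 8,
                          augment = TRUE, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  base <- which(!dataset$augmented)
  y <- as.character(dataset$y)[base]
  folds <- make_stratified_folds(y, k, seed = derive_seed(seed, "folds"))
  if (is.null(spec))
    spec <- model_spec(input_side = dataset$side,
                       channels = dim(dataset$x)[3])
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- base[folds == f]
    pool <- base[folds != f]
    vs <- make_stratified_folds(as.character(dataset$y)[pool],
                                k = max(2L, round(1 / val_fraction)),
                                seed = derive_seed(seed, paste0("val", f)))
    val_idx <- pool[vs == 1L]
    train_idx <- pool[vs != 1L]
    sub <- dataset
    keep <- c(train_idx, val_idx, test_idx)
    sub$x <- dataset$x[, , , keep, drop = FALSE]
    sub$y <- dataset$y[keep]
    sub$split <- factor(rep(c("train", "val", "test"),
                            c(length(train_idx), length(val_idx),
                              length(test_idx))),
                        levels = c("train", "val", "test"))
    sub$augmented <- rep(FALSE, length(keep))
    sub$origin <- dataset$origin[keep]
    sub$donor_id <- dataset$donor_id[keep]
    sub$label_statistic <- dataset$label_statistic[keep]
    if (augment) sub <- augment_train(sub)
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("fit", f))
    model <- build_model(spec, seed = derive_seed(seed, paste0("init", f)))
    model <- train_cnn(model, sub, cfg)
    te <- which(sub$split == "test")
    pred <- predict_cells(model, sub$x[, , , te, drop = FALSE])
    reports[[f]] <- compute_metrics(sub$y[te], pred$label,
                                    pred$prob_positive)
  }
  metrics <- c("accuracy", "sensitivity", "specificity", "f1", "auc")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], 0)
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               formatted = format_mean_sd(v), stringsAsFactors = FALSE)
  }))
  structure(list(folds = reports, summary = summ,
                 fold_sizes = as.integer(table(folds))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (fold sizes: %s)\n",
              length(x$folds), paste(x$fold_sizes, collapse = ", ")))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %s\n", x$summary$metric[i], x$summary$formatted[i]))
  invisible(x)
}
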