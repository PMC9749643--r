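# a small strongly-coupled dataset at reduced resolution for fast training
toy_dataset <- function() {
  cached("toy_dataset", {
    coh <- generate_cohort(list(donor_profile("T1", 40L, 0.6, 1),
                                donor_profile("T2", 40L, 0.4, 1)),
                           seed = 111)
    det <- detect_cohort(coh, "mask")
    ds <- build_labeled_dataset(det$crops, det$table$donor_id, seed = 7,
                                side = 56L)
    augment_train(ds)
  })
}

test_that("the classifier head follows the fixed seven-layer order", {
  m <- build_model(model_spec(), seed = 1)
  expect_identical(head_layers(m),
                   c("dropout", "global_max_pool", "dropout", "dense_relu",
                     "batch_norm", "dropout", "dense_softmax"))
  expect_identical(m$spec$dropout, 0.4)
  dr <- Filter(function(l) l$type == "dropout", m$layers)
  expect_true(all(vapply(dr, `[[`, 0, "p") == 0.4))
  expect_error(model_spec(filters = c(8, 16)), "three")
  expect_error(model_spec(dropout = 1.2), "dropout")
})

test_that("forward passes give probability rows that are deterministic in eval mode", {
  m <- build_model(model_spec(input_side = 56L, working_side = 28L), seed = 2)
  x <- with_seed(5, array(stats::runif(56 * 56 * 1 * 4), c(56L, 56L, 1L, 4L)))
  p1 <- model_probs(m, x)
  p2 <- model_probs(m, x)
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
  expect_identical(p1, p2)                    # dropout off at inference
  expect_true(all(p1 >= 0 & p1 <= 1))
  # duplicated input -> identical prediction
  xdup <- x[, , , c(1L, 1L), drop = FALSE]
  pd <- predict_cells(m, xdup)
  expect_identical(pd$prob_positive[1L], pd$prob_positive[2L])
  expect_identical(nrow(pd), 2L)
})

test_that("training configuration validates and early stopping obeys patience", {
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(patience = 50, max_epochs = 50), "patience")

  ds <- toy_dataset()
  # a divergent learning rate plateaus validation loss from the start:
  # training must stop by best_epoch + patience
  m <- build_model(model_spec(input_side = 56L, working_side = 28L), seed = 3)
  tr <- train_cnn(m, ds, train_config(learning_rate = 25, max_epochs = 20L,
                                      patience = 3L, seed = 1))
  expect_lte(nrow(tr$history), tr$best_epoch + 3L)
  expect_lte(nrow(tr$history), 20L)
  # restored weights correspond to the minimum validation loss seen
  expect_equal(min(tr$history$val_loss),
               tr$history$val_loss[tr$best_epoch])
  ds_noval <- ds
  ds_noval$split[] <- "train"
  expect_error(train_cnn(m, ds_noval, train_config()), "splits")
})

test_that("the classifier overfits a strongly coupled toy set", {
  ds <- toy_dataset()
  m <- build_model(model_spec(input_side = 56L, working_side = 28L), seed = 4)
  tr <- train_cnn(m, ds, train_config(learning_rate = 1e-3, max_epochs = 30L,
                                      patience = 30L %/% 2, seed = 11))
  idx <- which(ds$split == "train" & !ds$augmented)
  pr <- predict_cells(tr, ds$x[, , , idx, drop = FALSE])
  acc <- mean(pr$label == as.character(ds$y[idx]))
  expect_gte(acc, 0.95)
  expect_lte(nrow(tr$history), 50L)
})

test_that("metric identities hold against a brute-force recount", {
  with_seed(41, {
    truth <- sample(c("Positive", "Negative"), 500, replace = TRUE)
    scores <- stats::runif(500)
    pred <- ifelse(scores > 0.5, "Positive", "Negative")
  })
  r <- compute_metrics(truth, pred, scores)
  tp <- sum(truth == "Positive" & pred == "Positive")
  fp <- sum(truth == "Negative" & pred == "Positive")
  fn <- sum(truth == "Positive" & pred == "Negative")
  tn <- sum(truth == "Negative" & pred == "Negative")
  expect_identical(unname(r$confusion), c(tp, fp, fn, tn))
  expect_identical(sum(r$confusion), 500L)
  expect_equal(r$accuracy, (tp + tn) / 500)
  expect_equal(r$sensitivity, tp / (tp + fn))
  expect_equal(r$specificity, tn / (tn + fp))
  expect_equal(r$f1, 2 * tp / (2 * tp + fp + fn))
})

test_that("degenerate and reference confusion cases are exact", {
  perfect <- compute_metrics(c("Positive", "Negative"),
                             c("Positive", "Negative"), c(0.9, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  truth <- rep(c("Positive", "Negative"), c(1254L, 596L))
  allpos <- compute_metrics(truth, rep("Positive", 1850L))
  expect_equal(allpos$accuracy, 1254 / 1850)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)

  single <- compute_metrics(rep("Positive", 5L), rep("Positive", 5L),
                            runif(5))
  expect_true(is.na(single$auc))
})

test_that("AUC is 0.5 under random scores and invariant to monotone maps", {
  with_seed(43, {
    truth <- sample(c("Positive", "Negative"), 4000, replace = TRUE)
    scores <- stats::runif(4000)
  })
  r <- compute_metrics(truth, rep("Negative", 4000), scores)
  expect_lt(abs(r$auc - 0.5), 0.02)
  r2 <- compute_metrics(truth, rep("Negative", 4000), plogis(5 * scores - 2))
  expect_equal(r$auc, r2$auc)
  # pairwise concordance oracle on a small case
  with_seed(44, {
    tr <- sample(c("Positive", "Negative"), 60, replace = TRUE)
    sc <- stats::runif(60)
  })
  pos <- sc[tr == "Positive"]; neg <- sc[tr == "Negative"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(compute_metrics(tr, tr, sc)$auc, mean(pairs))
})

test_that("stratified folds partition every class evenly", {
  y <- rep(c("Positive", "Negative"), c(1254L, 596L))
  f <- make_stratified_folds(y, k = 5L, seed = 2)
  expect_identical(as.integer(table(f)), rep(370L, 5L))
  for (k in 1:5) {
    npos <- sum(y == "Positive" & f == k)
    expect_lte(abs(npos - 1254 / 5), 1)
  }
  expect_identical(f, make_stratified_folds(y, k = 5L, seed = 2))
  expect_error(make_stratified_folds(c("A", "B", "B"), k = 2L), "at least")
})

test_that("mean-sd rendering matches the reference table format", {
  v <- c(0.838 - 0.016 / sqrt(2), 0.838 + 0.016 / sqrt(2))
  expect_identical(format_mean_sd(v), "0.838 ± 0.016")
})

test_that("cross-validation tests each item exactly once", {
  ds <- toy_dataset()
  cv <- crossvalidate(ds, k = 2L,
                      config = train_config(learning_rate = 1e-3,
                                            max_epochs = 3L, patience = 2L),
                      spec = model_spec(input_side = 56L,
                                        working_side = 28L),
                      augment = FALSE, seed = 5)
  n_base <- sum(!ds$augmented)
  expect_identical(sum(cv$fold_sizes), n_base)
  expect_identical(length(cv$folds), 2L)
  expect_identical(sum(vapply(cv$folds, function(r) r$n, 0L)), n_base)
  expect_identical(cv$summary$metric,
                   c("accuracy", "sensitivity", "specificity", "f1", "auc"))
  expect_true(all(grepl("±", cv$summary$formatted)))
  expect_error(crossvalidate(ds, k = 1L), "k must be")
})
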