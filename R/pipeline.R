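donor_truth_fractions <- function(truth) {
  agg <- stats::aggregate(multipotent ~ donor_id, data = truth, FUN = mean)
  names(agg)[2L] <- "truth_fraction"
  agg
}

#' Run the full multipotency pipeline on a synthetic cohort
#'
#' Chains simulate, detect, label, split, augment, train, predict and report
#' under one master seed: generates a cohort from the donor profiles, detects
#' and crops single cells, labels them from the potency-marker channel,
#' builds the stratified 70/10/20 dataset with 4-fold training augmentation,
#' trains the classifier, evaluates it on the held-out test split, and
#' estimates per-donor multipotency ratios (with recovery against the
#' planted truth).
#'
#' @param profiles List of [donor_profile()].
#' @param image_config A [cohort_image_config()].
#' @param seed Master seed; fans out to cohort, split, initialization and
#'   training streams.
#' @param detector \code{"mask"} (default) or \code{"selective"}.
#' @param side Tensor side (default 224).
#' @param channels Channels fed to the classifier (default body only).
#' @param spec A [model_spec()] (defaults to one matching \code{side} /
#'   \code{channels}).
#' @param config A [train_config()].
#' @param augment Apply training augmentation (default TRUE).
#' @return List of class \code{potency_pipeline}: \code{cohort},
#'   \code{detection}, \code{dataset}, \code{model}, \code{test_report},
#'   \code{predictions}, \code{estimates}, \code{recovery}, \code{seed}.
#' @export
run_potency_pipeline <- function(profiles,
                                 image_config = cohort_image_config(),
                                 seed = 1L, detector = "mask", side = 224L,
                                 channels = "body", spec = NULL,
                                 config = train_config(), augment = TRUE) {
  cohort <- generate_cohort(profiles, image_config,
                            seed = derive_seed(seed, "cohort"))
  det <- detect_cohort(cohort, method = detector)
  dataset <- build_labeled_dataset(det$crops, donor_ids = det$table$donor_id,
                                   seed = derive_seed(seed, "split"),
                                   side = side, channels = channels)
  ds_train <- if (augment) augment_train(dataset) else dataset
  if (is.null(spec))
    spec <- model_spec(input_side = side, channels = length(channels))
  config$seed <- derive_seed(seed, "train")
  model <- build_model(spec, seed = derive_seed(seed, "init"))
  model <- train_cnn(model, ds_train, config)
  te <- which(dataset$split == "test")
  pred_te <- predict_cells(model, dataset$x[, , , te, drop = FALSE])
  test_report <- compute_metrics(dataset$y[te], pred_te$label,
                                 pred_te$prob_positive)
  pred_all <- predict_cells(model, dataset$x)
  pred_all$donor_id <- dataset$donor_id
  estimates <- donor_potency(pred_all, seed = derive_seed(seed, "boot"),
                             sensitivity = test_report$sensitivity,
                             specificity = test_report$specificity,
                             truth = donor_truth_fractions(cohort$truth))
  structure(list(cohort = cohort, detection = det, dataset = dataset,
                 model = model, test_report = test_report,
                 predictions = pred_all, estimates = estimates,
                 recovery = recovery_report(estimates),
                 seed = as.integer(seed)),
            class = "potency_pipeline")
}

#' @export
print.potency_pipeline <- function(x, ...) {
  cat(sprintf("potency_pipeline (seed %d): %d cells detected, test accuracy %.3f\n",
              x$seed, nrow(x$detection$table), x$test_report$accuracy))
  print(x$estimates[, c("donor_id", "n_cells", "ratio", "ci_low", "ci_high",
                        if ("truth_fraction" %in% names(x$estimates))
                          c("truth_fraction", "abs_error"))])
  invisible(x)
}

#' Apply a trained classifier to a freshly generated evaluation cohort
#'
#' Generates an independent cohort from the given profiles, detects and
#' crops cells, predicts with the trained model, and reports per-cell
#' accuracy against the planted labels (crops matched to truth boxes by IoU)
#' together with donor-ratio estimates and their recovery.
#'
#' @param model Trained \code{potency_cnn}.
#' @param profiles List of [donor_profile()].
#' @param image_config A [cohort_image_config()].
#' @param seed Cohort seed.
#' @param detector \code{"mask"} or \code{"selective"}.
#' @param channels Channels fed to the classifier.
#' @return List with \code{accuracy}, \code{report} (\code{eval_report}),
#'   \code{estimates}, \code{recovery}, \code{n_matched}.
#' @export
evaluate_on_cohort <- function(model, profiles,
                               image_config = cohort_image_config(),
                               seed = 1L, detector = "mask",
                               channels = "body") {
  cohort <- generate_cohort(profiles, image_config, seed = seed)
  det <- detect_cohort(cohort, method = detector)
  pred <- predict_cells(model, det$crops, channels = channels)
  pred$donor_id <- det$table$donor_id
  mt <- match_crops_to_truth(det$table, cohort$truth)
  mi <- match(mt$pairs$crop_id, det$table$crop_id)
  ti <- match(mt$pairs$cell_id, cohort$truth$cell_id)
  truth_lab <- ifelse(cohort$truth$multipotent[ti], "Positive", "Negative")
  report <- compute_metrics(truth_lab, pred$label[mi],
                            pred$prob_positive[mi])
  estimates <- donor_potency(pred, seed = derive_seed(seed, "boot"),
                             truth = donor_truth_fractions(cohort$truth))
  list(accuracy = report$accuracy, report = report, estimates = estimates,
       recovery = recovery_report(estimates), n_matched = nrow(mt$pairs))
}
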