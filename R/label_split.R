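#' Label a cell crop from its potency-marker channel
#'
#' The crop's marker statistic (by default the mean over the cell mask when
#' one is available, otherwise over the whole crop) is compared with the
#' 8-bit threshold: strictly greater than \code{threshold} is Positive
#' (multipotent), otherwise Negative. A statistic of exactly 90 is Negative
#' under the strict rule.
#'
#' @param crop A \code{cell_crop}.
#' @param threshold Intensity threshold on the 0-255 scale (default 90).
#' @param statistic One of \code{"mean"}, \code{"median"}, \code{"max"}.
#' @return List of class \code{labeled_cell}: \code{crop_id}, \code{label}
#'   (\code{"Positive"}/\code{"Negative"}), \code{label_statistic}.
#' @export
label_crop <- function(crop, threshold = 90,
                       statistic = c("mean", "median", "max")) {
  statistic <- match.arg(statistic)
  px <- crop$ssea3
  if (length(px) == 0) stop("empty crop")
  vals <- if (!is.null(crop$mask) && sum(crop$mask) > 0) px[crop$mask] else px
  stat <- switch(statistic, mean = mean(vals),
                 median = stats::median(vals), max = max(vals))
  structure(list(crop_id = crop$crop_id,
                 label = if (stat > threshold) "Positive" else "Negative",
                 label_statistic = stat),
            class = "labeled_cell")
}

# Largest-remainder allocation of n items to fractions.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))   # ties: earlier split wins
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Items are allocated per class by largest-remainder rounding of the split
#' fractions (ties go to the earlier split), then assigned by a seeded
#' within-class shuffle. For 1850 items at fractions (0.70, 0.10, 0.20) the
#' split sizes are exactly 1295/185/370, and the per-class composition of
#' each split is within one item of the overall class ratio.
#'
#' @param labels Character/factor vector of class labels, one per item.
#' @param fractions Numeric (train, val, test) summing to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return Factor of \code{"train"}/\code{"val"}/\code{"test"}, same length
#'   as \code{labels}.
#' @export
stratified_split <- function(labels, fractions = c(0.70, 0.10, 0.20),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  stopifnot(length(fractions) == 3L)
  labels <- as.character(labels)
  split <- character(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 3L)
        warning(sprintf("class '%s' has fewer items (%d) than splits", cl,
                        length(idx)))
      counts <- largest_remainder(length(idx), fractions)
      idx <- idx[sample.int(length(idx))]
      split[idx] <- rep(c("train", "val", "test"), counts)
    }
  })
  factor(split, levels = c("train", "val", "test"))
}

#' Resize a crop to a square tensor and min-max normalize
#'
#' Bilinear resize to \code{side x side} followed by per-image min-max
#' scaling to \code{[0, 1]}; constant images map to all zeros.
#'
#' @param crop A \code{cell_crop}, or a numeric matrix / H x W x C array.
#' @param side Output side (default 224).
#' @param channels For \code{cell_crop} input: which channels to stack,
#'   subset of \code{c("body", "ssea3")}. The classifier default is the body
#'   channel only, so the model sees morphology, not the labelling marker.
#' @return \code{side x side x C} array with values in \code{[0, 1]}.
#' @export
normalize_resize <- function(crop, side = 224L, channels = "body") {
  if (inherits(crop, "cell_crop")) {
    mats <- lapply(channels, function(ch) crop[[ch]])
  } else if (is.matrix(crop)) {
    mats <- list(crop)
  } else {
    mats <- lapply(seq_len(dim(crop)[3]), function(k) crop[, , k])
  }
  if (any(vapply(mats, length, 0L) == 0)) stop("empty crop")
  out <- array(0, c(side, side, length(mats)))
  for (k in seq_along(mats)) {
    m <- EBImage::resize(EBImage::Image(mats[[k]] / 255), w = side, h = side)
    m <- as.numeric(EBImage::imageData(m))
    lo <- min(m); hi <- max(m)
    out[, , k] <- if (hi - lo > 1e-8) (m - lo) / (hi - lo) else 0
  }
  out
}

#' Assemble a labeled, split dataset from crops
#'
#' Labels every crop from the marker channel, applies the stratified split,
#' and builds normalized tensors.
#'
#' @param crops List of \code{cell_crop}.
#' @param donor_ids Optional donor label per crop.
#' @param threshold,statistic Passed to [label_crop()].
#' @param fractions,seed Passed to [stratified_split()].
#' @param side,channels Passed to [normalize_resize()].
#' @return Object of class \code{labeled_dataset}: \code{x} (side x side x C
#'   x N array), \code{y} (factor Positive/Negative), \code{split},
#'   \code{augmented} (logical), \code{origin} (crop ids), \code{donor_id},
#'   \code{label_statistic}, \code{side}, \code{fractions}, \code{seed}.
#' @export
build_labeled_dataset <- function(crops, donor_ids = NULL, threshold = 90,
                                  statistic = "mean",
                                  fractions = c(0.70, 0.10, 0.20), seed = 1L,
                                  side = 224L, channels = "body") {
  stopifnot(length(crops) >= 2L)
  labs <- lapply(crops, label_crop, threshold = threshold,
                 statistic = statistic)
  y <- vapply(labs, function(l) l$label, "")
  stat <- vapply(labs, function(l) l$label_statistic, 0)
  split <- stratified_split(y, fractions, seed)
  n <- length(crops)
  x <- array(0, c(side, side, length(channels), n))
  for (i in seq_len(n)) x[, , , i] <- normalize_resize(crops[[i]], side,
                                                       channels)
  structure(list(
    x = x, y = factor(y, levels = c("Negative", "Positive")), split = split,
    augmented = rep(FALSE, n),
    origin = vapply(crops, function(cr) cr$crop_id, ""),
    donor_id = if (is.null(donor_ids)) rep(NA_character_, n) else donor_ids,
    label_statistic = stat, side = side, fractions = fractions,
    seed = as.integer(seed)), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d items (%s), %d positive\n",
              length(x$y), paste(table(x$split), collapse = "/"),
              sum(x$y == "Positive")))
  invisible(x)
}

rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

#' Deterministic 4-fold augmentation of the training split
#'
#' Each training item yields exactly four items: the original, a 90-degree
#' rotation, a horizontal flip and a vertical flip. Labels, donor ids and
#' origins are preserved; validation and test items are untouched, so no
#' augmented view of a held-out crop can enter training.
#'
#' @param dataset A \code{labeled_dataset}.
#' @return The augmented \code{labeled_dataset} (train size x 4).
#' @export
augment_train <- function(dataset) {
  tr <- which(dataset$split == "train" & !dataset$augmented)
  side <- dataset$side; C <- dim(dataset$x)[3]
  n_new <- 3L * length(tr)
  if (n_new == 0L) return(dataset)
  xa <- array(0, c(side, side, C, n_new))
  j <- 0L
  ops <- list(rot90 = rot90cw,
              fliph = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
              flipv = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  meta_idx <- integer(n_new)
  for (i in tr) for (op in ops) {
    j <- j + 1L
    for (k in seq_len(C)) xa[, , k, j] <- op(dataset$x[, , k, i])
    meta_idx[j] <- i
  }
  x_all <- array(0, c(side, side, C, dim(dataset$x)[4] + n_new))
  x_all[, , , seq_len(dim(dataset$x)[4])] <- dataset$x
  x_all[, , , dim(dataset$x)[4] + seq_len(n_new)] <- xa
  dataset$x <- x_all
  dataset$y <- factor(c(as.character(dataset$y),
                        as.character(dataset$y)[meta_idx]),
                      levels = levels(dataset$y))
  dataset$split <- factor(c(as.character(dataset$split),
                            rep("train", n_new)),
                          levels = levels(dataset$split))
  dataset$augmented <- c(dataset$augmented, rep(TRUE, n_new))
  dataset$origin <- c(dataset$origin, dataset$origin[meta_idx])
  dataset$donor_id <- c(dataset$donor_id, dataset$donor_id[meta_idx])
  dataset$label_statistic <- c(dataset$label_statistic,
                               dataset$label_statistic[meta_idx])
  dataset
}
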