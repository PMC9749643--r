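#' Specification of the multipotency classifier
#'
#' The classifier head is fixed: dropout (rate 0.4, shared by all three
#' dropout layers), 2-D global max pooling over the spatial dimensions,
#' dropout, a 64-unit ReLU hidden layer, batch normalization, dropout, and a
#' 2-unit softmax output. The backbone is a small scratch CNN (three
#' conv-ReLU-maxpool blocks with 16/32/64 filters) preceded by an integer
#' average-pool downsample that brings the 224 px input to a coarse working
#' resolution; the shape classes the model must separate are low-frequency,
#' so a ~28 px working map preserves them while keeping CPU training cheap.
#' All layers are trainable.
#'
#' @param input_side Input image side in pixels (default 224).
#' @param channels Number of input channels (default 1: the body channel).
#' @param working_side Approximate side of the map entering the first
#'   convolution; the downsample stride is \code{floor(input_side /
#'   working_side)}.
#' @param filters Three conv-block filter counts.
#' @param hidden Hidden dense width (default 64).
#' @param dropout Shared dropout rate (default 0.4).
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(input_side = 224L, channels = 1L, working_side = 28L,
                       filters = c(16L, 32L, 64L), hidden = 64L,
                       dropout = 0.4) {
  if (length(filters) != 3L || any(filters < 1L))
    stop("filters must be three positive counts")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (input_side < working_side) stop("input_side must be >= working_side")
  structure(list(backbone = "small_scratch_cnn",
                 input_side = as.integer(input_side),
                 channels = as.integer(channels),
                 working_side = as.integer(working_side),
                 filters = as.integer(filters), hidden = as.integer(hidden),
                 dropout = dropout, n_classes = 2L),
            class = "model_spec")
}

#' Build the classifier from a specification
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization (He-scaled normal).
#' @return Object of class \code{potency_cnn} with fields \code{spec},
#'   \code{layers} and \code{head_start} (index of the first head layer).
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  ds <- max(1L, spec$input_side %/% spec$working_side)
  layers <- list()
  if (ds > 1L) layers <- c(layers, list(nn_avgpool(ds)))
  c_in <- spec$channels
  for (f in spec$filters) {
    layers <- c(layers, list(nn_conv3(c_in, f), nn_relu(), nn_maxpool2()))
    c_in <- f
  }
  head_start <- length(layers) + 1L
  layers <- c(layers, list(
    nn_dropout(spec$dropout),
    nn_gmaxpool(),
    nn_dropout(spec$dropout),
    nn_dense(c_in, spec$hidden, activation = "relu"),
    nn_batchnorm(spec$hidden),
    nn_dropout(spec$dropout),
    nn_dense(spec$hidden, spec$n_classes, activation = "linear")))
  layers <- with_seed(seed, lapply(layers, nn_init_layer))
  structure(list(spec = spec, layers = layers, head_start = head_start),
            class = "potency_cnn")
}

#' Ordered head-layer description (introspection)
#'
#' @param model A \code{potency_cnn}.
#' @return Character vector naming the head layers in order.
#' @export
head_layers <- function(model) {
  ls <- model$layers[model$head_start:length(model$layers)]
  vapply(ls, function(l) {
    if (l$type == "dense")
      paste0("dense_", if (l$activation == "relu") "relu" else "softmax")
    else if (l$type == "gmaxpool") "global_max_pool"
    else if (l$type == "batchnorm") "batch_norm"
    else l$type
  }, "")
}

#' @export
print.potency_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    sum(vapply(l$params, length, 0L)), 0))
  cat(sprintf("potency_cnn: %s, input %dx%dx%d, %d parameters\n",
              x$spec$backbone, x$spec$input_side, x$spec$input_side,
              x$spec$channels, np))
  cat("head:", paste(head_layers(x), collapse = " -> "), "\n")
  invisible(x)
}

# dataset tensors (H, W, C, idx) -> network layout (H, W, N, C)
batch_tensor <- function(x, idx) {
  xb <- x[, , , idx, drop = FALSE]
  aperm(xb, c(1L, 2L, 4L, 3L))
}

# The leading average-pool downsample has no parameters, so for training and
# batched inference it is applied once per tensor instead of once per batch.
frontend_split <- function(layers) {
  if (length(layers) && layers[[1L]]$type == "avgpool")
    list(front = layers[[1L]], rest = layers[-1L])
  else list(front = NULL, rest = layers)
}

apply_frontend <- function(front, x, batch_size = 64L) {
  if (is.null(front)) return(x)
  n <- dim(x)[4L]
  out <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    y <- fwd_avgpool(front, batch_tensor(x, b))$out   # (Ho, Wo, nb, C)
    y <- aperm(y, c(1L, 2L, 4L, 3L))
    if (is.null(out)) out <- array(0, c(dim(y)[1:3], n))
    out[, , , b] <- y
  }
  out
}

#' Forward pass: per-class probabilities
#'
#' Inference mode (dropout off, batch-norm running statistics), so repeated
#' calls on the same input give identical outputs.
#'
#' @param model A \code{potency_cnn}.
#' @param x Tensor array \code{side x side x C x N} (or \code{H x W x N x C}
#'   network layout if \code{layout = "hwnc"}).
#' @param layout Input layout.
#' @return N x 2 matrix of class probabilities, columns
#'   \code{(Negative, Positive)}; rows sum to 1.
#' @export
model_probs <- function(model, x, layout = c("hwcn", "hwnc")) {
  layout <- match.arg(layout)
  if (layout == "hwcn") x <- aperm(x, c(1L, 2L, 4L, 3L))
  out <- nn_forward(model$layers, x, train = FALSE)$out
  p <- softmax_rows(out)
  colnames(p) <- c("Negative", "Positive")
  p
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param max_epochs Maximum epochs (default 50).
#' @param patience Early-stopping patience on validation loss (default 10;
#'   must be below \code{max_epochs}).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Master seed fanned out to shuffling and dropout.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 50L,
                         patience = 10L, batch_size = 32L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "train_config")
}

dataset_onehot <- function(y) {
  oh <- matrix(0, length(y), 2L)
  oh[cbind(seq_along(y), as.integer(y == "Positive") + 1L)] <- 1
  oh
}

eval_loss <- function(layers, x, idx, oh, batch_size) {
  tot <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    fw <- nn_forward(layers, batch_tensor(x, b), train = FALSE)
    tot <- tot + xent_loss_grad(fw$out, oh[b, , drop = FALSE])$loss * length(b)
  }
  tot / length(idx)
}

#' Train the classifier with Adam, cross-entropy and early stopping
#'
#' Minimizes categorical cross-entropy on the training split with Adam,
#' monitoring validation loss once per epoch; training stops after
#' \code{patience} epochs without improvement (or at \code{max_epochs}) and
#' the best-validation-loss weights are restored.
#'
#' @param model A \code{potency_cnn} from [build_model()].
#' @param dataset A \code{labeled_dataset} with non-empty train and val
#'   splits.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained model, with \code{history} (data frame of epoch,
#'   train_loss, val_loss) and \code{best_epoch} attached.
#' @export
train_cnn <- function(model, dataset, config = train_config(),
                      verbose = FALSE) {
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "val")
  if (length(tr) == 0L || length(va) == 0L)
    stop("dataset must have non-empty train and val splits")
  oh <- dataset_onehot(dataset$y)
  fs <- frontend_split(model$layers)
  xds <- apply_frontend(fs$front, dataset$x, config$batch_size)
  layers <- fs$rest
  state <- adam_init(layers)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  t_adam <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- tr[sample.int(length(tr))]
      ep_loss <- 0
      for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
        fw <- nn_forward(layers, batch_tensor(xds, b), train = TRUE)
        layers <- fw$layers      # batch-norm running stats
        lg <- xent_loss_grad(fw$out, oh[b, , drop = FALSE])
        grads <- nn_backward(layers, fw$caches, lg$dlogits)
        t_adam <- t_adam + 1L
        upd <- adam_step(layers, grads, state, config$learning_rate, t_adam)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(b)
      }
      vl <- eval_loss(layers, xds, va, oh, config$batch_size)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / length(idx),
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %02d train %.4f val %.4f", epoch,
                        ep_loss / length(idx), vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, layers = layers, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  model$layers <- c(if (!is.null(fs$front)) list(fs$front), best$layers)
  model$history <- hist
  model$best_epoch <- best$epoch
  model$config <- config
  model
}

#' Predict labels and positive-class probabilities for crops
#'
#' @param model Trained \code{potency_cnn}.
#' @param crops List of \code{cell_crop}, a \code{labeled_dataset}, or a
#'   tensor array \code{side x side x C x N}.
#' @param channels Channels used when resizing raw crops (must match the
#'   model input).
#' @param batch_size Inference batch size.
#' @return Data frame with \code{label} (\code{Positive}/\code{Negative}) and
#'   \code{prob_positive}.
#' @export
predict_cells <- function(model, crops, channels = "body",
                          batch_size = 64L) {
  side <- model$spec$input_side
  if (inherits(crops, "labeled_dataset")) {
    x <- crops$x
  } else if (is.array(crops) && length(dim(crops)) == 4L) {
    x <- crops
  } else {
    n <- length(crops)
    x <- array(0, c(side, side, model$spec$channels, n))
    for (i in seq_len(n))
      x[, , , i] <- normalize_resize(crops[[i]], side, channels)
  }
  n <- dim(x)[4]
  fs <- frontend_split(model$layers)
  xs <- apply_frontend(fs$front, x, batch_size)
  probs <- matrix(0, n, 2L)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size)))
    probs[b, ] <- softmax_rows(
      nn_forward(fs$rest, batch_tensor(xs, b), train = FALSE)$out)
  data.frame(label = ifelse(probs[, 2L] > probs[, 1L], "Positive",
                            "Negative"),
             prob_positive = probs[, 2L], stringsAsFactors = FALSE)
}
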