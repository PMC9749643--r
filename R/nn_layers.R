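# Minimal CNN engine on BLAS matrix multiplication.
#
# Activations flow through the network as 4-D arrays in (H, W, N, C) layout
# (channels last so that a 3x3 convolution reduces to nine shifted
# (H*W*N) x Cin by Cin x Cout matrix products), switching to (N, F) matrices
# after global pooling. Each layer is a plain list carrying `params` (named
# arrays) and enough structure for the backward pass.

nn_conv3 <- function(c_in, c_out) {
  list(type = "conv3", c_in = c_in, c_out = c_out,
       params = list(W = array(0, c(3L, 3L, c_in, c_out)),
                     b = numeric(c_out)))
}
nn_relu <- function() list(type = "relu", params = list())
nn_avgpool <- function(s) list(type = "avgpool", s = as.integer(s),
                               params = list())
nn_maxpool2 <- function() list(type = "maxpool2", params = list())
nn_gmaxpool <- function() list(type = "gmaxpool", params = list())
nn_dropout <- function(p) list(type = "dropout", p = p, params = list())
nn_dense <- function(n_in, n_out, activation = "linear") {
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       params = list(W = matrix(0, n_in, n_out), b = numeric(n_out)))
}
nn_batchnorm <- function(n, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", n = n, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n), beta = rep(0, n)),
       running_mean = rep(0, n), running_var = rep(1, n))
}

nn_init_layer <- function(layer) {
  if (layer$type == "conv3") {
    fan_in <- 9 * layer$c_in
    layer$params$W[] <- stats::rnorm(length(layer$params$W),
                                     sd = sqrt(2 / fan_in))
  } else if (layer$type == "dense") {
    layer$params$W[] <- stats::rnorm(length(layer$params$W),
                                     sd = sqrt(2 / layer$n_in))
  }
  layer
}

# ---- forward/backward ------------------------------------------------------

fwd_conv3 <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, N, Cin))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  Cout <- layer$c_out
  y <- matrix(rep(layer$params$b, each = H * W * N), H * W * N, Cout)
  for (di in 1:3) for (dj in 1:3) {
    xs <- xp[di:(di + H - 1), dj:(dj + W - 1), , , drop = FALSE]
    dim(xs) <- c(H * W * N, Cin)
    y <- y + xs %*% matrix(layer$params$W[di, dj, , ], Cin, Cout)
  }
  dim(y) <- c(H, W, N, Cout)
  list(out = y, cache = list(xp = xp, d = d))
}

bwd_conv3 <- function(layer, cache, dout, need_dx = TRUE) {
  d <- cache$d; H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- layer$c_out
  dY <- dout; dim(dY) <- c(H * W * N, Cout)
  dW <- array(0, c(3L, 3L, Cin, Cout))
  dxp <- if (need_dx) array(0, dim(cache$xp)) else NULL
  for (di in 1:3) for (dj in 1:3) {
    xs <- cache$xp[di:(di + H - 1), dj:(dj + W - 1), , , drop = FALSE]
    dim(xs) <- c(H * W * N, Cin)
    dW[di, dj, , ] <- crossprod(xs, dY)
    if (need_dx) {
      dxs <- dY %*% t(matrix(layer$params$W[di, dj, , ], Cin, Cout))
      dim(dxs) <- c(H, W, N, Cin)
      dxp[di:(di + H - 1), dj:(dj + W - 1), , ] <-
        dxp[di:(di + H - 1), dj:(dj + W - 1), , , drop = FALSE] + dxs
    }
  }
  list(dx = if (need_dx) dxp[2:(H + 1), 2:(W + 1), , , drop = FALSE],
       grads = list(W = dW, b = colSums(dY)))
}

fwd_avgpool <- function(layer, x) {
  s <- layer$s
  d <- dim(x); Ho <- d[1] %/% s; Wo <- d[2] %/% s
  if (d[1] > Ho * s) x <- x[seq_len(Ho * s), , , , drop = FALSE]
  if (d[2] > Wo * s) x <- x[, seq_len(Wo * s), , , drop = FALSE]
  # column-major reshape: pool rows, transpose spatial dims, pool again
  dim(x) <- c(s, Ho * Wo * s * d[3] * d[4])
  y <- colSums(x) / s
  dim(y) <- c(Ho, Wo * s, d[3] * d[4])
  y <- aperm(y, c(2L, 1L, 3L))
  dim(y) <- c(s, Wo * Ho * d[3] * d[4])
  y <- colSums(y) / s
  dim(y) <- c(Wo, Ho, d[3] * d[4])
  y <- aperm(y, c(2L, 1L, 3L))
  dim(y) <- c(Ho, Wo, d[3], d[4])
  list(out = y, cache = list(d = d))
}

bwd_avgpool <- function(layer, cache, dout) {
  s <- layer$s; d <- cache$d
  Ho <- d[1] %/% s; Wo <- d[2] %/% s
  g <- dout / s^2
  dx <- array(0, d)
  dx[seq_len(Ho * s), seq_len(Wo * s), , ] <-
    g[rep(seq_len(Ho), each = s), rep(seq_len(Wo), each = s), , ,
      drop = FALSE]
  list(dx = dx, grads = list())
}

fwd_maxpool2 <- function(layer, x) {
  d <- dim(x); Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq(1L, by = 2L, length.out = Ho)
  ci <- seq(1L, by = 2L, length.out = Wo)
  s <- list(x[ri, ci, , , drop = FALSE], x[ri + 1L, ci, , , drop = FALSE],
            x[ri, ci + 1L, , , drop = FALSE],
            x[ri + 1L, ci + 1L, , , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(out = y, cache = list(d = d, s = s, y = y))
}

bwd_maxpool2 <- function(layer, cache, dout) {
  d <- cache$d; Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  ri <- seq(1L, by = 2L, length.out = Ho)
  ci <- seq(1L, by = 2L, length.out = Wo)
  dx <- array(0, d)
  used <- array(FALSE, dim(cache$y))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- (cache$s[[k]] == cache$y) & !used
    used <- used | m
    dx[ri + offs[[k]][1], ci + offs[[k]][2], , ] <- dout * m
  }
  list(dx = dx, grads = list())
}

fwd_gmaxpool <- function(layer, x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  tm <- t(m)
  idx <- max.col(tm, ties.method = "first")
  y <- tm[cbind(seq_len(nrow(tm)), idx)]
  dim(y) <- c(d[3], d[4])                    # (N, C)
  list(out = y, cache = list(d = d, idx = idx))
}

bwd_gmaxpool <- function(layer, cache, dout) {
  d <- cache$d
  dm <- matrix(0, d[1] * d[2], d[3] * d[4])
  dm[cbind(cache$idx, seq_len(ncol(dm)))] <- as.numeric(dout)
  dim(dm) <- d
  list(dx = dm, grads = list())
}

fwd_dropout <- function(layer, x, train) {
  if (!train || layer$p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= layer$p, dim(x)) / (1 - layer$p)
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dout) {
  if (is.null(cache)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

fwd_dense <- function(layer, x) {
  z <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
  a <- if (layer$activation == "relu") pmax(z, 0) else z
  list(out = a, cache = list(x = x, z = z))
}

bwd_dense <- function(layer, cache, dout) {
  dz <- if (layer$activation == "relu") dout * (cache$z > 0) else dout
  list(dx = dz %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
}

fwd_batchnorm <- function(layer, x, train) {
  eps <- layer$eps
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * v
    out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
                 layer$params$beta, "+")
    list(out = out, cache = list(xhat = xhat, inv = inv), layer = layer)
  } else {
    inv <- 1 / sqrt(layer$running_var + eps)
    xhat <- sweep(sweep(x, 2L, layer$running_mean), 2L, inv, "*")
    out <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
                 layer$params$beta, "+")
    list(out = out, cache = NULL, layer = layer)
  }
}

bwd_batchnorm <- function(layer, cache, dout) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, layer$params$gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*"),
              2L, cache$inv, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_relu_arr <- function(layer, x) list(out = pmax(x, 0),
                                        cache = list(pos = x > 0))
bwd_relu_arr <- function(layer, cache, dout) list(dx = dout * cache$pos,
                                                  grads = list())

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv3 = fwd_conv3(l, x),
                relu = fwd_relu_arr(l, x),
                avgpool = fwd_avgpool(l, x),
                maxpool2 = fwd_maxpool2(l, x),
                gmaxpool = fwd_gmaxpool(l, x),
                dropout = fwd_dropout(l, x, train),
                dense = fwd_dense(l, x),
                batchnorm = fwd_batchnorm(l, x, train),
                stop("unknown layer type: ", l$type))
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv3 = bwd_conv3(l, caches[[i]], dout, need_dx = i > 1L),
                relu = bwd_relu_arr(l, caches[[i]], dout),
                avgpool = bwd_avgpool(l, caches[[i]], dout),
                maxpool2 = bwd_maxpool2(l, caches[[i]], dout),
                gmaxpool = bwd_gmaxpool(l, caches[[i]], dout),
                dropout = bwd_dropout(l, caches[[i]], dout),
                dense = bwd_dense(l, caches[[i]], dout),
                batchnorm = bwd_batchnorm(l, caches[[i]], dout))
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# categorical cross-entropy; y_onehot is (N, K)
xent_loss_grad <- function(logits, y_onehot) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(y_onehot * log(pmax(p, 1e-12))) / n
  list(loss = loss, dlogits = (p - y_onehot) / n, probs = p)
}

adam_init <- function(layers) {
  lapply(layers, function(l) lapply(l$params, function(p) {
    list(m = p * 0, v = p * 0)
  }))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
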