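# Matérn 5/2 covariance on absolute distances.
matern52 <- function(r, lengthscale, signal_var) {
  s <- sqrt(5) * r / lengthscale
  signal_var * (1 + s + s^2 / 3) * exp(-s)
}

chol_jitter <- function(K, jitter = 1e-10) {
  for (j in jitter * 10^(0:6)) {
    ch <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(list(L = ch, jitter = j))
  }
  stop("covariance matrix is numerically singular even after jitter escalation")
}

gp_nll <- function(theta, x, yc, fixed_noise) {
  l <- exp(theta[1L]); s2 <- exp(theta[2L])
  nv <- if (is.null(fixed_noise)) exp(theta[3L]) else fixed_noise
  K <- matern52(abs(outer(x, x, "-")), l, s2) + diag(nv + 1e-10, length(x))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), yc))
  0.5 * sum(yc * a) + sum(log(diag(ch))) + 0.5 * length(x) * log(2 * pi)
}

#' Fit an exact Gaussian-process surrogate to 1-D observations
#'
#' Matérn 5/2 kernel with a constant (sample mean) mean function and a
#' Gaussian noise term. Unless fixed, the kernel hyperparameters
#' (length-scale, signal variance, noise variance) are set by marginal-
#' likelihood maximization with a fixed multi-start L-BFGS-B design, so the
#' fit is deterministic.
#'
#' @param x Numeric vector of inputs (e.g. log10 learning rates).
#' @param y Numeric vector of objective values (same length).
#' @param noise_var Fixed noise variance, or \code{NULL} to optimize it.
#' @param lengthscale,signal_var Fixed kernel hyperparameters, or \code{NULL}
#'   to optimize.
#' @return Object of class \code{gp_fit} with the hyperparameters, the
#'   Cholesky factor and the fitted mean.
#' @export
gp_fit <- function(x, y, noise_var = NULL, lengthscale = NULL,
                   signal_var = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  mu0 <- mean(y)
  yc <- y - mu0
  span <- max(diff(range(x)), 1e-3)
  sv0 <- if (length(y) > 1L) max(stats::var(y), 1e-6) else 1
  if (is.null(lengthscale) || is.null(signal_var)) {
    starts <- expand.grid(l = log(span * c(0.1, 0.3, 1)),
                          s = log(sv0))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      th0 <- c(starts$l[i], starts$s[i],
               if (is.null(noise_var)) log(sv0 * 0.05 + 1e-8))
      op <- tryCatch(
        stats::optim(th0, gp_nll, x = x, yc = yc, fixed_noise = noise_var,
                     method = "L-BFGS-B",
                     lower = c(log(span * 1e-3), log(sv0 * 1e-4),
                               if (is.null(noise_var)) log(1e-10)),
                     upper = c(log(span * 100), log(sv0 * 1e4),
                               if (is.null(noise_var)) log(sv0 * 10 + 1e-6))),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    th <- best$par
    lengthscale <- exp(th[1L]); signal_var <- exp(th[2L])
    if (is.null(noise_var)) noise_var <- exp(th[3L])
  } else if (is.null(noise_var)) {
    noise_var <- 0
  }
  K <- matern52(abs(outer(x, x, "-")), lengthscale, signal_var) +
    diag(noise_var, length(x))
  ch <- chol_jitter(K)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), yc))
  structure(list(x = x, y = y, mean = mu0, lengthscale = lengthscale,
                 signal_var = signal_var, noise_var = noise_var,
                 L = ch$L, alpha = alpha, jitter = ch$jitter),
            class = "gp_fit")
}

#' Posterior mean and variance of a fitted GP
#'
#' @param fit A [gp_fit()].
#' @param xstar Numeric vector of query points.
#' @return List with \code{mean}, \code{var} (latent-function variance,
#'   floored at 0) and \code{sd}.
#' @export
gp_predict <- function(fit, xstar) {
  ks <- matern52(abs(outer(xstar, fit$x, "-")), fit$lengthscale,
                 fit$signal_var)
  mu <- fit$mean + as.numeric(ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(ks))
  var <- pmax(fit$signal_var - colSums(v^2), 0)
  list(mean = mu, var = var, sd = sqrt(var))
}

#' Expected improvement for minimization
#'
#' \eqn{EI = (f_{best} - \mu - \xi)\Phi(z) + \sigma\phi(z)} with
#' \eqn{z = (f_{best} - \mu - \xi)/\sigma}; at \eqn{\sigma = 0} the EI is
#' \eqn{\max(f_{best} - \mu - \xi, 0)}. Non-negative everywhere.
#'
#' @param mean,sd Posterior mean and sd at the candidate points (vectors),
#'   or a \code{gp_fit} as \code{mean} and candidate inputs as \code{sd}.
#' @param best_so_far Incumbent (lowest observed objective).
#' @param xi Exploration margin (default 0.01).
#' @return EI values (>= 0).
#' @export
expected_improvement <- function(mean, sd, best_so_far, xi = 0.01) {
  if (inherits(mean, "gp_fit")) {
    p <- gp_predict(mean, sd)
    mean <- p$mean; sd <- p$sd
  }
  imp <- best_so_far - mean - xi
  ei <- ifelse(sd > 0,
               imp * stats::pnorm(imp / sd) + sd * stats::dnorm(imp / sd),
               pmax(imp, 0))
  pmax(ei, 0)
}

#' Bayesian optimization of the learning rate
#'
#' Minimizes a (possibly stochastic) objective over log10 learning rate with
#' a GP surrogate and expected-improvement acquisition. Each repeat starts
#' from an evenly spaced initial design and runs \code{n_iter} EI-maximizing
#' queries (deterministic dense-grid argmax, ties to the smaller learning
#' rate); the repeats' observations are pooled and the global argmin
#' returned.
#'
#' @param objective Function of \code{log10_lr} returning the value to
#'   minimize (e.g. cross-validated validation loss). May accept a second
#'   argument, a repeat-specific integer seed, for stochastic objectives.
#' @param bounds Length-2 numeric, default \code{c(-5, -1)} (log10 scale).
#' @param n_iter EI iterations per repeat (default 10).
#' @param n_repeats Independent repeats pooled into one trace (default 5).
#' @param n_init Evenly spaced initial design points per repeat (default 3).
#' @param xi EI exploration margin.
#' @param grid_n Acquisition grid resolution (default 1001).
#' @param seed Master seed (fans out per repeat).
#' @return List of class \code{bo_result}: \code{best_log10_lr},
#'   \code{best_objective}, \code{trace} (repeat, iteration, log10_lr,
#'   objective, best_so_far; iteration 0 marks the initial design),
#'   \code{observations}.
#' @export
optimize_learning_rate <- function(objective, bounds = c(-5, -1),
                                   n_iter = 10L, n_repeats = 5L,
                                   n_init = 3L, xi = 0.01, grid_n = 1001L,
                                   seed = 1L) {
  stopifnot(length(bounds) == 2L, all(is.finite(bounds)),
            bounds[1] < bounds[2])
  takes_seed <- length(formals(objective)) >= 2L
  eval_obj <- function(x, rep_seed) {
    v <- tryCatch(if (takes_seed) objective(x, rep_seed) else objective(x),
                  error = function(e) {
                    warning(sprintf("objective failed at %.4f: %s", x,
                                    conditionMessage(e)))
                    NA_real_
                  })
    as.numeric(v)
  }
  grid <- seq(bounds[1], bounds[2], length.out = grid_n)
  trace <- list()
  for (r in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, paste0("bo_repeat", r))
    xs <- seq(bounds[1], bounds[2], length.out = n_init + 2L)[2:(n_init + 1L)]
    ys <- vapply(xs, eval_obj, 0, rep_seed = rep_seed)
    for (i in seq_along(xs))
      trace[[length(trace) + 1L]] <- data.frame(
        repeat_id = r, iteration = 0L, log10_lr = xs[i], objective = ys[i],
        best_so_far = min(ys[seq_len(i)], na.rm = TRUE))
    for (it in seq_len(n_iter)) {
      ok <- !is.na(ys)
      if (!any(ok)) break
      fit <- gp_fit(xs[ok], ys[ok])
      p <- gp_predict(fit, grid)
      ei <- expected_improvement(p$mean, p$sd, min(ys[ok]), xi)
      xnew <- grid[which.max(ei)]   # which.max: first (smallest lr) on ties
      ynew <- eval_obj(xnew, rep_seed)
      xs <- c(xs, xnew); ys <- c(ys, ynew)
      trace[[length(trace) + 1L]] <- data.frame(
        repeat_id = r, iteration = it, log10_lr = xnew, objective = ynew,
        best_so_far = min(ys, na.rm = TRUE))
    }
  }
  trace <- do.call(rbind, trace)
  obs <- trace[!is.na(trace$objective), , drop = FALSE]
  ord <- order(obs$objective, obs$log10_lr)
  best <- obs[ord[1L], ]
  structure(list(best_log10_lr = best$log10_lr,
                 best_objective = best$objective,
                 trace = trace, observations = obs),
            class = "bo_result")
}

#' @export
print.bo_result <- function(x, ...) {
  cat(sprintf("Bayesian optimization: best log10(lr) = %.3f (objective %.5f) over %d observations\n",
              x$best_log10_lr, x$best_objective, nrow(x$observations)))
  invisible(x)
}
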