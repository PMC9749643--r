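#' @useDynLib morphopotency, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored on exit. All exported stochastic entry points route
# their randomness through this.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream label, keeping the
# result a valid 32-bit R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

# Boxes are (row, col), 0-based, half-open: [r0, r1) x [c0, c1).
box_area <- function(b) {
  pmax(0, b[["r1"]] - b[["r0"]]) * pmax(0, b[["c1"]] - b[["c0"]])
}

#' Intersection-over-union of two pixel boxes
#'
#' Boxes use the package-wide convention: 0-based, half-open
#' \code{[r0, r1) x [c0, c1)} pixel intervals.
#'
#' @param a,b Named numeric vectors or one-row data frames with elements
#'   \code{r0, r1, c0, c1}.
#' @return The IoU in \code{[0, 1]}.
#' @export
box_iou <- function(a, b) {
  ir0 <- max(a[["r0"]], b[["r0"]]); ir1 <- min(a[["r1"]], b[["r1"]])
  ic0 <- max(a[["c0"]], b[["c0"]]); ic1 <- min(a[["c1"]], b[["c1"]])
  inter <- max(0, ir1 - ir0) * max(0, ic1 - ic0)
  un <- box_area(a) + box_area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' IoU matrix between two sets of boxes
#'
#' @param A,B Data frames of boxes (columns \code{r0, r1, c0, c1}).
#' @return \code{nrow(A)} x \code{nrow(B)} IoU matrix.
#' @export
box_iou_matrix <- function(A, B) {
  m <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      m[i, j] <- box_iou(A[i, , drop = FALSE], B[j, , drop = FALSE])
  m
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Otsu threshold on an 8-bit image: maximizes between-class variance over the
# 0..255 histogram. Returns the threshold on the input scale (foreground =
# values strictly above it).
otsu_threshold <- function(img) {
  v <- pmin(255L, pmax(0L, as.integer(round(img))))
  h <- as.numeric(tabulate(v + 1L, 256L))
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lv)
  mt <- m0[256L]
  w1 <- n - w0
  mu0 <- m0 / pmax(w0, 1)
  mu1 <- (mt - m0) / pmax(w1, 1)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -1
  lv[which.max(bcv)]
}

clip255 <- function(x) pmin(255, pmax(0, x))

# Separable Gaussian blur with replicate padding on a 2-D matrix.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- nrow(x)
    xp <- x[c(rep(1L, half), seq_len(n), rep(n, half)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (t in seq_along(k)) out <- out + k[t] * xp[t:(t + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}
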