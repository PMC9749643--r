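test_that("contour extraction traces closed boundaries at sub-pixel accuracy", {
  sq <- make_rect_mask(10L, 10L)
  ct <- extract_contour(sq)
  per <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1L), ])^2)))
  expect_gte(per, 36 * 0.98)
  expect_lte(per, 40 * 1.02)

  disk <- make_disk_mask(50L)
  ct2 <- extract_contour(disk)
  per2 <- sum(sqrt(rowSums((ct2 - ct2[c(2:nrow(ct2), 1L), ])^2)))
  expect_lt(abs(per2 - 2 * pi * 50) / (2 * pi * 50), 0.02)
  # counter-clockwise orientation (positive signed area in (col, row))
  x <- ct2[, 2L]; y <- ct2[, 1L]
  expect_gt(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2, 0)

  donut <- make_rect_mask(20L, 20L)
  donut[15:20, 15:20] <- 0
  expect_error(extract_contour(donut), "not simply traceable")
  expect_error(extract_contour(matrix(0, 10, 10)), "empty")
  two <- matrix(0, 30, 30); two[3:10, 3:10] <- 1; two[20:28, 20:28] <- 1
  expect_error(extract_contour(two), "one connected component")
})

test_that("equidistant resampling is exact and idempotent", {
  sq <- rbind(c(0, 0), c(0, 100), c(100, 100), c(100, 0))
  r1 <- resample_equidistant(sq, 50L)
  expect_identical(nrow(r1), 50L)
  expect_equal(attr(r1, "perimeter"), 400)
  expect_equal(attr(r1, "arc_spacing"), 8)      # 400 / 50, exactly
  r2 <- resample_equidistant(r1, 50L)
  expect_equal(max(abs(r1 - r2)), 0, tolerance = 1e-9)

  circ <- analytic_circle(30, n = 720L)
  rc <- resample_equidistant(circ, 50L)
  rad <- sqrt(rowSums(sweep(unclass(rc), 2L, colMeans(rc))^2))
  expect_true(all(abs(rad - 30) / 30 < 0.005))
  expect_error(resample_equidistant(rbind(c(0, 0), c(0, 0))), "zero length")
})

test_that("registration removes position, scale and rotation but not chirality", {
  c1 <- resample_equidistant(analytic_ellipse(40, 20), 50L)
  c2 <- resample_equidistant(
    analytic_ellipse(40, 20, theta = 1.1, ctr = c(33, -12), scale = 2.7), 50L)
  reg <- register_contours(list(c1, c2))
  expect_lt(max(abs(reg$coords[1L, ] - reg$coords[2L, ])), 1e-6)

  mirror <- analytic_ellipse(40, 20, theta = 0.6)
  mirror <- cbind(mirror[, 1L], -mirror[, 2L])
  regm <- register_contours(list(c1, resample_equidistant(mirror, 50L)))
  expect_gt(max(abs(regm$coords[1L, ] - regm$coords[2L, ])), 1e-3)

  with_seed(17, {
    ells <- lapply(1:100, function(i)
      resample_equidistant(analytic_ellipse(runif(1, 20, 50),
                                            runif(1, 10, 20),
                                            theta = runif(1, 0, pi),
                                            ctr = runif(2, -50, 50)), 50L))
  })
  rega <- register_contours(ells)
  expect_true(all(abs(sqrt(rowSums(rega$coords^2)) - 1) < 1e-9))
  expect_error(register_contours(list(structure(c1 * 0, class = class(c1)))),
               "degenerate")
})

test_that("eigenshape PCA recovers variance structure exactly", {
  c1 <- resample_equidistant(analytic_circle(30), 50L)
  reg <- register_contours(list(c1, c1, c1))
  pc <- eigenshape_pca(reg$coords)
  expect_true(all(pc$explained_variance == 0))

  # family varying along exactly one direction of the aligned space
  base <- as.numeric(reg$coords[1L, ])
  dir <- with_seed(3, stats::rnorm(length(base)))
  dir <- dir / sqrt(sum(dir^2))
  fam <- do.call(rbind, lapply(seq(-1, 1, length.out = 25L),
                               function(t) base + 0.1 * t * dir))
  pcf <- eigenshape_pca(fam)
  expect_lt(abs(pcf$explained_variance[1L] - 1), 1e-9)
  expect_true(all(diff(pcf$explained_variance) < 1e-12))
  expect_lte(sum(pcf$explained_variance), 1 + 1e-9)

  # orthonormal basis and perfect reconstruction
  with_seed(19, {
    mats <- lapply(1:12, function(i)
      resample_equidistant(analytic_ellipse(runif(1, 25, 45),
                                            runif(1, 12, 22)), 50L))
  })
  regr <- register_contours(mats)
  pcr <- eigenshape_pca(regr$coords)
  G <- crossprod(pcr$basis)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  rec <- sweep(pcr$scores %*% t(pcr$basis), 2L, pcr$mean_shape, "+")
  expect_lt(max(abs(rec - regr$coords)), 1e-8)
})

test_that("k-means shape modes separate planted families deterministically", {
  with_seed(23, {
    round_m <- lapply(1:20, function(i)
      make_ellipse_mask(20L + sample(0:3, 1), 16L + sample(0:3, 1)))
    elong_m <- lapply(1:20, function(i)
      make_ellipse_mask(44L + sample(0:3, 1), 11L + sample(0:2, 1)))
  })
  model <- fit_shape_modes(c(round_m, elong_m), k_modes = 2L, seed = 7)
  planted <- rep(1:2, each = 20L)
  tab <- table(model$assignments, planted)
  agree <- max(sum(diag(tab)), sum(tab[1L, 2L] + tab[2L, 1L])) / sum(tab)
  expect_equal(agree, 1.0)

  # determinism and the k = n degenerate case
  model2 <- fit_shape_modes(c(round_m, elong_m), k_modes = 2L, seed = 7)
  expect_identical(model$assignments, model2$assignments)
  scores <- model$scores[1:6, 1:2]
  cl <- cluster_shape_modes(scores, k = 6L, seed = 1)
  expect_lt(cl$inertia, 1e-12)
  expect_error(cluster_shape_modes(scores, k = 7L), "exceed")
  # modes are renumbered by descending size
  cl2 <- cluster_shape_modes(model$scores[, 1:2], k = 3L, seed = 2)
  expect_true(all(diff(cl2$sizes) <= 0))
})

test_that("scalar descriptors match closed forms within tolerance", {
  d <- shape_descriptors(make_disk_mask(50L))
  expect_lt(abs(d$circularity - 1), 0.03)
  expect_lt(abs(d$aspect_ratio - 1), 0.02)

  s <- shape_descriptors(make_rect_mask(80L, 80L))
  expect_lt(abs(s$circularity - pi / 4), 0.03)

  e <- shape_descriptors(make_ellipse_mask(80L, 20L))
  expect_lt(abs(e$aspect_ratio - 4) / 4, 0.02)
  expect_gt(d$area, 0)
  expect_gt(d$perimeter, 0)
})

test_that("donor mode tables are row-stochastic with calibrated homogeneity", {
  one <- donor_shape_distribution(rep(1L, 10L), rep("d1", 10L))
  expect_equal(unname(one$freq[1L, 1L]), 1.0)

  with_seed(29, {
    pvals <- replicate(60, {
      assng <- sample(1:4, 400, replace = TRUE)       # identical distributions
      donors <- rep(c("a", "b", "c", "d"), each = 100L)
      donor_shape_distribution(assng, donors)$chisq$p.value
    })
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  with_seed(31, {
    assng <- sample(1:5, 300, replace = TRUE)
    donors <- sample(c("x", "y", "z"), 300, replace = TRUE)
  })
  tabs <- donor_shape_distribution(assng, donors)
  expect_equal(unname(rowSums(tabs$freq)), rep(1, 3))
})

test_that("shape scores are invariant to mask placement and scale", {
  base <- make_ellipse_mask(30L, 18L, pad = 40L)
  shifted <- base[c(21:nrow(base), 1:20), ]            # translated content
  model <- fit_shape_modes(list(base, shifted, base), k_modes = 1L, seed = 1)
  expect_lt(max(abs(model$coords[1L, ] - model$coords[2L, ])), 1e-6)
})

test_that("morphometry separates coupled families with >= 99% accuracy", {
  coh <- cached("morpho_cohort", generate_cohort(
    list(donor_profile("M", 60, 0.5, 1)), seed = 83))
  desc <- t(vapply(coh$truth$cell_id, function(cid)
    unlist(shape_descriptors(coh$masks[[cid]]$mask)[c("circularity",
                                                      "aspect_ratio")]),
    c(0, 0)))
  fam <- coh$truth$shape_family
  # best single threshold on aspect ratio
  thr <- seq(1.5, 3.5, by = 0.05)
  acc <- vapply(thr, function(t)
    mean((desc[, 2L] > t) == (fam == "elongated")), 0)
  expect_gte(max(acc), 0.99)
})
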