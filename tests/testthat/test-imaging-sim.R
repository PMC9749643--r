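test_that("donor profiles validate their invariants", {
  expect_error(donor_profile("S1", 0), "n_cells")
  expect_error(donor_profile("S1", 10, potency_fraction = 1.2), "potency_fraction")
  expect_error(donor_profile("S1", 10, coupling = -0.1), "coupling")
  p <- donor_profile("S1", 10, 0.5, 0.7)
  expect_s3_class(p, "donor_profile")
  expect_error(generate_cohort(list()), "length")
})

test_that("phenotype sampling follows the planted potency and coupling", {
  p1 <- donor_profile("A", 1, potency_fraction = 1, coupling = 0.5)
  with_seed(11, {
    draws <- replicate(200, sample_cell_phenotype(p1)$multipotent)
    expect_true(all(draws))
  })
  pc <- donor_profile("B", 1, potency_fraction = 0.5, coupling = 1)
  with_seed(12, {
    phs <- replicate(1000, sample_cell_phenotype(pc), simplify = FALSE)
    mult <- vapply(phs, `[[`, TRUE, "multipotent")
    fam <- vapply(phs, `[[`, "", "shape_family")
    expect_identical(fam == "round", mult)
  })
})

test_that("empirical potency fraction matches the planted rate at scale", {
  prof <- donor_profile("C", 1, potency_fraction = 0.678, coupling = 0.9)
  with_seed(13, {
    mult <- replicate(10000, sample_cell_phenotype(prof)$multipotent)
  })
  expect_lt(abs(mean(mult) - 0.678), 0.02)
})

test_that("marker intensities straddle the 8-bit labelling threshold", {
  prof <- donor_profile("D", 1, potency_fraction = 0.5, coupling = 0.9)
  with_seed(14, {
    phs <- replicate(500, sample_cell_phenotype(prof), simplify = FALSE)
  })
  ints <- vapply(phs, `[[`, 0L, "ssea3_intensity")
  mult <- vapply(phs, `[[`, TRUE, "multipotent")
  expect_true(all(ints >= 0 & ints <= 255))
  expect_gt(mean(ints[mult] > 90), 0.97)
  expect_gt(mean(ints[!mult] <= 90), 0.97)
})

test_that("rendered masks reproduce the analytic shape scalars", {
  ph <- with_seed(1, sample_cell_phenotype(donor_profile("E", 1, 1, 1)))
  ph$boundary_roughness <- 0
  ph$center <- c(row = 100, col = 100)

  ph$ellipse_axes <- c(major = 40, minor = 40)
  r <- render_cell(ph, c(200L, 200L))
  d <- shape_descriptors(r$mask)
  expect_lt(abs(d$circularity - 1), 0.03)

  ph$ellipse_axes <- c(major = 80, minor = 20)
  ph$center <- c(row = 110, col = 110)
  r2 <- render_cell(ph, c(220L, 220L))
  d2 <- shape_descriptors(r2$mask)
  expect_lt(abs(d2$aspect_ratio - 4) / 4, 0.05)
})

test_that("rendered marker intensity survives the blur over the mask", {
  ph <- with_seed(2, sample_cell_phenotype(donor_profile("F", 1, 1, 1)))
  ph$ssea3_intensity <- 150L
  ph$boundary_roughness <- 0      # isolate the blur from boundary geometry
  ph$center <- c(row = 100, col = 100)
  r <- render_cell(ph, c(200L, 200L))
  m <- mean(r$sprite[, , 2L][r$mask])
  expect_gte(m, 145)
  expect_lte(m, 155)
})

test_that("out-of-bounds placement fails naming the offending center", {
  ph <- with_seed(3, sample_cell_phenotype(donor_profile("G", 1, 1, 1)))
  ph$center <- c(row = 5, col = 100)
  expect_error(render_cell(ph, c(200L, 200L)), "5\\.0.*does not fit")
})

test_that("cohort generation is deterministic and conserves cells", {
  profs <- list(donor_profile("S1", 13, 0.4, 0.8),
                donor_profile("S2", 9, 0.7, 0.8))
  c1 <- generate_cohort(profs, seed = 42)
  c2 <- generate_cohort(profs, seed = 42)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$images[[1]]$px, c2$images[[1]]$px)
  expect_identical(nrow(c1$truth), 22L)
  expect_identical(nrow(c1$truth), length(c1$masks))
  for (img in c1$images) {
    expect_true(all(img$px >= 0 & img$px <= 255))
    expect_identical(dim(img$px)[3], 2L)
  }
  # boxes within bounds, one truth row per rendered mask
  cfg <- c1$config
  expect_true(all(c1$truth$r0 >= 0 & c1$truth$r1 <= cfg$canvas[1]))
  expect_true(all(c1$truth$c0 >= 0 & c1$truth$c1 <= cfg$canvas[2]))
})

test_that("per-donor truth fractions equal an independent recount", {
  profs <- study_profiles(40L, 0.9)
  coh <- generate_cohort(profs, seed = 77)
  recount <- vapply(split(coh$truth$multipotent, coh$truth$donor_id), mean, 0)
  agg <- stats::aggregate(multipotent ~ donor_id, coh$truth, mean)
  expect_equal(unname(recount[agg$donor_id]), agg$multipotent)
  expect_identical(as.integer(table(coh$truth$donor_id)),
                   rep(40L, 5L))
})

test_that("infeasible packings are rejected with an explicit error", {
  cfg <- cohort_image_config(canvas = c(160L, 160L), cells_per_image = 8L,
                             min_spacing = 120, max_place_tries = 20L)
  expect_error(generate_cohort(list(donor_profile("X", 8, 0.5, 0.5)),
                               cfg, seed = 1),
               "infeasible packing")
})

test_that("cohorts round-trip through TIFF + CSV", {
  dir <- tempfile("cohort")
  coh <- generate_cohort(list(donor_profile("S1", 5, 0.6, 0.9)), seed = 9)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(sort(names(back$images)), sort(names(coh$images)))
  expect_identical(back$images[[1]]$px, coh$images[[1]]$px)
  expect_equal(back$truth$multipotent, coh$truth$multipotent)
  expect_equal(back$truth$r0, coh$truth$r0)
  unlink(dir, recursive = TRUE)
})

test_that("at full coupling and zero roughness the families are separable", {
  prof <- donor_profile("H", 1, potency_fraction = 0.5, coupling = 1)
  with_seed(15, {
    desc <- t(replicate(40, {
      ph <- sample_cell_phenotype(prof)
      ph$boundary_roughness <- 0
      ph$center <- c(row = 110, col = 110)
      r <- render_cell(ph, c(220L, 220L))
      d <- shape_descriptors(r$mask)
      c(circ = d$circularity, ar = d$aspect_ratio,
        round = ph$shape_family == "round")
    }))
  })
  ar_round <- desc[desc[, "round"] == 1, "ar"]
  ar_elong <- desc[desc[, "round"] == 0, "ar"]
  expect_lt(max(ar_round), min(ar_elong))  # a threshold separates exactly
})
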