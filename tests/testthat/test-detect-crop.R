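test_that("oversegmentation partitions the image", {
  img <- matrix(100, 40, 40)
  lab <- oversegment(img, scale_param = 100, min_region_size = 10)
  expect_identical(max(lab), 1L)                       # constant image
  expect_identical(length(lab), 1600L)

  set.seed(5)
  img2 <- matrix(rnorm(60 * 60, 20, 4), 60, 60)
  img2[20:40, 20:40] <- img2[20:40, 20:40] + 150
  lab2 <- oversegment(img2, scale_param = 100, min_region_size = 20)
  expect_identical(sum(tabulate(lab2)), 3600L)         # pixel conservation
  expect_true(all(tabulate(lab2) >= 20))
  expect_error(oversegment(matrix(numeric(0), 0, 0)), "empty")
})

test_that("a bright disk separates from a clean background", {
  coh <- generate_cohort(list(donor_profile("A", 1, 1, 1)),
                         cohort_image_config(canvas = c(160L, 160L),
                                             cells_per_image = 1L),
                         seed = 8)
  img <- coh$images[[1]]
  lab <- oversegment(img$px[, , 1])
  mask_entry <- coh$masks[[1]]
  full <- matrix(FALSE, 160, 160)
  b <- mask_entry$box
  full[(b[["r0"]] + 1):b[["r1"]], (b[["c0"]] + 1):b[["c1"]]] <- mask_entry$mask
  # erode the mask by the blur band before asking for purity
  core <- full & !gaussian_blur(1 - full * 1, 1.5) > 0.05
  cell_labels <- lab[core]
  bg_label <- names(which.max(table(lab[!full])))
  expect_lt(mean(cell_labels == as.integer(bg_label)), 0.01)
})

test_that("hierarchical merging is greedy, monotone and emits all boxes", {
  img <- matrix(50, 20, 40)
  lab <- matrix(1L, 20, 40); lab[, 21:40] <- 2L
  props <- hierarchical_merge(lab, img)
  # two identical adjacent regions merge immediately into the full box
  merged <- props[props$score > 0, ]
  expect_identical(nrow(merged), 1L)
  expect_equal(unlist(merged[, c("r0", "r1", "c0", "c1")]),
               c(r0 = 0, r1 = 20, c0 = 0, c1 = 40))
  expect_gt(merged$sim_color, 0.999)

  one <- hierarchical_merge(matrix(1L, 10, 10), matrix(0, 10, 10))
  expect_identical(nrow(one), 1L)
  expect_equal(one$score, 0)
})

test_that("every planted cell is matched by some proposal at IoU 0.5", {
  coh <- cached("sel_cohort", generate_cohort(
    list(donor_profile("A", 12, 0.678, 0.9)),
    cohort_image_config(canvas = c(448L, 448L), cells_per_image = 12L),
    seed = 21))
  img <- coh$images[[1]]
  props <- propose_regions(img$px[, , 1])
  tt <- coh$truth
  best <- vapply(seq_len(nrow(tt)), function(i)
    max(box_iou_matrix(props[, c("r0", "r1", "c0", "c1")],
                       tt[i, c("r0", "r1", "c0", "c1")])), 0)
  expect_true(all(best >= 0.5))
  # merging is monotone: merge ranks are consecutive
  expect_identical(sort(props$score[props$score > 0]),
                   as.numeric(seq_len(sum(props$score > 0))))
})

test_that("crop filtering and IoU dedup behave as specified", {
  blank <- list(image_id = "img", px = array(5, c(64L, 64L, 2L)))
  props0 <- data.frame(r0 = numeric(0), r1 = numeric(0), c0 = numeric(0),
                       c1 = numeric(0), score = numeric(0))
  expect_length(crop_cells(blank, props0), 0L)

  two <- data.frame(r0 = c(10, 12), r1 = c(50, 52), c0 = c(10, 12),
                    c1 = c(50, 52), score = c(2, 1))
  expect_gt(box_iou(two[1, ], two[2, ]), 0.8)
  kept <- crop_cells(blank, two, min_area = 100, max_area = 4000,
                     dedup_iou = 0.5, refine = FALSE)
  expect_length(kept, 1L)

  # brute-force independence property on random boxes
  set.seed(31)
  n <- 40
  r0 <- runif(n, 0, 150); c0 <- runif(n, 0, 150)
  boxes <- data.frame(r0 = r0, r1 = r0 + runif(n, 20, 60),
                      c0 = c0, c1 = c0 + runif(n, 20, 60),
                      score = runif(n))
  keep <- morphopotency:::iou_dedup(boxes[, 1:4], boxes$score, 0.5,
                                    contain_thresh = 1.1)
  M <- box_iou_matrix(boxes[keep, 1:4], boxes[keep, 1:4])
  diag(M) <- 0
  expect_lte(max(M), 0.5)
  # greedy maximality: every suppressed box conflicts with a kept one
  for (i in setdiff(seq_len(n), keep)) {
    conf <- box_iou_matrix(boxes[i, 1:4], boxes[keep, 1:4])
    expect_gt(max(conf), 0.5)
  }
})

test_that("both detector paths find the planted cells and agree", {
  coh <- cached("sel_cohort", generate_cohort(
    list(donor_profile("A", 12, 0.678, 0.9)),
    cohort_image_config(canvas = c(448L, 448L), cells_per_image = 12L),
    seed = 21))
  sel <- detect_cohort(coh, "selective")
  msk <- detect_cohort(coh, "mask")
  mt_sel <- match_crops_to_truth(sel$table, coh$truth)
  mt_msk <- match_crops_to_truth(msk$table, coh$truth)
  expect_gte(mt_sel$recall, 0.9)
  expect_gte(mt_sel$precision, 0.9)
  expect_gte(mt_msk$recall, 0.9)
  expect_gte(mt_msk$precision, 0.9)
  M <- box_iou_matrix(sel$table[, c("r0", "r1", "c0", "c1")],
                      msk$table[, c("r0", "r1", "c0", "c1")])
  expect_true(all(apply(M, 1, max) >= 0.8))
  expect_true(all(sel$table$source == "selective_search"))
  expect_true(all(msk$table$source == "mask_fallback"))
})

test_that("crops carry congruent channels and respect padding", {
  coh <- generate_cohort(list(donor_profile("B", 4, 0.7, 0.9)), seed = 55)
  crops <- detect_cells(coh$images[[1]], "mask")
  for (cr in crops) {
    expect_identical(dim(cr$body), dim(cr$ssea3))
    expect_identical(dim(cr$mask), dim(cr$body))
    b <- cr$box
    expect_true(b[["r0"]] >= 0 && b[["c0"]] >= 0)
    expect_true(b[["r1"]] <= dim(coh$images[[1]]$px)[1])
  }
})
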