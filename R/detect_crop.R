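#' Graph-based oversegmentation of the body channel
#'
#' Partitions a single-channel 8-bit image into regions by the classic
#' graph-based method: an 8-connected grid graph with absolute intensity
#' difference edge weights, greedy merging under the adaptive threshold
#' \code{scale / |C|}, then absorption of regions smaller than
#' \code{min_region_size}. Every pixel belongs to exactly one region.
#'
#' @param body_channel Numeric matrix (0-255 scale).
#' @param scale_param Granularity constant (larger = fewer, larger regions).
#' @param min_region_size Minimum region size in pixels.
#' @param smooth_sigma Gaussian pre-smoothing in pixels.
#' @return Integer label matrix with contiguous labels \code{1..R}.
#' @export
oversegment <- function(body_channel, scale_param = 100, min_region_size = 50L,
                        smooth_sigma = 0.8) {
  if (length(body_channel) == 0) stop("empty image")
  img <- gaussian_blur(matrix(as.numeric(body_channel), nrow(body_channel)),
                       smooth_sigma)
  .fh_segment(img, scale_param, as.integer(min_region_size))
}

# Per-region descriptors for the similarity measures: size, bounding box,
# 25-bin intensity histogram and an 8-orientation x 10-bin gradient-magnitude
# texture histogram (both L1-normalized).
region_features <- function(labels, img) {
  H <- nrow(img); W <- ncol(img)
  gy <- rbind(img[2L, , drop = FALSE], img[-1L, , drop = FALSE]) -
    rbind(img[1L, , drop = FALSE], img[-H, , drop = FALSE])
  gx <- cbind(img[, 2L, drop = FALSE], img[, -1L, drop = FALSE]) -
    cbind(img[, 1L, drop = FALSE], img[, -W, drop = FALSE])
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)                      # (-pi, pi]
  obin <- pmin(8L, 1L + floor((ori + pi) / (2 * pi) * 8))
  mbin <- pmin(10L, 1L + floor(mag / (max(mag) + 1e-9) * 10))
  cbin <- pmin(25L, 1L + floor(img / 256 * 25))
  lab <- as.integer(labels)
  R <- max(lab)
  feats <- vector("list", R)
  rows <- row(img); cols <- col(img)
  tex_idx <- (obin - 1L) * 10L + mbin       # 1..80
  for (r in seq_len(R)) {
    sel <- lab == r
    ch <- tabulate(cbin[sel], 25L); ch <- ch / sum(ch)
    th <- tabulate(tex_idx[sel], 80L); th <- th / sum(th)
    feats[[r]] <- list(
      id = r, size = sum(sel),
      box = c(r0 = min(rows[sel]) - 1, r1 = max(rows[sel]),
              c0 = min(cols[sel]) - 1, c1 = max(cols[sel])),
      color = ch, texture = th)
  }
  feats
}

region_adjacency <- function(labels) {
  a <- labels[-nrow(labels), ]; b <- labels[-1L, ]
  v <- labels[, -ncol(labels)]; w <- labels[, -1L]
  pairs <- rbind(cbind(as.integer(a), as.integer(b)),
                 cbind(as.integer(v), as.integer(w)))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  unique(pairs)
}

box_union <- function(a, b) {
  c(r0 = min(a[["r0"]], b[["r0"]]), r1 = max(a[["r1"]], b[["r1"]]),
    c0 = min(a[["c0"]], b[["c0"]]), c1 = max(a[["c1"]], b[["c1"]]))
}

pair_similarity <- function(fa, fb, n_pixels, weights) {
  s_color <- sum(pmin(fa$color, fb$color))
  s_texture <- sum(pmin(fa$texture, fb$texture))
  s_size <- clip01(1 - (fa$size + fb$size) / n_pixels)
  bb <- box_union(fa$box, fb$box)
  s_fill <- clip01(1 - (box_area(bb) - fa$size - fb$size) / n_pixels)
  comps <- c(color = s_color, texture = s_texture, size = s_size,
             fill = s_fill)
  list(sim = sum(weights * comps) / sum(weights), components = comps)
}

#' Hierarchical region merging (selective-search proposals)
#'
#' Greedy agglomeration of the oversegmentation by a weighted combination of
#' color, texture, size and fill similarities. Every merge emits the merged
#' region's bounding box as a proposal; the initial regions' boxes are
#' included with score 0 and merges are scored by merge order, so later
#' (larger, more object-like) merges rank higher. Ties in similarity break on
#' the lexicographically smallest region-id pair, making the procedure
#' deterministic.
#'
#' @param labels Label matrix from [oversegment()].
#' @param img The image the labels were computed on (numeric matrix, 0-255).
#' @param weights Named non-negative weights for
#'   \code{color, texture, size, fill}.
#' @return Data frame of proposals: \code{r0, r1, c0, c1, score,
#'   sim_color, sim_texture, sim_size, sim_fill, n_pixels}.
#' @export
hierarchical_merge <- function(labels, img,
                               weights = c(color = 1, texture = 1,
                                           size = 1, fill = 1)) {
  stopifnot(all(weights >= 0), sum(weights) > 0)
  feats <- region_features(labels, matrix(as.numeric(img), nrow(img)))
  n_pixels <- length(labels)
  props <- lapply(feats, function(f)
    c(f$box, score = 0, sim_color = NA, sim_texture = NA, sim_size = NA,
      sim_fill = NA, n_pixels = f$size))
  adj <- region_adjacency(labels)
  nb <- lapply(seq_along(feats), function(i) integer(0))
  for (k in seq_len(nrow(adj))) {
    i <- adj[k, 1L]; j <- adj[k, 2L]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  alive <- rep(TRUE, length(feats))
  simkey <- function(i, j) paste(min(i, j), max(i, j))
  sims <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(adj))) {
    i <- adj[k, 1L]; j <- adj[k, 2L]
    assign(simkey(i, j),
           pair_similarity(feats[[i]], feats[[j]], n_pixels, weights), sims)
  }
  merge_rank <- 0L
  repeat {
    keys <- ls(sims)
    if (length(keys) == 0L) break
    vals <- vapply(keys, function(k) get(k, sims)$sim, 0)
    best <- max(vals)
    cand <- keys[vals >= best - 1e-12]
    # deterministic tie-break: smallest (id_a, id_b) pair
    ij <- do.call(rbind, lapply(strsplit(cand, " "), as.integer))
    pick <- order(ij[, 1L], ij[, 2L])[1L]
    i <- ij[pick, 1L]; j <- ij[pick, 2L]
    chosen <- get(simkey(i, j), sims)
    new_id <- length(feats) + 1L
    fi <- feats[[i]]; fj <- feats[[j]]
    wsum <- fi$size + fj$size
    feats[[new_id]] <- list(
      id = new_id, size = wsum, box = box_union(fi$box, fj$box),
      color = (fi$color * fi$size + fj$color * fj$size) / wsum,
      texture = (fi$texture * fi$size + fj$texture * fj$size) / wsum)
    merge_rank <- merge_rank + 1L
    props[[length(props) + 1L]] <- c(feats[[new_id]]$box, score = merge_rank,
                                     sim_color = chosen$components[["color"]],
                                     sim_texture = chosen$components[["texture"]],
                                     sim_size = chosen$components[["size"]],
                                     sim_fill = chosen$components[["fill"]],
                                     n_pixels = wsum)
    alive[c(i, j)] <- FALSE; alive[new_id] <- TRUE
    new_nb <- setdiff(unique(c(nb[[i]], nb[[j]])), c(i, j))
    new_nb <- new_nb[alive[new_nb]]
    nb[[new_id]] <- new_nb
    # drop all similarities touching i or j, add ones touching the new region
    for (k in keys) {
      ab <- as.integer(strsplit(k, " ")[[1L]])
      if (any(ab %in% c(i, j))) rm(list = k, envir = sims)
    }
    for (m in new_nb) {
      nb[[m]] <- c(setdiff(nb[[m]], c(i, j)), new_id)
      assign(simkey(new_id, m),
             pair_similarity(feats[[new_id]], feats[[m]], n_pixels, weights),
             sims)
    }
  }
  out <- as.data.frame(do.call(rbind, props))
  rownames(out) <- NULL
  out
}

#' Region proposals for one image (oversegment + merge)
#'
#' @inheritParams oversegment
#' @inheritParams hierarchical_merge
#' @return Proposal data frame (see [hierarchical_merge()]).
#' @export
propose_regions <- function(body_channel, scale_param = 100,
                            min_region_size = 50L,
                            weights = c(color = 1, texture = 1, size = 1,
                                        fill = 1)) {
  labels <- oversegment(body_channel, scale_param, min_region_size)
  hierarchical_merge(labels, body_channel, weights)
}

# Greedy IoU suppression: order by score (desc), keep a box only if its IoU
# with every already-kept box is <= threshold and it is not mostly contained
# in (or containing) a kept box.
iou_dedup <- function(boxes, scores, threshold, contain_thresh = 0.8) {
  keep <- integer(0)
  for (i in order(-scores, seq_along(scores))) {
    ok <- TRUE
    for (k in keep) {
      a <- boxes[i, , drop = FALSE]; b <- boxes[k, , drop = FALSE]
      inter <- max(0, min(a[["r1"]], b[["r1"]]) - max(a[["r0"]], b[["r0"]])) *
        max(0, min(a[["c1"]], b[["c1"]]) - max(a[["c0"]], b[["c0"]]))
      if (box_iou(a, b) > threshold ||
          inter / min(box_area(a), box_area(b)) > contain_thresh) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  sort(keep)
}

new_cell_crop <- function(image_id, crop_id, box, body, ssea3, mask, source) {
  structure(list(image_id = image_id, crop_id = crop_id, box = box,
                 body = body, ssea3 = ssea3, mask = mask, source = source),
            class = "cell_crop")
}

#' Filter, deduplicate and crop proposals into single-cell crops
#'
#' Proposals are filtered by pixel-box area and bounding-box aspect ratio,
#' deduplicated by greedy IoU suppression (higher score kept first), padded,
#' clipped to the image bounds and cropped congruently from both channels.
#'
#' @param image Cohort image entry (\code{list(image_id, px)}, \code{px} an
#'   H x W x 2 array) .
#' @param proposals Proposal data frame with \code{r0, r1, c0, c1, score}.
#' @param min_area,max_area Area filters on the unpadded box (px^2).
#' @param max_aspect Maximum bounding-box aspect ratio (long/short side).
#' @param dedup_iou Greedy suppression threshold.
#' @param pad Padding added to each side, clipped at borders.
#' @param source Provenance tag stored in each crop.
#' @param refine Tighten each surviving box to the bounding box of its
#'   foreground pixels (global Otsu threshold on the body channel) before
#'   deduplication, so crops frame the cell region rather than the merge
#'   geometry.
#' @return List of \code{cell_crop} objects (possibly empty).
#' @export
crop_cells <- function(image, proposals, min_area = 400, max_area = 25000,
                       max_aspect = 10, dedup_iou = 0.5, pad = 4L,
                       source = "selective_search", refine = TRUE) {
  H <- dim(image$px)[1]; W <- dim(image$px)[2]
  if (nrow(proposals) == 0L) return(list())
  h <- proposals$r1 - proposals$r0; w <- proposals$c1 - proposals$c0
  area <- h * w
  asp <- pmax(h, w) / pmax(1, pmin(h, w))
  ok <- area >= min_area & area <= max_area & asp <= max_aspect & h > 0 & w > 0
  proposals <- proposals[ok, , drop = FALSE]
  if (nrow(proposals) == 0L) return(list())
  if (refine) {
    body <- image$px[, , 1L]
    fg <- body > otsu_threshold(body)
    for (i in seq_len(nrow(proposals))) {
      rows <- (floor(proposals$r0[i]) + 1):ceiling(proposals$r1[i])
      cols <- (floor(proposals$c0[i]) + 1):ceiling(proposals$c1[i])
      sub <- fg[rows, cols, drop = FALSE]
      if (!any(sub)) next
      rr <- range(which(rowSums(sub) > 0)); cc <- range(which(colSums(sub) > 0))
      proposals$r0[i] <- rows[1] - 1 + rr[1] - 1
      proposals$r1[i] <- rows[1] - 1 + rr[2]
      proposals$c0[i] <- cols[1] - 1 + cc[1] - 1
      proposals$c1[i] <- cols[1] - 1 + cc[2]
    }
    area <- (proposals$r1 - proposals$r0) * (proposals$c1 - proposals$c0)
    proposals <- proposals[area >= min_area & area <= max_area, ,
                           drop = FALSE]
    if (nrow(proposals) == 0L) return(list())
  }
  keep <- iou_dedup(proposals[, c("r0", "r1", "c0", "c1")], proposals$score,
                    dedup_iou)
  proposals <- proposals[keep, , drop = FALSE]
  out <- vector("list", nrow(proposals))
  for (i in seq_len(nrow(proposals))) {
    r0 <- max(0L, floor(proposals$r0[i]) - pad)
    r1 <- min(H, ceiling(proposals$r1[i]) + pad)
    c0 <- max(0L, floor(proposals$c0[i]) - pad)
    c1 <- min(W, ceiling(proposals$c1[i]) + pad)
    out[[i]] <- new_cell_crop(
      image$image_id, sprintf("%s_crop%03d", image$image_id, i),
      c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
      body = image$px[(r0 + 1):r1, (c0 + 1):c1, 1L],
      ssea3 = image$px[(r0 + 1):r1, (c0 + 1):c1, 2L],
      mask = NULL, source = source)
  }
  out
}

# Threshold-based detector: Otsu on the body channel, connected components,
# size filter. On clean-background images this is near-exact and fast; it
# also supplies a per-crop mask.
detect_mask_fallback <- function(image, min_area = 400, max_area = 25000,
                                 pad = 4L) {
  body <- image$px[, , 1L]
  lab <- EBImage::bwlabel(body > otsu_threshold(body))
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0)
  if (length(idx) == 0L) return(list())
  labs <- lab[idx]
  ri <- (idx - 1L) %% H + 1L
  ci <- (idx - 1L) %/% H + 1L
  rmin <- tapply(ri, labs, min); rmax <- tapply(ri, labs, max)
  cmin <- tapply(ci, labs, min); cmax <- tapply(ci, labs, max)
  sizes <- tabulate(labs)
  out <- list()
  for (r in seq_along(sizes)) {
    if (sizes[r] < min_area || sizes[r] > max_area) next
    key <- as.character(r)
    r0 <- max(0L, rmin[[key]] - 1L - pad); r1 <- min(H, rmax[[key]] + pad)
    c0 <- max(0L, cmin[[key]] - 1L - pad); c1 <- min(W, cmax[[key]] + pad)
    out[[length(out) + 1L]] <- new_cell_crop(
      image$image_id, sprintf("%s_crop%03d", image$image_id, length(out) + 1L),
      c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
      body = image$px[(r0 + 1):r1, (c0 + 1):c1, 1L],
      ssea3 = image$px[(r0 + 1):r1, (c0 + 1):c1, 2L],
      mask = lab[(r0 + 1):r1, (c0 + 1):c1] == r, source = "mask_fallback")
  }
  out
}

#' Detect and crop single cells in one cohort image
#'
#' Two detectors are available: \code{"mask"} (Otsu threshold + connected
#' components; the default, adequate on clean backgrounds and the only path
#' that yields per-crop masks) and \code{"selective"} (graph oversegmentation
#' + hierarchical similarity merging, the region-proposal path).
#'
#' @param image Cohort image entry.
#' @param method \code{"mask"} or \code{"selective"}.
#' @param ... Passed to [crop_cells()] / the fallback detector.
#' @return List of \code{cell_crop} objects.
#' @export
detect_cells <- function(image, method = c("mask", "selective"), ...) {
  method <- match.arg(method)
  if (method == "mask") return(detect_mask_fallback(image, ...))
  props <- propose_regions(image$px[, , 1L])
  crop_cells(image, props, ...)
}

#' Detect cells across a whole cohort
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param method Detector, see [detect_cells()].
#' @param ... Passed to [detect_cells()].
#' @return List with \code{crops} (flat list of \code{cell_crop}) and
#'   \code{table} (one row per crop: image_id, crop_id, donor_id, box,
#'   source).
#' @export
detect_cohort <- function(cohort, method = c("mask", "selective"), ...) {
  method <- match.arg(method)
  crops <- list()
  for (img in cohort$images) crops <- c(crops, detect_cells(img, method, ...))
  tab <- do.call(rbind, lapply(crops, function(cr) {
    donor <- cohort$images[[cr$image_id]]$donor_id
    data.frame(image_id = cr$image_id, crop_id = cr$crop_id,
               donor_id = if (is.null(donor)) NA_character_ else donor,
               r0 = cr$box[["r0"]], r1 = cr$box[["r1"]],
               c0 = cr$box[["c0"]], c1 = cr$box[["c1"]],
               source = cr$source, stringsAsFactors = FALSE)
  }))
  list(crops = crops, table = tab)
}

#' Match detected crops to ground-truth boxes by IoU
#'
#' Greedy one-to-one matching in decreasing IoU order at a minimum IoU.
#'
#' @param crop_table Data frame with crop boxes (from [detect_cohort()]).
#' @param truth Cohort truth table.
#' @param min_iou Matching threshold (default 0.5).
#' @return List with \code{pairs} (crop_id, cell_id, iou), \code{recall},
#'   \code{precision}.
#' @export
match_crops_to_truth <- function(crop_table, truth, min_iou = 0.5) {
  pairs <- list()
  for (img in unique(truth$image_id)) {
    ct <- crop_table[crop_table$image_id == img, , drop = FALSE]
    tt <- truth[truth$image_id == img, , drop = FALSE]
    if (nrow(ct) == 0L || nrow(tt) == 0L) next
    M <- box_iou_matrix(ct[, c("r0", "r1", "c0", "c1")],
                        tt[, c("r0", "r1", "c0", "c1")])
    while (TRUE) {
      best <- which(M == max(M), arr.ind = TRUE)[1L, , drop = FALSE]
      if (M[best] < min_iou) break
      pairs[[length(pairs) + 1L]] <- data.frame(
        crop_id = ct$crop_id[best[1L]], cell_id = tt$cell_id[best[2L]],
        iou = M[best], stringsAsFactors = FALSE)
      M[best[1L], ] <- -1; M[, best[2L]] <- -1
      if (all(M < min_iou)) break
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(crop_id = character(0), cell_id = character(0),
               iou = numeric(0))
  list(pairs = pairs,
       recall = nrow(pairs) / nrow(truth),
       precision = if (nrow(crop_table)) nrow(pairs) / nrow(crop_table) else NA_real_)
}
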