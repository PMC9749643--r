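#' Donor profile for synthetic cohort generation
#'
#' A donor is the sampling unit of the study: each donor contributes a planted
#' multipotency fraction (the fraction of its cells that carry the potency
#' marker) and a shape-potency coupling strength. Coupling is the probability
#' that a multipotent cell is drawn from the round shape family and a
#' non-multipotent cell from the uniaxially elongated family: at coupling 1
#' morphology determines potency exactly, at 0.5 they are independent (the
#' falsification-control condition for any morphology-based classifier), and
#' at 0 they are perfectly anti-coupled.
#'
#' @param donor_id Short character label (e.g. \code{"S8"}).
#' @param n_cells Positive integer, number of cells to plant for this donor.
#' @param potency_fraction Real in \code{[0, 1]}: probability each cell is
#'   multipotent. The default 0.678 reproduces the 1254:596 class balance of
#'   the reference dataset.
#' @param coupling Real in \code{[0, 1]}: shape-potency coupling strength.
#' @return An object of class \code{donor_profile}.
#' @export
donor_profile <- function(donor_id, n_cells, potency_fraction = 0.678,
                          coupling = 0.9) {
  stopifnot(length(donor_id) == 1L, nchar(donor_id) >= 1L)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("n_cells must be a positive integer (>= 1)")
  if (potency_fraction < 0 || potency_fraction > 1)
    stop("potency_fraction must lie in [0, 1]")
  if (coupling < 0 || coupling > 1)
    stop("coupling must lie in [0, 1]")
  structure(list(donor_id = as.character(donor_id), n_cells = n_cells,
                 potency_fraction = potency_fraction, coupling = coupling),
            class = "donor_profile")
}

# Family-level shape priors. Roughness amplitudes are calibrated so that
# rendered masks reproduce the reference family means (circularity 0.469 /
# aspect ratio 1.528 for the round family; 0.262 / 4.162 for the elongated
# family): a smooth ellipse at aspect 1.5 has circularity ~0.94, so the low
# observed circularities force a rough, lobed boundary.
shape_family_params <- function() {
  list(
    round = list(aspect_mean = 1.528, aspect_sdlog = 0.12,
                 major_range = c(17, 26), roughness = 0.19,
                 freq_range = c(8L, 11L)),
    elongated = list(aspect_mean = 4.162, aspect_sdlog = 0.10,
                     major_range = c(32, 46), roughness = 0.33,
                     freq_range = c(8L, 11L))
  )
}

#' Sample a single cell phenotype from a donor profile
#'
#' Draws potency (Bernoulli with the donor's potency fraction), a shape family
#' coupled to potency with the donor's coupling probability, ellipse axes and
#' boundary roughness from family priors, and the two channel intensities. The
#' potency-marker (SSEA3-like) intensity is drawn from a high mode
#' (mean 150, sd 20) for multipotent cells and a low mode (mean 45, sd 15)
#' otherwise, straddling the 8-bit labelling threshold of 90.
#'
#' Consumes the current RNG stream; call \code{set.seed()} first (or use the
#' cohort generator, which seeds everything from its master seed).
#'
#' @param profile A [donor_profile()].
#' @param intensity_modes List with \code{high = c(mean, sd)} and
#'   \code{low = c(mean, sd)} for the potency channel.
#' @return An object of class \code{cell_phenotype}.
#' @export
sample_cell_phenotype <- function(profile,
                                  intensity_modes = list(high = c(150, 20),
                                                         low = c(45, 15))) {
  stopifnot(inherits(profile, "donor_profile"))
  fam <- shape_family_params()
  multipotent <- stats::runif(1) < profile$potency_fraction
  match <- stats::runif(1) < profile$coupling
  shape_family <- if (multipotent == match) "round" else "elongated"
  p <- fam[[shape_family]]
  aspect <- exp(stats::rnorm(1, log(p$aspect_mean), p$aspect_sdlog))
  aspect <- max(1.05, aspect)
  major <- stats::runif(1, p$major_range[1], p$major_range[2])
  minor <- major / aspect
  freq <- sample(seq(p$freq_range[1], p$freq_range[2]), 1L)
  mode <- if (multipotent) intensity_modes$high else intensity_modes$low
  ssea3 <- as.integer(round(clip255(stats::rnorm(1, mode[1], mode[2]))))
  body <- as.integer(round(clip255(stats::rnorm(1, 140, 15))))
  structure(list(
    multipotent = multipotent,
    shape_family = shape_family,
    ellipse_axes = c(major = major, minor = minor),
    boundary_roughness = p$roughness,
    roughness_freq = freq,
    roughness_phase = stats::runif(1, 0, 2 * pi),
    orientation = stats::runif(1, 0, pi),
    ssea3_intensity = ssea3,
    body_intensity = body,
    center = c(row = NA_real_, col = NA_real_)
  ), class = "cell_phenotype")
}

# Radial boundary function of a phenotype: a rotated ellipse modulated by a
# sinusoidal lobe pattern. Star-shaped by construction (single component).
phenotype_radius <- function(ph, theta) {
  a <- ph$ellipse_axes[["major"]]; b <- ph$ellipse_axes[["minor"]]
  phi <- theta - ph$orientation
  r_ell <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  r_ell * (1 + ph$boundary_roughness *
             sin(ph$roughness_freq * theta + ph$roughness_phase))
}

# Analytic boundary polygon (dense), used for ground-truth shape scalars.
phenotype_polygon <- function(ph, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- phenotype_radius(ph, th)
  cbind(row = r * sin(th), col = r * cos(th))
}

polygon_perimeter <- function(xy) {
  d <- xy - xy[c(2:nrow(xy), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_area <- function(xy) {
  x <- xy[, 2L]; y <- xy[, 1L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Render one cell into a sprite, mask and bounding box
#'
#' Rasterizes the phenotype's star-shaped boundary at the phenotype's center
#' on a canvas of the given shape. Both channels carry the phenotype's flat
#' intensity over the mask, softened by a Gaussian blur of \code{blur_sigma}.
#'
#' @param phenotype A \code{cell_phenotype} whose \code{center} is set.
#' @param canvas_shape Integer (rows, cols) of the target canvas.
#' @param blur_sigma Gaussian blur of the rendered intensities, in pixels.
#' @return List with \code{sprite} (h x w x 2 array, channels body then
#'   potency marker), \code{mask} (h x w logical), \code{box} (0-based
#'   half-open canvas box of the sprite window) and \code{mask_box} (tight
#'   box of the mask).
#' @export
render_cell <- function(phenotype, canvas_shape, blur_sigma = 0.6) {
  ph <- phenotype
  ctr <- ph$center
  if (any(is.na(ctr))) stop("phenotype center is not set")
  rmax <- max(phenotype_radius(ph, seq(0, 2 * pi, length.out = 360L)))
  half <- ceiling(rmax + 3 * blur_sigma + 1)
  r0 <- floor(ctr[["row"]]) - half; r1 <- floor(ctr[["row"]]) + half + 1
  c0 <- floor(ctr[["col"]]) - half; c1 <- floor(ctr[["col"]]) + half + 1
  if (r0 < 0 || c0 < 0 || r1 > canvas_shape[1] || c1 > canvas_shape[2])
    stop(sprintf("cell at center (%.1f, %.1f) does not fit the %d x %d canvas",
                 ctr[["row"]], ctr[["col"]], canvas_shape[1], canvas_shape[2]))
  rows <- seq(r0, r1 - 1L); cols <- seq(c0, c1 - 1L)
  dy <- outer(rows - ctr[["row"]], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - ctr[["col"]])
  theta <- atan2(dy, dx)
  dist <- sqrt(dy^2 + dx^2)
  mask <- dist <= phenotype_radius(ph, theta)
  bm <- gaussian_blur(mask * 1, blur_sigma)   # both channels share the mask
  sprite <- array(0, c(length(rows), length(cols), 2L))
  sprite[, , 1L] <- bm * ph$body_intensity
  sprite[, , 2L] <- bm * ph$ssea3_intensity
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  mask_box <- c(r0 = r0 + rr[1] - 1, r1 = r0 + rr[2],
                c0 = c0 + cc[1] - 1, c1 = c0 + cc[2])
  list(sprite = sprite, mask = mask,
       box = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1),
       mask_box = mask_box)
}

#' Image-level configuration of the cohort generator
#'
#' @param canvas Integer (rows, cols) canvas size per image.
#' @param cells_per_image Cells planted per image (last image of a donor may
#'   carry fewer).
#' @param background_mean,background_sd Background intensity model (8-bit
#'   units); the defaults give the clean, low-noise background the detection
#'   step assumes.
#' @param min_spacing Minimum center-to-center distance between cells of the
#'   same image, in pixels.
#' @param blur_sigma Per-cell Gaussian blur in pixels.
#' @param max_place_tries Rejection-sampling budget per cell before the
#'   generator declares the packing infeasible.
#' @return A list of class \code{cohort_image_config}.
#' @export
cohort_image_config <- function(canvas = c(448L, 448L), cells_per_image = 6L,
                                background_mean = 8, background_sd = 3,
                                min_spacing = 95, blur_sigma = 0.6,
                                max_place_tries = 500L) {
  structure(list(canvas = as.integer(canvas),
                 cells_per_image = as.integer(cells_per_image),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 min_spacing = min_spacing, blur_sigma = blur_sigma,
                 max_place_tries = as.integer(max_place_tries)),
            class = "cohort_image_config")
}

#' Generate a synthetic multi-donor cohort
#'
#' Produces two-channel 8-bit images (channel 1: cell-body marker, channel 2:
#' potency marker) together with a per-cell ground-truth table. Cell centers
#' are placed by rejection sampling under a minimum-spacing constraint;
#' generation is fully deterministic given \code{seed}.
#'
#' @param profiles List of [donor_profile()] objects (one per donor).
#' @param image_config A [cohort_image_config()].
#' @param seed Integer master seed.
#' @return An object of class \code{synthetic_cohort}: \code{images} (list of
#'   \code{list(image_id, donor_id, px)} with \code{px} an H x W x 2 integer
#'   array), \code{truth} (data frame, one row per rendered cell with 0-based
#'   half-open boxes), and \code{masks} (per-cell window masks keyed by
#'   \code{cell_id}).
#' @export
generate_cohort <- function(profiles, image_config = cohort_image_config(),
                            seed = 1L) {
  if (inherits(profiles, "donor_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "donor_profile")))
  cfg <- image_config
  with_seed(seed, {
    images <- list(); truth <- list(); masks <- list()
    img_n <- 0L
    for (prof in profiles) {
      remaining <- prof$n_cells
      cell_n <- 0L
      while (remaining > 0L) {
        k <- min(cfg$cells_per_image, remaining)
        remaining <- remaining - k
        img_n <- img_n + 1L
        image_id <- sprintf("img%03d", img_n)
        px <- array(0, c(cfg$canvas[1], cfg$canvas[2], 2L))
        # N(8, 3) backgrounds cannot reach 255; only the lower clip matters,
        # and sprites (blurred 0/1 mask x 8-bit intensity) stay in range
        px[, , 1L] <- pmax(0, stats::rnorm(prod(cfg$canvas),
                                           cfg$background_mean,
                                           cfg$background_sd))
        px[, , 2L] <- pmax(0, stats::rnorm(prod(cfg$canvas),
                                           cfg$background_mean,
                                           cfg$background_sd))
        centers <- matrix(numeric(0), 0L, 2L)
        for (ci in seq_len(k)) {
          ph <- sample_cell_phenotype(prof)
          rmax <- max(phenotype_radius(ph, seq(0, 2 * pi, length.out = 360L)))
          margin <- ceiling(rmax + 3 * cfg$blur_sigma + 2)
          placed <- FALSE
          for (try in seq_len(cfg$max_place_tries)) {
            ctr <- c(stats::runif(1, margin, cfg$canvas[1] - margin),
                     stats::runif(1, margin, cfg$canvas[2] - margin))
            ok <- nrow(centers) == 0L ||
              min(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 2,
                                                 byrow = TRUE))^2))) >=
              cfg$min_spacing
            if (ok) { placed <- TRUE; break }
          }
          if (!placed)
            stop(sprintf(paste0("infeasible packing: could not place cell %d",
                                " of image %s after %d tries"),
                         ci, image_id, cfg$max_place_tries))
          centers <- rbind(centers, ctr)
          ph$center <- c(row = ctr[1], col = ctr[2])
          rend <- render_cell(ph, cfg$canvas, cfg$blur_sigma)
          b <- rend$box
          rows <- (b[["r0"]] + 1):b[["r1"]]; cols <- (b[["c0"]] + 1):b[["c1"]]
          px[rows, cols, 1L] <- pmax(px[rows, cols, 1L], rend$sprite[, , 1L])
          px[rows, cols, 2L] <- pmax(px[rows, cols, 2L], rend$sprite[, , 2L])
          cell_n <- cell_n + 1L
          cell_id <- sprintf("%s_c%04d", prof$donor_id, cell_n)
          poly <- phenotype_polygon(ph)
          circ_true <- 4 * pi * polygon_area(poly) / polygon_perimeter(poly)^2
          truth[[length(truth) + 1L]] <- data.frame(
            image_id = image_id, donor_id = prof$donor_id, cell_id = cell_id,
            r0 = rend$mask_box[["r0"]], r1 = rend$mask_box[["r1"]],
            c0 = rend$mask_box[["c0"]], c1 = rend$mask_box[["c1"]],
            multipotent = ph$multipotent, shape_family = ph$shape_family,
            ssea3_intensity = ph$ssea3_intensity,
            body_intensity = ph$body_intensity,
            circularity_true = circ_true,
            aspect_true = ph$ellipse_axes[["major"]] / ph$ellipse_axes[["minor"]],
            stringsAsFactors = FALSE)
          masks[[cell_id]] <- list(box = rend$box, mask = rend$mask)
        }
        px <- round(px)
        storage.mode(px) <- "integer"
        images[[image_id]] <- list(image_id = image_id,
                                   donor_id = prof$donor_id, px = px)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    structure(list(images = images, truth = truth, masks = masks,
                   config = cfg, seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d images, %d cells, %d donors\n",
              length(x$images), nrow(x$truth),
              length(unique(x$truth$donor_id))))
  invisible(x)
}

#' Write a cohort to disk as two-page TIFFs plus a truth-table CSV
#'
#' Each image becomes an 8-bit two-page TIFF (page 1: body channel, page 2:
#' potency marker channel); the truth table is written as \code{truth.csv}.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (img in cohort$images) {
    pages <- list(img$px[, , 1L] / 255, img$px[, , 2L] / 255)
    tiff::writeTIFF(pages, file.path(dir, paste0(img$image_id, ".tif")),
                    bits.per.sample = 8L)
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing \code{*.tif} two-page images and
#'   \code{truth.csv}.
#' @return A \code{synthetic_cohort} (without per-cell masks, which are not
#'   serialized).
#' @export
read_cohort <- function(dir) {
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "\\.tif$", full.names = TRUE))
  images <- list()
  donor_of <- truth$donor_id[match(sub("\\.tif$", "", basename(files)),
                                   truth$image_id)]
  for (i in seq_along(files)) {
    pages <- tiff::readTIFF(files[i], all = TRUE)
    id <- sub("\\.tif$", "", basename(files[i]))
    px <- array(0L, c(dim(pages[[1]])[1], dim(pages[[1]])[2], 2L))
    px[, , 1L] <- as.integer(round(pages[[1]] * 255))
    px[, , 2L] <- as.integer(round(pages[[2]] * 255))
    images[[id]] <- list(image_id = id, donor_id = donor_of[i], px = px)
  }
  structure(list(images = images, truth = truth, masks = NULL, config = NULL,
                 seed = NA_integer_), class = "synthetic_cohort")
}
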