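# Shared fixtures (built in code) and a per-session cache for the expensive
# end-to-end objects reused across test files.

make_disk_mask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- r + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

make_rect_mask <- function(h, w, pad = 10L) {
  m <- matrix(0, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1
  m
}

make_ellipse_mask <- function(a, b, pad = 10L) {
  n <- 2L * max(a, b) + 2L * pad + 1L
  ctr <- max(a, b) + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - ctr) / a)^2 + ((j - ctr) / b)^2 <= 1)
}

# analytic closed curves (row, col), no rasterization
analytic_circle <- function(r, n = 360L, ctr = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(row = ctr[1] + r * sin(t), col = ctr[2] + r * cos(t))
}

analytic_ellipse <- function(a, b, n = 360L, theta = 0, ctr = c(0, 0),
                             scale = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- cbind(a * sin(t), b * cos(t))
  R <- rbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
  sweep(scale * (p %*% R), 2L, -ctr)
}

# The five-donor study design: planted potency fractions spanning 0.2-0.8.
study_profiles <- function(n_cells = 60L, coupling = 0.9) {
  fr <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  lapply(1:5, function(i)
    donor_profile(paste0("S", i), n_cells, fr[i], coupling))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Desk-scale study configuration used by the end-to-end checks: input side
# 112 (same 28-px working map as the 224 default), scratch backbone,
# learning rate 3e-3 (converges within the 50-epoch cap so early stopping
# engages), patience 10.
study_side <- 112L
study_spec <- function() model_spec(input_side = study_side, channels = 1L,
                                    working_side = 28L)
study_config <- function(seed = 1L)
  train_config(learning_rate = 3e-3, max_epochs = 50L, patience = 10L,
               batch_size = 32L, seed = seed)

# One trained end-to-end pipeline on the 5 x 60-cell coupling-0.9 cohort.
study_pipeline <- function() {
  cached("study_pipeline", run_potency_pipeline(
    study_profiles(60L, 0.9), cohort_image_config(), seed = 101L,
    detector = "mask", side = study_side, spec = study_spec(),
    config = study_config()))
}

# 20 independently seeded evaluation cohorts (200 cells/donor) scored with
# the trained classifier.
study_evaluations <- function() {
  cached("study_evaluations", {
    model <- study_pipeline()$model
    lapply(1:20, function(i) evaluate_on_cohort(
      model, study_profiles(200L, 0.9), cohort_image_config(),
      seed = 2000L + i, detector = "mask"))
  })
}

# Falsification control: shape independent of potency. Under the generator's
# parameterization (shape matches potency with probability = coupling) the
# independence point is coupling 0.5.
study_control <- function() {
  cached("study_control", {
    pipe <- run_potency_pipeline(
      study_profiles(60L, 0.5), cohort_image_config(), seed = 301L,
      detector = "mask", side = study_side, spec = study_spec(),
      config = study_config())
    ev <- evaluate_on_cohort(pipe$model, study_profiles(100L, 0.5),
                             cohort_image_config(), seed = 2101L,
                             detector = "mask")
    list(pipe = pipe, eval = ev)
  })
}
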