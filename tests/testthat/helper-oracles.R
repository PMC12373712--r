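# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check: the convolution
# oracle is an explicit O(n^2) loop (the package uses FFT convolution),
# the ANOVA oracle is a hand-written sums-of-squares decomposition, and
# the searchlight oracle enumerates lattice offsets.

# brute-force discrete convolution at microtime resolution, then
# downsampled to the TR grid
oracle_convolve <- function(onsets, n_vol, tr, kernel, weights = NULL,
                            dt = 0.1) {
  if (is.null(weights)) weights <- rep(1, length(onsets))
  n_micro <- ceiling(n_vol * tr / dt) + length(kernel)
  stick <- numeric(n_micro)
  for (k in seq_along(onsets)) {
    i <- round(onsets[k] / dt) + 1
    stick[i] <- stick[i] + weights[k]
  }
  conv <- numeric(n_micro)
  for (i in seq_len(n_micro)) {
    jmax <- min(i, length(kernel))
    acc <- 0
    for (j in seq_len(jmax)) acc <- acc + stick[i - j + 1] * kernel[j]
    conv[i] <- acc
  }
  conv[round((seq_len(n_vol) - 1) * tr / dt) + 1]
}

# exhaustive lattice enumeration of sphere members around an interior
# center
oracle_sphere_offsets <- function(radius_mm, voxel_mm) {
  r <- ceiling(radius_mm / voxel_mm)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- (off$dx^2 + off$dy^2 + off$dz^2) * voxel_mm^2 <= radius_mm^2 + 1e-9
  off[keep, , drop = FALSE]
}

# one-way repeated-measures F from first principles on a subject x
# category cell-mean table
oracle_rm_anova_f <- function(cells) {
  # cells: matrix subjects x categories
  n <- nrow(cells); k <- ncol(cells)
  grand <- mean(cells)
  ss_cond <- n * sum((colMeans(cells) - grand)^2)
  ss_subj <- k * sum((rowMeans(cells) - grand)^2)
  ss_tot <- sum((cells - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  list(F = (ss_cond / df1) / (ss_err / df2), df1 = df1, df2 = df2)
}

# shared small grid + masks (computed once per test run)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_grid_and_masks(c(12, 12, 12), seed = 1,
                                        n_voxels = 160)
    }
    cache
  }
})

# simulate one session end-to-end and return design, runs and per-region
# pattern sets
simulate_session <- function(gm, context = "HP", phase = "visible",
                             amplitude = 0, rho = 0.7,
                             history_increment = 0, ar = 0.3, sd = 1,
                             drift = 0, seed = 1,
                             trials_per_run_cell = 20, n_runs = 2,
                             region = "lowerV1") {
  design <- generate_design(context, phase, seed = seed, n_runs = n_runs,
                            trials_per_run_cell = trials_per_run_cell)
  effects <- effect_spec(gm$masks, amplitude = amplitude, rho = rho,
                         history_increment = history_increment,
                         seed = seed + 1000L)
  noise <- noise_spec(ar = ar, sd = sd, drift_amplitude = drift)
  runs <- simulate_bold(design, gm$grid, gm$masks, effects, noise,
                        seed = seed + 2000L)
  betas <- suppressMessages(fit_lss_betas(runs, design))
  patterns <- extract_roi_patterns(betas, gm$masks[[region]], design)
  list(design = design, effects = effects, runs = runs, betas = betas,
       patterns = patterns)
}

# hand-built design object (bypasses the generator) for GLM oracle tests
# needing controlled onsets
manual_design <- function(onsets, conditions, run = 1L, tr = 2,
                          duration = 1) {
  d <- tibble::tibble(
    run = run, trial = seq_along(onsets), onset = onsets,
    duration = duration, horizontal_duration = duration / 2,
    vertical_duration = duration / 2,
    direction = sub("_.*", "", conditions),
    velocity = "fast", congruency = "congruent",
    phase = "visible", context = "HP", condition = conditions
  )
  n_runs <- length(unique(run))
  run_len <- vapply(split(d, d$run), function(x) {
    as.integer(ceiling((max(x$onset + x$duration) + 20) / tr))
  }, integer(1))
  structure(
    tibble::new_tibble(d, nrow = nrow(d), class = "ip_design"),
    n_runs = n_runs, tr = tr, run_length_volumes = unname(run_len),
    run_configuration = rep("up-fast/down-slow", n_runs), seed = 0L
  )
}

# pattern_set built directly from a matrix (skips the GLM chain)
manual_pattern_set <- function(X, voxels, run, grid,
                               meta_extra = NULL) {
  meta <- tibble::tibble(run = run, trial = seq_len(nrow(X)))
  if (!is.null(meta_extra)) meta <- dplyr::bind_cols(meta, meta_extra)
  structure(
    list(matrix = X, voxels = voxels, meta = meta, region = "synthetic",
         phase = "visible", context = "HP"),
    class = "pattern_set"
  )
}
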