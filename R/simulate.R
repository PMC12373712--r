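#' Specify planted condition effects
#'
#' Draws, once per region, a multivoxel response pattern for every
#' direction x velocity x congruency condition and both phases. Patterns
#' are standard-normal over mask voxels and z-scored, so a condition
#' amplitude `a` yields a single-trial contrast-to-noise ratio of
#' `a / noise_sd` at signal voxels. The occluded-phase pattern of each
#' condition shares a correlation `rho` with its visible-phase counterpart:
#' `rho = 1` makes visible-trained classifiers transfer perfectly to the
#' occluded phase, `rho = 0` makes the phases carry unrelated patterns.
#'
#' @param masks Named list of `roi_mask` objects (see
#'   [generate_grid_and_masks()]).
#' @param amplitude Scalar response amplitude per trial, or a named vector
#'   over condition labels (`direction_velocity_congruency`).
#' @param rho Visible/occluded pattern correlation in `[0, 1]`.
#' @param history_increment Spatially uniform response amplitude added,
#'   over all mask voxels, to trials whose predecessor in the run belonged
#'   to the other congruency category (the CI and IC trial-history cells);
#'   a univariate effect detectable in the ROI-mean betas.
#' @param seed Integer seed for the pattern draws.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(masks, amplitude = 1, rho = 0.7,
                        history_increment = 0, seed = 1) {
  stopifnot(rho >= 0, rho <= 1)
  conds <- as.vector(outer(
    c("up_fast", "down_fast", "up_slow", "down_slow"),
    c("congruent", "incongruent"), paste, sep = "_"
  ))
  znorm <- function(x) {
    if (stats::sd(x) == 0) return(x * 0)
    (x - mean(x)) / stats::sd(x)
  }
  patterns <- purrr::imap(masks, function(mask, region) {
    nv <- length(mask$member_voxels)
    with_substream(seed, paste0("effects/", region), {
      vis <- vapply(conds, function(cc) znorm(stats::rnorm(nv)), numeric(nv))
      ind <- vapply(conds, function(cc) znorm(stats::rnorm(nv)), numeric(nv))
      occ <- apply(rho * vis + sqrt(1 - rho^2) * ind, 2, znorm)
      colnames(occ) <- conds
      list(visible = vis, occluded = occ)
    })
  })
  structure(
    list(patterns = patterns, amplitude = amplitude, rho = rho,
         history_increment = history_increment, conditions = conds,
         seed = seed),
    class = "effect_spec"
  )
}

#' Specify the noise model of simulated BOLD runs
#'
#' @param ar AR(1) coefficient of the temporal noise (0 = white).
#' @param sd Marginal standard deviation of the noise, signal units.
#' @param drift_amplitude Amplitude of a slow cosine drift (random phase
#'   per voxel, 128 s period).
#' @param baseline Constant baseline intensity.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(ar = 0.3, sd = 1, drift_amplitude = 0.5,
                       baseline = 100) {
  stopifnot(abs(ar) < 1, sd >= 0, drift_amplitude >= 0)
  structure(list(ar = ar, sd = sd, drift_amplitude = drift_amplitude,
                 baseline = baseline),
            class = "noise_spec")
}

# per-trial planted pattern amplitude (condition effect only; the
# trial-history increment is a separate spatially uniform component)
trial_amplitudes <- function(design, effects) {
  amp <- effects$amplitude
  if (length(amp) == 1) rep(amp, nrow(design)) else {
    unname(amp[design$condition])
  }
}

# logical: trial follows a predecessor of the other congruency category
switch_trials <- function(design) {
  unlist(purrr::map(split(design$congruency, design$run), function(cg) {
    c(FALSE, cg[-1] != cg[-length(cg)])
  }), use.names = FALSE)
}

#' Simulate 4D BOLD runs with planted multivoxel patterns
#'
#' Each voxel time series is `baseline + signal + drift + AR(1) noise`,
#' where the signal sums, over trials, the planted amplitude times the
#' voxel's condition-pattern weight times a canonical HRF locked to the
#' trial onset (built at 0.1 s microtime and sampled on the TR grid).
#' Voxels outside every mask carry noise only. Motion parameters are six
#' independent Gaussian random walks. Fully deterministic given `seed`.
#'
#' @param design An [generate_design()] tibble.
#' @param grid A [volume_grid()].
#' @param masks Named list of `roi_mask` objects.
#' @param effects An [effect_spec()] built on `masks`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A list of `bold_run` objects: `data` (4D array `[x, y, z, t]`),
#'   `tr`, `motion_params` (t x 6 matrix), `run`, and `ground_truth`
#'   (per-trial planted amplitudes and the condition patterns).
#' @export
simulate_bold <- function(design, grid, masks, effects, noise, seed) {
  tr <- attr(design, "tr")
  run_len <- attr(design, "run_length_volumes")
  for (m in masks) {
    for (ph in c("visible", "occluded")) {
      pat <- effects$patterns[[m$region]][[ph]]
      if (nrow(pat) != length(m$member_voxels)) {
        stop("pattern rows (", nrow(pat), ") do not match mask '", m$region,
             "' size (", length(m$member_voxels), ")", call. = FALSE)
      }
    }
  }
  amps <- trial_amplitudes(design, effects)
  switches <- switch_trials(design)
  basis <- hrf_basis()
  nvox <- prod(grid$dims)

  purrr::map(sort(unique(design$run)), function(r) {
    ev <- design[design$run == r, ]
    a <- amps[design$run == r]
    sw <- switches[design$run == r]
    nt <- run_len[r]
    sig <- matrix(0, nvox, nt)
    # spatially uniform response increment on congruency-switch trials:
    # a univariate amplitude effect, visible to the ROI-mean analysis
    hist_course <- if (effects$history_increment != 0 && any(sw)) {
      convolve_onsets(ev$onset[sw], nt, tr, basis$hrf,
                      weights = rep(effects$history_increment, sum(sw)))
    } else {
      NULL
    }
    for (m in masks) {
      pat <- effects$patterns[[m$region]][[ev$phase[1]]]
      courses <- vapply(effects$conditions, function(cc) {
        sel <- ev$condition == cc
        if (!any(sel)) return(numeric(nt))
        convolve_onsets(ev$onset[sel], nt, tr, basis$hrf, weights = a[sel])
      }, numeric(nt))
      sig[m$member_voxels, ] <- sig[m$member_voxels, ] +
        pat %*% t(courses)
      if (!is.null(hist_course)) {
        sig[m$member_voxels, ] <- sig[m$member_voxels, ] +
          matrix(hist_course, length(m$member_voxels), nt, byrow = TRUE)
      }
    }
    eps <- with_substream(seed, paste0("noise/run", r), {
      if (noise$sd == 0) {
        matrix(0, nt, nvox)
      } else {
        w <- matrix(stats::rnorm(nt * nvox, sd = noise$sd * sqrt(1 - noise$ar^2)),
                    nt, nvox)
        if (noise$ar != 0) {
          matrix(stats::filter(w, noise$ar, method = "recursive"),
                 nt, nvox)
        } else {
          w
        }
      }
    })
    drift <- with_substream(seed, paste0("drift/run", r), {
      if (noise$drift_amplitude == 0) {
        matrix(0, nt, nvox)
      } else {
        phase <- stats::runif(nvox, 0, 2 * pi)
        tt <- (seq_len(nt) - 1) * tr
        noise$drift_amplitude *
          cos(outer(tt, rep(2 * pi / 128, nvox)) +
                matrix(phase, nt, nvox, byrow = TRUE))
      }
    })
    motion <- with_substream(seed, paste0("motion/run", r), {
      apply(matrix(stats::rnorm(nt * 6, sd = 0.01), nt, 6), 2, cumsum)
    })
    dat <- noise$baseline + t(sig) + eps + drift # time x voxels
    arr <- array(t(dat), dim = c(grid$dims, nt))
    structure(
      list(data = arr, tr = tr, motion_params = motion, run = r,
           ground_truth = list(
             trials = tibble::tibble(run = ev$run, trial = ev$trial,
                                     condition = ev$condition,
                                     amplitude = a, switch_trial = sw),
             patterns = effects$patterns,
             history_increment = effects$history_increment
           )),
      class = "bold_run"
    )
  })
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> run %d: %d x %d x %d voxels, %d volumes (TR %.1f s)\n",
              x$run, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

# time x voxels matrix view of a bold_run
bold_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}

#' Write a simulated run as NIfTI plus a motion-parameter TSV
#'
#' @param run A `bold_run`.
#' @param grid The [volume_grid()] it was simulated on.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, a list with `bold` and `motion` paths.
#' @export
write_bold_nifti <- function(run, grid, dir, prefix = "bold") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bold_path <- file.path(dir, sprintf("%s_run-%02d.nii.gz", prefix, run$run))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size, 3), run$tr)
  RNifti::writeNifti(img, bold_path)
  mot <- tibble::as_tibble(run$motion_params, .name_repair = ~ paste0(
    c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  ))
  mot_path <- file.path(dir, sprintf("%s_run-%02d_motion.tsv", prefix, run$run))
  readr::write_tsv(mot, mot_path)
  invisible(list(bold = bold_path, motion = mot_path))
}

#' Read a run written by [write_bold_nifti()]
#'
#' @param bold_path NIfTI path.
#' @param motion_path Motion TSV path.
#' @param run Run index to attach.
#' @return A `bold_run` (without ground truth).
#' @export
read_bold_nifti <- function(bold_path, motion_path, run = 1L) {
  img <- RNifti::readNifti(bold_path)
  arr <- as.array(img)
  mot <- as.matrix(readr::read_tsv(motion_path, show_col_types = FALSE))
  structure(
    list(data = arr, tr = RNifti::pixdim(img)[4], motion_params = mot,
         run = run, ground_truth = NULL),
    class = "bold_run"
  )
}
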