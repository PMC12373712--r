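#' Cosine drift basis
#'
#' DCT-II columns modelling slow scanner drift up to a period cutoff, the
#' convention of standard fMRI design-matrix builders.
#'
#' @param n_vol Number of volumes.
#' @param tr Repetition time (s).
#' @param cutoff High-pass period cutoff (s); components slower than it are
#'   modelled.
#' @return A `n_vol` x `k` matrix (possibly 0 columns).
#' @export
cosine_drift_basis <- function(n_vol, tr, cutoff = 128) {
  dur <- n_vol * tr
  k <- max(0L, floor(2 * dur / cutoff))
  if (k == 0L) return(matrix(0, n_vol, 0))
  t0 <- seq_len(n_vol) - 1
  b <- vapply(seq_len(k), function(j) {
    cos(pi * (2 * t0 + 1) * j / (2 * n_vol))
  }, numeric(n_vol))
  colnames(b) <- paste0("drift_", seq_len(k))
  b
}

#' Build a run's GLM design matrix
#'
#' One regressor triplet per condition present in the run -- the onset
#' stick convolved with the canonical HRF and with its temporal and
#' dispersion derivatives -- followed by the six motion parameters, a
#' cosine drift basis and an intercept. Onsets are modelled as impulses at
#' the start of the initial (horizontal) trajectory of each trial.
#'
#' @param design An [generate_design()] tibble.
#' @param run Run index to build for.
#' @param motion t x 6 motion-parameter matrix for that run.
#' @param drift_cutoff Cosine drift period cutoff (s).
#' @param n_vol Number of volumes; defaults to the design's stored run
#'   length.
#' @return A list of class `design_matrix`: `x` (t x p matrix), `columns`
#'   (labels), `conditions`, `hrf_columns` (condition -> canonical column).
#' @export
build_design_matrix <- function(design, run, motion, drift_cutoff = 128,
                                n_vol = NULL) {
  ev <- design[design$run == run, ]
  if (nrow(ev) == 0) stop("run ", run, " not present in design", call. = FALSE)
  tr <- attr(design, "tr")
  if (is.null(n_vol)) n_vol <- attr(design, "run_length_volumes")[run]
  motion <- as.matrix(motion)
  if (nrow(motion) != n_vol || ncol(motion) != 6) {
    stop("motion parameters must be ", n_vol, " x 6, got ",
         nrow(motion), " x ", ncol(motion), call. = FALSE)
  }
  basis <- hrf_basis()
  conds <- sort(unique(ev$condition))
  cond_cols <- purrr::map(conds, function(cc) {
    on <- ev$onset[ev$condition == cc]
    cbind(
      convolve_onsets(on, n_vol, tr, basis$hrf),
      convolve_onsets(on, n_vol, tr, basis$tderiv),
      convolve_onsets(on, n_vol, tr, basis$ddisp)
    )
  })
  xc <- do.call(cbind, cond_cols)
  colnames(xc) <- as.vector(t(outer(conds, c("hrf", "tderiv", "ddisp"),
                                    paste, sep = ":")))
  drift <- cosine_drift_basis(n_vol, tr, drift_cutoff)
  colnames(motion) <- paste0("motion_", 1:6)
  x <- cbind(xc, motion, drift, intercept = 1)
  structure(
    list(x = x, columns = colnames(x), conditions = conds,
         hrf_columns = stats::setNames(match(paste0(conds, ":hrf"),
                                             colnames(x)), conds),
         run = run, tr = tr),
    class = "design_matrix"
  )
}

# OLS solve with an informative error on rank deficiency
ols_fit <- function(x, y) {
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qr.coef(qr_x, y)
}

#' Fit the condition-wise GLM
#'
#' Ordinary least squares per voxel and run; the canonical-HRF coefficient
#' of each condition is kept (derivative coefficients are estimated and
#' discarded) and averaged across the runs in which the condition occurs.
#'
#' @param runs List of `bold_run` objects.
#' @param matrices List of [build_design_matrix()] outputs, one per run.
#' @return A list of class `beta_map` with `level = "condition"`: `values`
#'   is a voxel x condition matrix, `labels` the condition names.
#' @export
fit_condition_glm <- function(runs, matrices) {
  stopifnot(length(runs) == length(matrices))
  per_run <- purrr::map2(runs, matrices, function(run, dm) {
    y <- bold_matrix(run)
    if (nrow(y) != nrow(dm$x)) {
      stop("run ", run$run, ": ", nrow(y), " volumes but design matrix has ",
           nrow(dm$x), " rows", call. = FALSE)
    }
    beta <- ols_fit(dm$x, y)
    b <- t(beta[dm$hrf_columns, , drop = FALSE]) # voxels x conditions
    colnames(b) <- dm$conditions
    b
  })
  conds <- sort(unique(unlist(purrr::map(matrices, "conditions"))))
  nvox <- nrow(per_run[[1]])
  acc <- matrix(0, nvox, length(conds), dimnames = list(NULL, conds))
  cnt <- stats::setNames(numeric(length(conds)), conds)
  for (b in per_run) {
    cc <- colnames(b)
    acc[, cc] <- acc[, cc] + b
    cnt[cc] <- cnt[cc] + 1
  }
  values <- sweep(acc, 2, pmax(cnt, 1), "/")
  structure(
    list(level = "condition", values = values, labels = conds,
         runs = purrr::map_int(runs, ~ as.integer(.x$run))),
    class = "beta_map"
  )
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("<beta_map> level=%s: %d voxels x %d labels\n",
              x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Estimate single-trial betas with the least-squares-separate approach
#'
#' For every trial a dedicated GLM is fit whose regressors are (i) that
#' trial's HRF-convolved onset, (ii) one regressor pooling the onsets of
#' all other trials in the run, and (iii) motion, cosine drift and
#' intercept nuisance columns. The coefficient of (i) is the trial's beta.
#' Trials whose HRF support is truncated by more than half at the run end
#' are dropped (a message reports the count). A run with a single trial
#' falls back to the condition-style estimate with a warning.
#'
#' @param runs List of `bold_run` objects.
#' @param design The [generate_design()] tibble the runs were simulated
#'   from.
#' @param drift_cutoff Cosine drift period cutoff (s).
#' @return A list of class `beta_map` with `level = "trial"`: `values` is a
#'   voxel x trial matrix, `trials` a tibble describing the retained trials
#'   in estimation order.
#' @export
fit_lss_betas <- function(runs, design, drift_cutoff = 128) {
  tr <- attr(design, "tr")
  run_len <- attr(design, "run_length_volumes")
  basis <- hrf_basis()
  half_support <- 16 # s; drop trials with > 50% of the 32 s HRF truncated
  out <- purrr::map(runs, function(run) {
    r <- run$run
    ev <- design[design$run == r, ]
    nt <- run_len[r]
    y <- bold_matrix(run)
    keep <- ev$onset + half_support <= nt * tr
    if (any(!keep)) {
      message(sum(!keep), " trial(s) in run ", r,
              " dropped: HRF support truncated past 50%")
    }
    ev_keep <- ev[keep, ]
    drift <- cosine_drift_basis(nt, tr, drift_cutoff)
    motion <- as.matrix(run$motion_params)
    colnames(motion) <- paste0("motion_", 1:6)
    nuis <- cbind(motion, drift, intercept = 1)
    if (nrow(ev_keep) < 2) {
      warning("run ", r, " has a single usable trial; ",
              "falling back to a condition-style estimate", call. = FALSE)
      x <- cbind(trial = convolve_onsets(ev_keep$onset, nt, tr, basis$hrf),
                 nuis)
      beta <- ols_fit(x, y)["trial", ]
      vals <- matrix(beta, ncol = 1)
    } else {
      all_courses <- vapply(seq_len(nrow(ev_keep)), function(i) {
        convolve_onsets(ev_keep$onset[i], nt, tr, basis$hrf)
      }, numeric(nt))
      # Frisch-Waugh: residualize data and trial regressors against the
      # nuisance block once, then each trial's GLM collapses to an exact
      # 2 x 2 solve (trial course vs pooled others)
      qr_n <- qr(nuis)
      if (qr_n$rank < ncol(nuis)) {
        bad <- colnames(nuis)[qr_n$pivot[(qr_n$rank + 1):ncol(nuis)]]
        stop("design matrix is rank deficient; offending columns: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      yr <- qr.resid(qr_n, y)
      cr <- qr.resid(qr_n, all_courses)
      tot <- rowSums(cr)
      a_y <- crossprod(cr, yr)            # trials x voxels
      t_y <- drop(crossprod(tot, yr))     # voxels
      aa <- colSums(cr^2)
      at <- drop(crossprod(cr, tot))
      tt_ <- sum(tot^2)
      ab <- at - aa
      bb <- tt_ - 2 * at + aa
      det <- aa * bb - ab^2
      if (any(det <= 1e-10 * aa * tt_)) {
        stop("design matrix is rank deficient; offending columns: trial ",
             paste(which(det <= 1e-10 * aa * tt_), collapse = ", "),
             call. = FALSE)
      }
      b_y <- matrix(t_y, nrow(a_y), ncol(a_y), byrow = TRUE) - a_y
      vals <- t((bb * a_y - ab * b_y) / det)
    }
    list(values = vals,
         trials = tibble::tibble(run = ev_keep$run, trial = ev_keep$trial,
                                 condition = ev_keep$condition))
  })
  structure(
    list(level = "trial",
         values = do.call(cbind, purrr::map(out, "values")),
         trials = dplyr::bind_rows(purrr::map(out, "trials"))),
    class = "beta_map"
  )
}

#' Extract an ROI-restricted trial-by-voxel pattern matrix
#'
#' Restricts single-trial betas to a mask's member voxels minus its
#' reappearance-tagged voxels and attaches per-trial labels from the
#' design. Rows follow trial (estimation) order.
#'
#' @param betas A trial-level `beta_map` from [fit_lss_betas()].
#' @param mask An `roi_mask` on the same grid as the betas.
#' @param design The design the betas were estimated from.
#' @return A list of class `pattern_set`: `matrix` (trials x voxels),
#'   `voxels` (retained linear voxel indices), `meta` (per-trial tibble
#'   with condition labels and run/chunk), `region`, `phase`, `context`.
#' @export
extract_roi_patterns <- function(betas, mask, design) {
  stopifnot(inherits(betas, "beta_map"), betas$level == "trial")
  voxels <- setdiff(mask$member_voxels, mask$reappearance_voxels)
  if (length(voxels) == 0) {
    stop("mask '", mask$region,
         "' is empty after reappearance-voxel exclusion", call. = FALSE)
  }
  if (max(voxels) > nrow(betas$values)) {
    stop("mask voxel indices exceed the beta grid (", nrow(betas$values),
         " voxels)", call. = FALSE)
  }
  meta <- dplyr::left_join(
    betas$trials,
    dplyr::select(design, "run", "trial", "direction", "velocity",
                  "congruency", "phase", "context"),
    by = c("run", "trial")
  )
  structure(
    list(matrix = t(betas$values[voxels, , drop = FALSE]),
         voxels = sort(voxels), meta = meta, region = mask$region,
         phase = meta$phase[1], context = meta$context[1]),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %s (%s/%s): %d trials x %d voxels\n",
              x$region, x$context, x$phase, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write a trial-level beta map as 4D NIfTI plus a label sidecar
#'
#' @param betas A `beta_map`.
#' @param grid The [volume_grid()].
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the `nifti` and `sidecar` paths.
#' @export
write_beta_nifti <- function(betas, grid, dir, prefix = "betas") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(betas$values)
  arr <- array(betas$values, dim = c(grid$dims, n))
  path <- file.path(dir, paste0(prefix, ".nii.gz"))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(grid$voxel_size, 3), 1)
  RNifti::writeNifti(img, path)
  side <- if (betas$level == "trial") {
    dplyr::mutate(betas$trials, volume = dplyr::row_number() - 1L)
  } else {
    tibble::tibble(volume = seq_len(n) - 1L, label = betas$labels)
  }
  side_path <- file.path(dir, paste0(prefix, "_labels.tsv"))
  readr::write_tsv(side, side_path)
  invisible(list(nifti = path, sidecar = side_path))
}
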