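#' Assemble a pipeline configuration
#'
#' Bundles every knob of the simulate -> GLM -> searchlight -> inference ->
#' report chain. Defaults give the desk-scale demo: 4 subjects on a
#' 12 x 12 x 12 grid, 60 trials per phase (2 runs of 15 trials per
#' direction x velocity cell), 99 permutation iterations, and two
#' LP-context direction analyses (within the visible phase, and training
#' visible / testing occluded).
#'
#' @param seed Top-level integer seed (mandatory; every random draw in the
#'   pipeline descends from it).
#' @param out_dir Output directory.
#' @param n_subjects Number of simulated subjects.
#' @param dims Grid dimensions.
#' @param n_voxels Voxels per ROI blob.
#' @param reappearance_fraction Fraction of V1 voxels tagged
#'   reappearance-responsive (excluded from patterns).
#' @param n_runs,trials_per_run_cell Design size per session (see
#'   [generate_design()]).
#' @param amplitude,rho,history_increment Planted effects (see
#'   [effect_spec()]).
#' @param ar,noise_sd,drift_amplitude Noise model (see [noise_spec()]).
#' @param radius_mm Searchlight radius.
#' @param drift_cutoff GLM cosine drift cutoff (s).
#' @param n_iter Permutation iterations per subject.
#' @param top_fraction,cutoff Informative-sphere selection parameters.
#' @param analyses List of analysis descriptors; each is a list with `id`,
#'   `factor` (`"direction"`, `"velocity"` or `"congruency"`), `context`,
#'   `region`, `train_phase` and optional `test_phase` (cross-phase when
#'   given).
#' @param history_region Region whose mean betas feed the trial-history
#'   contrasts (LP visible session).
#' @param write_volumes Write 4D NIfTI intermediates (events and report
#'   TSVs are always written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir, n_subjects = 4,
                            dims = c(12, 12, 12), n_voxels = 160,
                            reappearance_fraction = 0.1, n_runs = 2,
                            trials_per_run_cell = 15, amplitude = 1,
                            rho = 0.7, history_increment = 0,
                            ar = 0.3, noise_sd = 1, drift_amplitude = 0.5,
                            radius_mm = 4.4, drift_cutoff = 128,
                            n_iter = 99, top_fraction = 0.05, cutoff = 0.5,
                            analyses = NULL, history_region = "lowerV1",
                            write_volumes = FALSE) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(analyses)) {
    analyses <- list(
      list(id = "direction_LP_visible", factor = "direction",
           context = "LP", region = "lowerV1",
           train_phase = "visible", test_phase = NULL),
      list(id = "direction_LP_crossphase", factor = "direction",
           context = "LP", region = "lowerV1",
           train_phase = "visible", test_phase = "occluded")
    )
  }
  for (a in analyses) {
    stopifnot(a$factor %in% c("direction", "velocity", "congruency"),
              a$context %in% c("HP", "LP"),
              a$train_phase %in% c("visible", "occluded"))
    if (a$factor == "congruency" && a$context == "HP") {
      stop("analysis '", a$id,
           "': congruency cannot be decoded in the HP context",
           call. = FALSE)
    }
  }
  structure(
    list(seed = seed, out_dir = out_dir, n_subjects = n_subjects,
         dims = dims, n_voxels = n_voxels,
         reappearance_fraction = reappearance_fraction, n_runs = n_runs,
         trials_per_run_cell = trials_per_run_cell, amplitude = amplitude,
         rho = rho, history_increment = history_increment, ar = ar,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         radius_mm = radius_mm, drift_cutoff = drift_cutoff,
         n_iter = n_iter, top_fraction = top_fraction, cutoff = cutoff,
         analyses = analyses, history_region = history_region,
         write_volumes = write_volumes),
    class = "pipeline_config"
  )
}

config_hash <- function(config, fields) {
  rlang::hash(config[sort(intersect(fields, names(config)))])
}

# cache an expensive stage result under out_dir/cache, keyed by the
# configuration fields it depends on; stale keys simply never match
stage_cached <- function(config, stage, fields, expr) {
  dir <- file.path(config$out_dir, "cache")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  key <- config_hash(config, fields)
  path <- file.path(dir, paste0(stage, "_", key, ".rds"))
  if (file.exists(path)) {
    message("[", stage, "] reusing cache ", basename(path))
    return(readRDS(path))
  }
  message("[", stage, "] computing")
  value <- force(expr)
  saveRDS(value, path)
  value
}

analysis_labels <- function(meta, factor) as.character(meta[[factor]])

FIELDS_MASKS <- c("seed", "dims", "n_voxels", "reappearance_fraction")
FIELDS_DATA <- c(FIELDS_MASKS, "n_subjects", "n_runs",
                 "trials_per_run_cell", "amplitude", "rho",
                 "history_increment", "ar", "noise_sd", "drift_amplitude",
                 "analyses", "history_region")
FIELDS_BETAS <- c(FIELDS_DATA, "drift_cutoff")
FIELDS_MAPS <- c(FIELDS_BETAS, "radius_mm")
FIELDS_INFER <- c(FIELDS_MAPS, "n_iter", "top_fraction", "cutoff")

#' Run the full simulation-to-report pipeline
#'
#' Simulates every subject's sessions, estimates single-trial betas,
#' runs each configured searchlight analysis, selects informative spheres,
#' builds subject permutation nulls, computes group permutation p-values,
#' runs the trial-history contrasts on the LP visible session, and writes
#' events TSVs, accuracy-map TSVs (plus NIfTI if requested), a group
#' report TSV and a trial-history TSV under `config$out_dir`. Stages are
#' cached under `out_dir/cache`, keyed by the configuration fields they
#' depend on; reruns with an identical configuration reuse cached stages
#' bit-exactly, and deleting a late stage's cache never forces early
#' stages to recompute.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse cached stage outputs (default); `FALSE` clears the
#'   cache first.
#' @return A list of class `pipeline_result`: `report` (group tibble),
#'   `inference` (per-analysis `perm_null`), `history`
#'   (`history_summary`), `selected` (per analysis x subject),
#'   `paths`, `config`.
#' @export
run_full_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!resume) unlink(file.path(config$out_dir, "cache"), recursive = TRUE)
  message("pipeline seed ", config$seed, ", config hash ",
          config_hash(config, names(config)[names(config) != "out_dir"]))

  sessions <- unique(purrr::map_dfr(config$analyses, function(a) {
    tibble::tibble(context = a$context,
                   phase = c(a$train_phase, a$test_phase %||% character(0)))
  }))
  sessions <- unique(dplyr::bind_rows(
    sessions, tibble::tibble(context = "LP", phase = "visible")
  ))

  gm <- stage_cached(config, "masks", FIELDS_MASKS, {
    generate_grid_and_masks(
      dims = config$dims, seed = config$seed, n_voxels = config$n_voxels,
      reappearance_fraction = config$reappearance_fraction
    )
  })

  subjects <- seq_len(config$n_subjects)
  patterns <- stage_cached(config, "patterns", FIELDS_BETAS, {
    purrr::map(subjects, function(s) {
      subj_seed <- substream_seed(config$seed, paste0("subject", s))
      effects <- effect_spec(gm$masks, amplitude = config$amplitude,
                             rho = config$rho,
                             history_increment = config$history_increment,
                             seed = subj_seed)
      noise <- noise_spec(ar = config$ar, sd = config$noise_sd,
                          drift_amplitude = config$drift_amplitude)
      sess <- purrr::pmap(sessions, function(context, phase) {
        design <- generate_design(
          context, phase, seed = substream_seed(subj_seed, phase),
          n_runs = config$n_runs,
          trials_per_run_cell = config$trials_per_run_cell
        )
        runs <- simulate_bold(design, gm$grid, gm$masks, effects, noise,
                              seed = substream_seed(subj_seed, phase))
        sub_dir <- file.path(config$out_dir, sprintf("sub-%02d", s),
                             paste0(context, "_", phase))
        write_events_tsv(design, sub_dir)
        if (config$write_volumes) {
          purrr::walk(runs, write_bold_nifti, grid = gm$grid,
                      dir = sub_dir)
        }
        betas <- suppressMessages(
          fit_lss_betas(runs, design, drift_cutoff = config$drift_cutoff)
        )
        pats <- purrr::map(gm$masks, extract_roi_patterns, betas = betas,
                           design = design)
        list(context = context, phase = phase, patterns = pats)
      })
      names(sess) <- paste0(sessions$context, "_", sessions$phase)
      sess
    })
  })

  region_voxels <- purrr::map(gm$masks, ~ setdiff(.x$member_voxels,
                                                  .x$reappearance_voxels))
  spheres <- purrr::map(region_voxels, build_searchlights, grid = gm$grid,
                        radius_mm = config$radius_mm)

  infer <- stage_cached(config, "inference", FIELDS_INFER, {
    purrr::map(config$analyses, function(a) {
      per_subj <- purrr::map(subjects, function(s) {
        subj_seed <- substream_seed(config$seed, paste0("subject", s))
        ses_train <- patterns[[s]][[paste0(a$context, "_", a$train_phase)]]
        train_ps <- ses_train$patterns[[a$region]]
        train_lab <- analysis_labels(train_ps$meta, a$factor)
        sph <- spheres[[a$region]]
        if (is.null(a$test_phase)) {
          scheme <- make_partitions(
            train_lab, train_ps$meta$run,
            seed = substream_seed(subj_seed, paste0("scheme/", a$id))
          )
          map <- searchlight_accuracy_map(train_ps, sph, scheme,
                                          labels = train_lab,
                                          analysis_id = a$id)
          test_ps <- NULL; test_lab <- NULL
        } else {
          ses_test <- patterns[[s]][[paste0(a$context, "_", a$test_phase)]]
          test_ps <- ses_test$patterns[[a$region]]
          test_lab <- analysis_labels(test_ps$meta, a$factor)
          map <- cross_phase_decode(
            train_ps, test_ps, sph, train_lab, test_lab,
            seed = substream_seed(subj_seed, paste0("scheme/", a$id)),
            analysis_id = a$id
          )
        }
        map_dir <- file.path(config$out_dir, sprintf("sub-%02d", s), "maps")
        write_accuracy_map(map, map_dir)
        sel <- select_informative_spheres(
          map, cutoff = config$cutoff, top_fraction = config$top_fraction,
          subject_id = sprintf("sub-%02d", s)
        )
        null <- if (sel$empty) rep(NA_real_, config$n_iter) else {
          subject_permutation_null(
            train_ps, sph, sel, train_lab, n_iter = config$n_iter,
            seed = substream_seed(subj_seed, paste0("perm/", a$id)),
            test_patterns = test_ps, test_labels = test_lab
          )
        }
        list(map = map, selected = sel, null = null)
      })
      ok <- !purrr::map_lgl(per_subj, ~ .x$selected$empty)
      null_mat <- do.call(rbind, purrr::map(per_subj[ok], "null"))
      pn <- group_level_p(
        purrr::map_dbl(per_subj[ok], ~ .x$selected$mean_accuracy),
        null_mat, analysis_id = a$id
      )
      list(analysis = a, per_subject = per_subj, group = pn)
    })
  })

  report <- purrr::map_dfr(infer, function(res) {
    sel <- purrr::map(res$per_subject, "selected")
    n_sel <- purrr::map_int(sel, "n_selected")
    tibble::tibble(
      analysis_id = res$analysis$id,
      true_accuracy = res$group$true_value,
      accuracy_se = stats::sd(purrr::map_dbl(sel, "mean_accuracy"),
                              na.rm = TRUE) / sqrt(res$group$n_subjects),
      p_permutation = res$group$p_value,
      p_conservative = res$group$p_conservative,
      n_spheres_mean = mean(n_sel), n_spheres_sd = stats::sd(n_sel),
      n_subjects = res$group$n_subjects, n_iter = res$group$n_iter
    )
  })
  readr::write_tsv(report, file.path(config$out_dir, "group_report.tsv"))

  history_data <- purrr::map_dfr(subjects, function(s) {
    ps <- patterns[[s]][["LP_visible"]]$patterns[[config$history_region]]
    subj_seed <- substream_seed(config$seed, paste0("subject", s))
    design <- generate_design(
      "LP", "visible", seed = substream_seed(subj_seed, "visible"),
      n_runs = config$n_runs,
      trials_per_run_cell = config$trials_per_run_cell
    )
    hl <- label_trial_sequences(design)
    dplyr::mutate(
      dplyr::left_join(roi_trial_means(ps), hl, by = c("run", "trial"),
                       suffix = c("", ".design")),
      subject = sprintf("sub-%02d", s)
    )
  })
  history <- tryCatch(
    history_contrasts(history_data),
    error = function(e) {
      warning("trial-history contrasts unavailable: ",
              conditionMessage(e), call. = FALSE)
      NULL
    }
  )
  history_tsv <- if (is.null(history)) {
    tibble::tibble(contrast = NA_character_, mean_diff = NA_real_,
                   t = NA_real_, p_raw = NA_real_, p_bonf = NA_real_,
                   F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                   p_anova = NA_real_)
  } else {
    dplyr::mutate(history$contrasts,
                  F = history$anova$F, df1 = history$anova$df1,
                  df2 = history$anova$df2,
                  p_anova = history$anova$p_value)
  }
  readr::write_tsv(history_tsv,
                   file.path(config$out_dir, "history_report.tsv"))

  structure(
    list(report = report, inference = infer, history = history,
         selected = purrr::map(infer,
                               ~ purrr::map(.x$per_subject, "selected")),
         paths = list(
           report = file.path(config$out_dir, "group_report.tsv"),
           history = file.path(config$out_dir, "history_report.tsv")
         ),
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
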