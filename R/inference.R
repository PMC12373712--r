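#' Select the top-5% informative searchlight spheres
#'
#' Applies the chance-level cutoff first -- spheres with accuracy at or
#' below `cutoff` are discarded -- then keeps the highest `top_fraction`
#' of the surviving distribution (round-half-up, floor of one sphere).
#' Ties at the selection boundary are broken by ascending center index.
#' If nothing survives the cutoff an explicitly flagged empty selection is
#' returned rather than a silent zero.
#'
#' @param map An `accuracy_map`.
#' @param cutoff Chance-level accuracy cutoff (default 0.5).
#' @param top_fraction Fraction of surviving spheres retained (default
#'   0.05).
#' @param subject_id Optional subject tag carried into reports.
#' @return A list of class `top_sphere_set`: `selected_centers`,
#'   `selected_accuracies`, `mean_accuracy` (`NA` when empty),
#'   `n_selected`, `n_surviving`, `n_spheres`, `empty`, `analysis_id`,
#'   `subject_id`, `grid`.
#' @export
select_informative_spheres <- function(map, cutoff = 0.5,
                                       top_fraction = 0.05,
                                       subject_id = NA_character_) {
  stopifnot(nrow(map) > 0)
  surv <- map[map$accuracy > cutoff, ]
  if (nrow(surv) == 0) {
    out <- list(selected_centers = integer(0),
                selected_accuracies = numeric(0),
                mean_accuracy = NA_real_, n_selected = 0L,
                n_surviving = 0L, n_spheres = nrow(map), empty = TRUE,
                cutoff = cutoff, top_fraction = top_fraction,
                analysis_id = attr(map, "analysis_id"),
                subject_id = subject_id, grid = attr(map, "grid"))
    return(structure(out, class = "top_sphere_set"))
  }
  n_sel <- max(1L, as.integer(floor(top_fraction * nrow(surv) + 0.5)))
  ord <- order(-surv$accuracy, surv$center)
  sel <- surv[ord[seq_len(n_sel)], ]
  structure(
    list(selected_centers = as.integer(sel$center),
         selected_accuracies = sel$accuracy,
         mean_accuracy = mean(sel$accuracy), n_selected = n_sel,
         n_surviving = nrow(surv), n_spheres = nrow(map), empty = FALSE,
         cutoff = cutoff, top_fraction = top_fraction,
         analysis_id = attr(map, "analysis_id"), subject_id = subject_id,
         grid = attr(map, "grid")),
    class = "top_sphere_set"
  )
}

#' @export
print.top_sphere_set <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<top_sphere_set> %s: no informative spheres (0/%d above cutoff)\n",
                x$analysis_id, x$n_spheres))
  } else {
    cat(sprintf(
      "<top_sphere_set> %s: %d/%d spheres (of %d surviving), mean accuracy %.3f\n",
      x$analysis_id, x$n_selected, x$n_spheres, x$n_surviving,
      x$mean_accuracy))
  }
  invisible(x)
}

# lean split generator for the permutation loop: same partition law as
# make_partitions (class-stratified folds, majority subsampled to the
# minority within each training split) but drawn from the caller's
# current RNG stream with no per-fold sub-stream bookkeeping
perm_iteration_splits <- function(labels, n_folds = 4L, n_repeats = 4L) {
  by_class <- split(seq_along(labels), labels)
  train <- vector("list", n_folds * n_repeats)
  test <- vector("list", n_folds * n_repeats)
  k <- 0L
  for (rep_i in seq_len(n_repeats)) {
    f <- integer(length(labels))
    for (idx in by_class) {
      f[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
    for (fd in seq_len(n_folds)) {
      te <- which(f == fd)
      tr <- which(f != fd)
      cls <- lapply(by_class, function(idx) intersect(tr, idx))
      m <- min(lengths(cls))
      bal <- unlist(lapply(cls, function(pool) {
        if (length(pool) > m) sample(pool, m) else pool
      }), use.names = FALSE)
      k <- k + 1L
      train[[k]] <- sort(bal)
      test[[k]] <- te
    }
  }
  list(train = train, test = test)
}

# shuffle labels independently within each run, preserving per-run counts
shuffle_within_run <- function(labels, chunks) {
  out <- labels
  for (r in unique(chunks)) {
    idx <- which(chunks == r)
    out[idx] <- labels[idx][sample(length(idx))]
  }
  out
}

#' Mean accuracy over fixed sphere centers
#'
#' Recomputes the searchlight analysis restricted to the given centers
#' under a label assignment and a partition-scheme seed, and returns the
#' mean accuracy over those centers. This is the statistic sampled by the
#' permutation null: the centers stay fixed at the true-label selection
#' while the labels change.
#'
#' @param patterns A `pattern_set`.
#' @param spheres The full sphere set the centers come from.
#' @param centers Sphere centers (linear voxel indices) to evaluate.
#' @param labels Per-trial labels to decode.
#' @param scheme_seed Seed for the [make_partitions()] scheme.
#' @param test_patterns,test_labels For cross-phase analyses: the test-side
#'   pattern set and labels (balancing redraws then replace the fold
#'   scheme, seeded by `scheme_seed`).
#' @return Mean accuracy over `centers`.
#' @export
sphere_mean_accuracy <- function(patterns, spheres, centers, labels,
                                 scheme_seed, test_patterns = NULL,
                                 test_labels = NULL) {
  sub <- subset_spheres(spheres, centers)
  mean_acc_at_spheres(patterns, sub, labels, scheme_seed,
                      test_patterns, test_labels)
}

subset_spheres <- function(spheres, centers) {
  keep <- purrr::map_int(spheres, ~ as.integer(.x$center)) %in% centers
  structure(spheres[keep], class = "searchlight_set",
            radius_mm = attr(spheres, "radius_mm"),
            grid = attr(spheres, "grid"))
}

mean_acc_at_spheres <- function(patterns, sub, labels, scheme_seed,
                                test_patterns = NULL, test_labels = NULL) {
  map <- if (is.null(test_patterns)) {
    scheme <- make_partitions(labels, patterns$meta$run, seed = scheme_seed)
    searchlight_accuracy_map(patterns, sub, scheme, labels = labels)
  } else {
    cross_phase_decode(patterns, test_patterns, sub,
                       train_labels = labels, test_labels = test_labels,
                       seed = scheme_seed)
  }
  mean(map$accuracy)
}

#' Subject-level label-permutation null
#'
#' For each iteration, class labels are shuffled independently within each
#' run (the data themselves are untouched), the partitioning is redrawn
#' from an iteration-derived seed, and the full searchlight analysis is
#' recomputed. By default (`reselect = TRUE`) the iteration's null value
#' is the mean accuracy over the top spheres *reselected on the permuted
#' map* with the same cutoff and top fraction as the true-label selection.
#' Reselection keeps the null distribution subject to the same selection
#' inflation as the true statistic, which is what makes the group test
#' calibrated; sampling the permuted maps at the fixed true-label centers
#' (`reselect = FALSE`) is retained for comparison but is strongly
#' anti-conservative, since only the true statistic then benefits from
#' selection (see the package vignette).
#'
#' @param patterns A `pattern_set`.
#' @param spheres Full sphere set of the analysis.
#' @param selected A [select_informative_spheres()] result (non-empty);
#'   supplies the cutoff, top fraction and -- for `reselect = FALSE` --
#'   the fixed centers.
#' @param labels True per-trial labels of the analysis.
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param reselect Recompute the top-sphere selection on every permuted
#'   map (default) instead of sampling the fixed true-label centers.
#' @param test_patterns,test_labels Cross-phase test side, if any; labels
#'   are then shuffled within run on both sides and the balancing redraws
#'   are regenerated per iteration.
#' @return Numeric vector of `n_iter` null mean accuracies. A permuted
#'   map with no sphere above the cutoff contributes the cutoff value.
#' @export
subject_permutation_null <- function(patterns, spheres, selected, labels,
                                     n_iter = 1000L, seed = 1L,
                                     reselect = TRUE,
                                     test_patterns = NULL,
                                     test_labels = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (selected$empty) {
    stop("cannot build a null for an empty sphere selection", call. = FALSE)
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  cross <- !is.null(test_patterns)
  if (cross) test_labels <- as.character(test_labels)

  iter_train <- vector("list", n_iter)
  iter_test <- vector("list", n_iter)
  ytr <- matrix(0L, length(labels), n_iter)
  yte <- matrix(0L, if (cross) length(test_labels) else length(labels),
                n_iter)
  for (j in seq_len(n_iter)) {
    with_substream(seed, paste0("perm/iter", j), {
      perm <- shuffle_within_run(labels, patterns$meta$run)
      ytr[, j] <- as.integer(perm == classes[2])
      if (!cross) {
        sp <- perm_iteration_splits(perm)
        iter_train[[j]] <- sp$train
        iter_test[[j]] <- sp$test
        yte[, j] <- ytr[, j]
      } else {
        perm_test <- shuffle_within_run(test_labels,
                                        test_patterns$meta$run)
        yte[, j] <- as.integer(perm_test == classes[2])
        iter_train[[j]] <- lapply(1:4, function(k) {
          balance_indices(seq_along(perm), perm)
        })
        iter_test[[j]] <- lapply(1:4, function(k) {
          balance_indices(seq_along(perm_test), perm_test)
        })
      }
    })
  }
  centers_idx <- match(selected$selected_centers,
                       purrr::map_int(spheres, ~ as.integer(.x$center)))
  as.numeric(cpp_perm_null(
    patterns$matrix,
    if (cross) test_patterns$matrix else patterns$matrix,
    purrr::map(spheres, "cols"), iter_train, iter_test, ytr, yte,
    cutoff = selected$cutoff %||% 0.5,
    top_fraction = selected$top_fraction %||% 0.05,
    reselect = reselect, centers_idx = as.integer(centers_idx)
  ))
}

#' Group-level permutation p-value
#'
#' Builds the group null by averaging, per iteration, the subject-level
#' null means across subjects; together with the true-label group average
#' this gives `n_iter + 1` group-level accuracies. The p-value is the
#' number of permuted group means at or above the true one divided by
#' `n_iter + 1` -- which can be exactly 0; the conservative variant
#' `(b + 1) / (n_iter + 1)` is reported alongside without replacing it.
#'
#' @param true_means Per-subject true mean accuracies (over their selected
#'   spheres).
#' @param null_means Subjects x `n_iter` matrix of subject null means.
#' @param analysis_id Identifier carried into reports.
#' @return A list of class `perm_null`: `true_value`, `permuted_values`,
#'   `p_value`, `p_conservative`, `n_iter`, `n_subjects`.
#' @export
group_level_p <- function(true_means, null_means,
                          analysis_id = "analysis") {
  null_means <- as.matrix(null_means)
  if (length(true_means) == 0) stop("no subjects", call. = FALSE)
  if (nrow(null_means) != length(true_means)) {
    stop("null_means must have one row per subject", call. = FALSE)
  }
  group_null <- colMeans(null_means)
  true_value <- mean(true_means)
  b <- sum(group_null >= true_value)
  n_iter <- length(group_null)
  structure(
    list(true_value = true_value, permuted_values = group_null,
         p_value = b / (n_iter + 1),
         p_conservative = (b + 1) / (n_iter + 1),
         n_iter = n_iter, n_subjects = length(true_means),
         analysis_id = analysis_id),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> %s: true accuracy %.3f, p = %.4g (conservative %.4g), %d subjects, %d iterations\n",
    x$analysis_id, x$true_value, x$p_value, x$p_conservative,
    x$n_subjects, x$n_iter))
  invisible(x)
}

#' Sphere-center overlap across analyses
#'
#' Counts, for one subject, how many selected sphere centers are shared
#' between every pair of analyses (and by all analyses at once). Under
#' random selection the expected pairwise overlap is hypergeometric:
#' `k1 * k2 / N` for selections of size `k1`, `k2` from `N` spheres.
#'
#' @param sets List (length >= 2) of `top_sphere_set`s on the same grid.
#' @return A list of class `sphere_overlap`: `pairs` tibble (analysis ids,
#'   overlap, expected random overlap), `all_way` count, `mean_pairwise`.
#' @export
sphere_center_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sphere sets", call. = FALSE)
  dims <- purrr::map(sets, ~ .x$grid$dims)
  if (!all(purrr::map_lgl(dims, identical, dims[[1]]))) {
    stop("sphere sets live on different grids", call. = FALSE)
  }
  ids <- purrr::map_chr(sets, ~ .x$analysis_id %||% "analysis")
  combs <- utils::combn(length(sets), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    n_pop <- max(sets[[i]]$n_spheres, sets[[j]]$n_spheres)
    tibble::tibble(
      analysis_a = ids[i], analysis_b = ids[j],
      overlap = length(intersect(sets[[i]]$selected_centers,
                                 sets[[j]]$selected_centers)),
      expected_random = sets[[i]]$n_selected * sets[[j]]$n_selected / n_pop
    )
  })
  structure(
    list(pairs = pairs,
         all_way = length(purrr::reduce(purrr::map(sets, "selected_centers"),
                                        intersect)),
         mean_pairwise = mean(pairs$overlap)),
    class = "sphere_overlap"
  )
}

#' @export
print.sphere_overlap <- function(x, ...) {
  cat(sprintf("<sphere_overlap> mean pairwise overlap %.2f, all-way %d\n",
              x$mean_pairwise, x$all_way))
  print(x$pairs)
  invisible(x)
}

#' Paired t-test on per-subject decoding accuracies
#'
#' Plain paired t utility for comparing two analyses' per-subject mean
#' accuracies (e.g. HP vs LP). Accuracies entering it were selected as the
#' top 5% of spheres, so their absolute level is selection-inflated; the
#' comparison between conditions shares that inflation.
#'
#' @param acc_a,acc_b Per-subject accuracy vectors, same subject order.
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`.
#' @export
paired_accuracy_test <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
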