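#' Label trials by their congruency-transition history
#'
#' Each trial (except the first of a run) is labeled with the pair formed
#' by its predecessor's and its own congruency category: CC, CI, IC or II,
#' first letter = previous trial, second letter = current trial (so CI is
#' an incongruent trial that followed a congruent one). Run boundaries are
#' never bridged: the first trial of every run carries `NA`.
#'
#' Note: the field literature is not unanimous on whether the first letter
#' names the previous or the current trial; this package follows the
#' pair-order reading (previous, current) throughout.
#'
#' @param design An [generate_design()] tibble.
#' @return A tibble with `run`, `trial`, `congruency`, `history` (`NA` for
#'   first-in-run trials).
#' @export
#' @examples
#' d <- generate_design("LP", "visible", seed = 1)
#' table(label_trial_sequences(d)$history)
label_trial_sequences <- function(design) {
  if (all(design$congruency == "congruent")) {
    warning("design contains no incongruent trials; ",
            "all history labels are CC", call. = FALSE)
  }
  code <- c(congruent = "C", incongruent = "I")
  out <- dplyr::group_by(design, .data$run)
  out <- dplyr::mutate(
    out,
    history = dplyr::if_else(
      dplyr::row_number() == 1, NA_character_,
      paste0(code[dplyr::lag(.data$congruency)], code[.data$congruency])
    )
  )
  out <- dplyr::ungroup(out)
  dplyr::select(out, "run", "trial", "congruency", "history")
}

#' Mean ROI beta per trial
#'
#' Averages a pattern set's betas over its voxels, yielding one value per
#' trial -- the univariate quantity entering the trial-history analysis.
#'
#' @param patterns A `pattern_set`.
#' @return The pattern set's `meta` tibble with a `beta` column appended.
#' @export
roi_trial_means <- function(patterns) {
  dplyr::mutate(patterns$meta, beta = rowMeans(patterns$matrix))
}

#' Trial-history repeated-measures contrasts
#'
#' Aggregates per-trial ROI betas into subject x history-category cell
#' means, runs a one-way repeated-measures ANOVA over the four categories
#' (F on (3, 3(n-1)) degrees of freedom), and computes the six pairwise
#' paired-t contrasts with Bonferroni correction. Subjects missing a
#' category are excluded with a warning. No sphericity correction is
#' applied.
#'
#' @param data A tibble with columns `subject`, `history` (CC/CI/IC/II;
#'   `NA` rows are dropped) and `beta` (one row per trial, or already
#'   aggregated).
#' @return A list of class `history_summary`: `cell_means` (subject x
#'   category tibble), `anova` (one-row tibble with `F`, `df1`, `df2`,
#'   `p_value`), `contrasts` (6-row tibble with `mean_diff`, `t`,
#'   `p_raw`, `p_bonf`), `n_subjects`.
#' @export
history_contrasts <- function(data) {
  stopifnot(all(c("subject", "history", "beta") %in% names(data)))
  data <- dplyr::filter(data, !is.na(.data$history))
  cats <- c("CC", "CI", "IC", "II")
  cells <- dplyr::summarise(
    dplyr::group_by(data, .data$subject, .data$history),
    beta = mean(.data$beta), .groups = "drop"
  )
  complete <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(cells, .data$subject),
                     n_cat = dplyr::n_distinct(.data$history),
                     .groups = "drop"),
    .data$n_cat == length(cats)
  )$subject
  dropped <- setdiff(unique(cells$subject), complete)
  if (length(dropped) > 0) {
    warning("excluding ", length(dropped),
            " subject(s) missing a history category: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  cells <- dplyr::filter(cells, .data$subject %in% complete)
  n <- length(complete)
  if (n < 2) stop("need at least 2 complete subjects", call. = FALSE)

  cells$subject <- factor(cells$subject)
  cells$history <- factor(cells$history, levels = cats)
  fit <- stats::aov(beta ~ history + Error(subject), data = cells)
  tab <- summary(fit)[["Error: Within"]][[1]]
  anova_row <- tibble::tibble(
    F = tab["history", "F value"],
    df1 = tab["history", "Df"], df2 = tab["Residuals", "Df"],
    p_value = tab["history", "Pr(>F)"]
  )

  wide <- tidyr::pivot_wider(cells, names_from = "history",
                             values_from = "beta")
  pair_idx <- utils::combn(cats, 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(k) {
    a <- pair_idx[1, k]; b <- pair_idx[2, k]
    tt <- stats::t.test(wide[[a]], wide[[b]], paired = TRUE)
    tibble::tibble(contrast = paste(a, "vs", b),
                   mean_diff = unname(tt$estimate),
                   t = unname(tt$statistic), p_raw = tt$p.value)
  })
  contrasts$p_bonf <- stats::p.adjust(contrasts$p_raw, method = "bonferroni")
  structure(
    list(cell_means = cells, anova = anova_row, contrasts = contrasts,
         n_subjects = n),
    class = "history_summary"
  )
}

#' @export
print.history_summary <- function(x, ...) {
  cat(sprintf(
    "<history_summary> %d subjects; congruence F(%d, %d) = %.3f, p = %.4g\n",
    x$n_subjects, x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  print(x$contrasts)
  invisible(x)
}
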