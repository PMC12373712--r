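#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.accuracy_map <- function(x, ...) {
  tibble::tibble(center = x$center, accuracy = x$accuracy,
                 analysis_id = attr(x, "analysis_id"))
}

#' @exportS3Method generics::glance
glance.accuracy_map <- function(x, ...) {
  tibble::tibble(
    analysis_id = attr(x, "analysis_id"), n_spheres = nrow(x),
    mean_accuracy = mean(x$accuracy), max_accuracy = max(x$accuracy),
    prop_above_chance = mean(x$accuracy > 0.5)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_map <- function(object, cutoff = 0.5, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "sphere decoding accuracy", y = "spheres",
                  title = attr(object, "analysis_id")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.top_sphere_set <- function(x, ...) {
  tibble::tibble(center = x$selected_centers,
                 accuracy = x$selected_accuracies,
                 analysis_id = x$analysis_id, subject_id = x$subject_id)
}

#' @exportS3Method generics::glance
glance.top_sphere_set <- function(x, ...) {
  tibble::tibble(
    analysis_id = x$analysis_id, subject_id = x$subject_id,
    n_selected = x$n_selected, n_surviving = x$n_surviving,
    n_spheres = x$n_spheres, mean_accuracy = x$mean_accuracy,
    empty = x$empty
  )
}

#' @exportS3Method generics::tidy
tidy.perm_null <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$permuted_values),
                 group_mean = x$permuted_values)
}

#' @exportS3Method generics::glance
glance.perm_null <- function(x, ...) {
  tibble::tibble(
    analysis_id = x$analysis_id, true_value = x$true_value,
    p_value = x$p_value, p_conservative = x$p_conservative,
    n_iter = x$n_iter, n_subjects = x$n_subjects
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$group_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$true_value,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "group-mean accuracy under label permutation", y = "iterations",
      title = object$analysis_id,
      subtitle = sprintf("true = %.3f, p = %.4g", object$true_value,
                         object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.history_summary <- function(x, ...) {
  x$contrasts
}

#' @exportS3Method generics::glance
glance.history_summary <- function(x, ...) {
  dplyr::mutate(x$anova, n_subjects = x$n_subjects)
}

#' @exportS3Method ggplot2::autoplot
autoplot.history_summary <- function(object, ...) {
  ggplot2::ggplot(object$cell_means,
                  ggplot2::aes(x = .data$history, y = .data$beta)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       colour = "grey70") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "firebrick") +
    ggplot2::labs(x = "trial-history category (previous, current)",
                  y = "mean ROI beta") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of an accuracy map
#'
#' @param map An `accuracy_map`.
#' @param z 0-based slice index (defaults to the slice holding most
#'   centers).
#' @return A ggplot object.
#' @export
plot_accuracy_slice <- function(map, z = NULL) {
  grid <- attr(map, "grid")
  ijk <- voxel_ijk(grid, map$center)
  if (is.null(z)) z <- as.integer(names(which.max(table(ijk[, "k"]))))
  d <- tibble::tibble(x = ijk[, "i"], y = ijk[, "j"], k = ijk[, "k"],
                      accuracy = map$accuracy)
  d <- d[d$k == z, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (z = %d)", attr(map, "analysis_id"), z),
                  x = "x voxel", y = "y voxel") +
    ggplot2::theme_minimal()
}
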