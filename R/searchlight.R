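#' Build searchlight spheres over a retained voxel set
#'
#' One sphere per retained voxel: every retained voxel acts as a center,
#' and membership is decided by Euclidean distance between voxel centers
#' (mm) within `radius_mm`, intersected with the retained set. With the
#' default 4.4 mm radius on a 2.2 mm grid an interior sphere holds 33
#' voxels.
#'
#' @param pattern_voxels Retained (1-based linear) voxel indices, e.g.
#'   `pattern_set$voxels`.
#' @param grid The [volume_grid()].
#' @param radius_mm Sphere radius in mm.
#' @return A list of class `searchlight_set`; each element has `center`
#'   (linear voxel index), `members` (linear indices) and `cols` (positions
#'   of the members within `pattern_voxels`, i.e. pattern-matrix columns).
#' @export
build_searchlights <- function(pattern_voxels, grid, radius_mm = 4.4) {
  stopifnot(length(pattern_voxels) > 0, radius_mm > 0)
  xyz <- voxel_coords_mm(grid, pattern_voxels)
  r2 <- radius_mm^2
  out <- purrr::map(seq_along(pattern_voxels), function(i) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    keep <- which(d2 <= r2 + 1e-9)
    list(center = pattern_voxels[i], members = pattern_voxels[keep],
         cols = keep)
  })
  structure(out, class = "searchlight_set",
            radius_mm = radius_mm, grid = grid)
}

#' Balanced leave-25%-trials-out partition scheme
#'
#' Assigns trials to 4 folds stratified by class, so each test fold holds
#' 25% of the trials; the training three-quarters is balanced by randomly
#' subsampling the majority class down to the minority count. The whole
#' assignment is repeated four times with fresh fold draws and balancing
#' subsamples, giving 16 train/test splits.
#'
#' @param labels Per-trial class labels (two or more classes, at least 8
#'   trials each; fewer than 4 in any class is an error).
#' @param chunks Per-trial run indices (recorded for permutation use;
#'   folds stratify by class, not run).
#' @param seed Integer seed; the scheme is deterministic given it.
#' @param n_folds,n_repeats Partition shape (defaults 4 and 4).
#' @return A list of class `partition_scheme` with `splits` (a list of
#'   `train`/`test` index pairs), `fold` (trials x repeats fold matrix),
#'   `labels`, `chunks`.
#' @export
make_partitions <- function(labels, chunks, seed, n_folds = 4L,
                            n_repeats = 4L) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(chunks))
  counts <- table(labels)
  if (length(counts) < 2) {
    stop("need at least 2 classes, got ", length(counts), call. = FALSE)
  }
  if (min(counts) < n_folds) {
    stop("class '", names(counts)[which.min(counts)], "' has ",
         min(counts), " trials; cannot stratify into ", n_folds, " folds",
         call. = FALSE)
  }
  n <- length(labels)
  fold <- matrix(0L, n, n_repeats)
  splits <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold[, rep_i] <- with_substream(seed, paste0("partition/rep", rep_i), {
      f <- integer(n)
      for (cl in names(counts)) {
        idx <- sample(which(labels == cl))
        f[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      f
    })
    for (fd in seq_len(n_folds)) {
      test <- which(fold[, rep_i] == fd)
      train <- which(fold[, rep_i] != fd)
      train_bal <- with_substream(
        seed, paste0("balance/rep", rep_i, "/fold", fd),
        balance_indices(train, labels[train])
      )
      splits[[length(splits) + 1]] <- list(
        train = train_bal, test = test, repeat_index = rep_i, fold = fd
      )
    }
  }
  structure(
    list(splits = splits, fold = fold, labels = labels,
         chunks = as.integer(chunks), n_folds = n_folds,
         n_repeats = n_repeats, seed = seed),
    class = "partition_scheme"
  )
}

# subsample each class to the minimum class count (drawn at random from
# the current RNG stream); returns sorted indices
balance_indices <- function(idx, labels) {
  counts <- table(labels)
  m <- min(counts)
  keep <- unlist(lapply(names(counts), function(cl) {
    pool <- idx[labels == cl]
    if (length(pool) > m) sample(pool, m) else pool
  }))
  sort(keep)
}

#' Linear discriminant classification of one pattern sample
#'
#' Fisher/Gaussian linear discriminant with equal priors and a pooled
#' within-class covariance shrunk toward a scaled identity using the
#' Ledoit-Wolf analytic coefficient, so the rule stays defined when
#' features outnumber training samples or are collinear. A discriminant
#' score of exactly zero is resolved to the first class in sorted label
#' order. This is the reference R implementation of the rule the compiled
#' searchlight engine applies sphere-wise.
#'
#' @param train Training matrix (samples x features).
#' @param labels Training class labels (exactly 2 classes present).
#' @param test Test matrix (same feature count).
#' @return Character vector of predicted labels, one per test row.
#' @export
lda_classify <- function(train, labels, test) {
  train <- as.matrix(train)
  test <- as.matrix(test, ncol = ncol(train))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop("training data must contain exactly 2 classes, got ",
         length(classes), call. = FALSE)
  }
  y <- as.integer(labels == classes[2])
  pred <- cpp_lda_predict(train, y, test)
  classes[pred + 1L]
}

#' Searchlight decoding accuracy map
#'
#' Runs the shrinkage-LDA classifier inside every sphere for each of the
#' scheme's 16 balanced train/test splits and averages accuracies per
#' sphere.
#'
#' @param patterns A `pattern_set`.
#' @param spheres A [build_searchlights()] set built on `patterns$voxels`.
#' @param scheme A [make_partitions()] scheme built from the same trials.
#' @param labels Per-trial class labels; defaults to the scheme's.
#' @param analysis_id Identifier carried into reports.
#' @return A tibble of class `accuracy_map` with columns `center` and
#'   `accuracy`, and attributes `analysis_id`, `n_spheres`, `grid`,
#'   `radius_mm`.
#' @export
searchlight_accuracy_map <- function(patterns, spheres, scheme,
                                     labels = scheme$labels,
                                     analysis_id = "analysis") {
  check_spheres_match(patterns, spheres)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(patterns$matrix))
  y <- label_to_int(labels)
  acc <- cpp_sphere_split_accuracy(
    patterns$matrix, patterns$matrix,
    purrr::map(spheres, "cols"),
    purrr::map(scheme$splits, "train"),
    purrr::map(scheme$splits, "test"),
    y, y
  )
  new_accuracy_map(
    center = purrr::map_int(spheres, ~ as.integer(.x$center)),
    accuracy = rowMeans(acc),
    analysis_id = analysis_id, spheres = spheres
  )
}

#' Cross-phase searchlight decoding
#'
#' Trains the sphere-wise classifier on one phase (typically visible) and
#' tests on the other (occluded), using the full trial sets of both sides
#' rather than folds -- train and test are disjoint by construction. Class
#' balance is enforced by subsampling each side, redrawn `n_repeats` times,
#' and the per-sphere accuracies are averaged over redraws. Decoding one
#' factor while collapsing the other (e.g. decoding velocity with both
#' directions pooled) is expressed by passing that factor's labels.
#'
#' @param train_patterns,test_patterns `pattern_set`s on identical voxel
#'   sets (e.g. visible- and occluded-phase patterns of one region).
#' @param spheres Sphere set built on the shared voxel set.
#' @param train_labels,test_labels Per-trial class labels of each side.
#' @param seed Integer seed for the balancing redraws.
#' @param n_repeats Number of balancing redraws (default 4).
#' @param analysis_id Identifier carried into reports.
#' @return An `accuracy_map` tibble.
#' @export
cross_phase_decode <- function(train_patterns, test_patterns, spheres,
                               train_labels, test_labels, seed,
                               n_repeats = 4L, analysis_id = "crossphase") {
  if (!identical(train_patterns$voxels, test_patterns$voxels)) {
    stop("train and test pattern sets live on different voxel sets",
         call. = FALSE)
  }
  check_spheres_match(train_patterns, spheres)
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  stopifnot(length(train_labels) == nrow(train_patterns$matrix),
            length(test_labels) == nrow(test_patterns$matrix))
  classes <- sort(unique(train_labels))
  if (!setequal(classes, unique(test_labels))) {
    stop("train and test label sets differ", call. = FALSE)
  }
  train_sets <- purrr::map(seq_len(n_repeats), function(k) {
    with_substream(seed, paste0("xphase/train/rep", k),
      balance_indices(seq_along(train_labels), train_labels))
  })
  test_sets <- purrr::map(seq_len(n_repeats), function(k) {
    with_substream(seed, paste0("xphase/test/rep", k),
      balance_indices(seq_along(test_labels), test_labels))
  })
  acc <- cpp_sphere_split_accuracy(
    train_patterns$matrix, test_patterns$matrix,
    purrr::map(spheres, "cols"),
    train_sets, test_sets,
    label_to_int(train_labels, classes), label_to_int(test_labels, classes)
  )
  new_accuracy_map(
    center = purrr::map_int(spheres, ~ as.integer(.x$center)),
    accuracy = rowMeans(acc),
    analysis_id = analysis_id, spheres = spheres
  )
}

label_to_int <- function(labels, classes = sort(unique(labels))) {
  if (length(classes) != 2) {
    stop("decoding requires exactly 2 classes, got ", length(classes),
         call. = FALSE)
  }
  as.integer(labels == classes[2])
}

check_spheres_match <- function(patterns, spheres) {
  ncols <- ncol(patterns$matrix)
  bad <- purrr::detect_index(spheres, ~ max(.x$cols) > ncols)
  if (bad > 0) {
    stop("sphere ", bad, " references pattern column ",
         max(spheres[[bad]]$cols), " but the pattern set has ", ncols,
         " voxels", call. = FALSE)
  }
  invisible(TRUE)
}

new_accuracy_map <- function(center, accuracy, analysis_id, spheres) {
  structure(
    tibble::new_tibble(
      tibble::tibble(center = center, accuracy = accuracy),
      nrow = length(center), class = "accuracy_map"
    ),
    analysis_id = analysis_id, n_spheres = length(center),
    grid = attr(spheres, "grid"), radius_mm = attr(spheres, "radius_mm")
  )
}

#' Write an accuracy map as NIfTI and TSV
#'
#' The NIfTI volume carries each sphere's accuracy at its center voxel and
#' 0 elsewhere; the TSV lists center index and accuracy.
#'
#' @param map An `accuracy_map`.
#' @param dir Output directory.
#' @param prefix Filename prefix (defaults to the analysis id).
#' @return Invisibly, the `nifti` and `tsv` paths.
#' @export
write_accuracy_map <- function(map, dir, prefix = attr(map, "analysis_id")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- attr(map, "grid")
  vol <- array(0, dim = grid$dims)
  vol[map$center] <- map$accuracy
  nii <- file.path(dir, paste0(prefix, "_accuracy.nii.gz"))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(img, nii)
  tsv <- file.path(dir, paste0(prefix, "_accuracy.tsv"))
  readr::write_tsv(tibble::tibble(center = map$center,
                                  accuracy = map$accuracy), tsv)
  invisible(list(nifti = nii, tsv = tsv))
}
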