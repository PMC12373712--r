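# accuracy_map stub with controlled accuracies
fake_map <- function(acc, centers = seq_along(acc), id = "fake") {
  structure(
    tibble::new_tibble(tibble::tibble(center = as.integer(centers),
                                      accuracy = acc),
                       nrow = length(acc), class = "accuracy_map"),
    analysis_id = id, n_spheres = length(acc),
    grid = volume_grid(c(12, 12, 12)), radius_mm = 4.4
  )
}

test_that("top-5% selection applies the cutoff, rounding and tie rules", {
  # 100 surviving spheres with distinct accuracies -> 5 selected
  acc <- c(seq(0.501, 0.6, length.out = 100), seq(0.1, 0.5, length.out = 50))
  sel <- select_informative_spheres(fake_map(acc))
  expect_equal(sel$n_surviving, 100)
  expect_equal(sel$n_selected, 5)
  expect_true(all(sel$selected_accuracies >=
                    stats::quantile(acc[acc > 0.5], 0.95)))
  # 40 surviving -> round(0.05 * 40) = 2
  sel40 <- select_informative_spheres(fake_map(seq(0.51, 0.9,
                                                   length.out = 40)))
  expect_equal(sel40$n_selected, 2)
  # fewer than 10 surviving -> floor of one sphere
  sel1 <- select_informative_spheres(fake_map(c(0.55, 0.52, 0.3)))
  expect_equal(sel1$n_selected, 1)
  expect_equal(sel1$selected_centers, 1L)
  # boundary ties break toward the lower center index
  tied <- fake_map(c(0.7, rep(0.6, 5)), centers = c(10L, 5L, 4L, 3L, 2L, 1L))
  sel_t <- select_informative_spheres(tied, top_fraction = 0.5)
  expect_equal(sel_t$n_selected, 3)
  expect_equal(sel_t$selected_centers, c(10L, 1L, 2L))
  # accuracies at or below the cutoff never enter
  expect_false(any(select_informative_spheres(
    fake_map(c(0.5, 0.500001, 0.49)))$selected_accuracies <= 0.5))
})

test_that("an all-below-chance map yields an explicit empty selection", {
  sel <- select_informative_spheres(fake_map(c(0.5, 0.42, 0.31)))
  expect_true(sel$empty)
  expect_equal(sel$n_selected, 0L)
  expect_true(is.na(sel$mean_accuracy))
  expect_error(
    subject_permutation_null(NULL, NULL, sel, labels = "x", n_iter = 5),
    "empty"
  )
})

test_that("the permutation p-value follows the N + 1 formula at both edges", {
  null3 <- rbind(c(0.48, 0.52, 0.55), c(0.50, 0.49, 0.51))
  # no permuted group mean reaches the true value -> p = 0
  pn <- group_level_p(c(0.9, 0.9), null3)
  expect_equal(pn$p_value, 0)
  expect_equal(pn$p_conservative, 1 / 4)
  # every permuted group mean reaches it -> p = N / (N + 1)
  pn2 <- group_level_p(c(0.4, 0.4), null3)
  expect_equal(pn2$p_value, 3 / 4)
  expect_equal(max(pn2$p_value), pn2$n_iter / (pn2$n_iter + 1))
  # p is monotonically non-increasing in the true value
  ps <- purrr::map_dbl(seq(0.4, 0.9, by = 0.05),
                       ~ group_level_p(c(.x, .x), null3)$p_value)
  expect_true(all(diff(ps) <= 0))
  expect_error(group_level_p(numeric(0), null3[0, , drop = FALSE]),
               "no subjects")
})

test_that("the identity permutation reproduces the true selected mean", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$lowerV1$member_voxels,
                 gm$masks$lowerV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  set.seed(21)
  X <- matrix(rnorm(64 * length(vox)), 64)
  lab <- rep(rep(c("a", "b"), each = 16), 2)
  ps <- manual_pattern_set(X, vox, run = rep(1:2, each = 32), gm$grid)
  sch <- make_partitions(lab, ps$meta$run, seed = 77)
  m <- searchlight_accuracy_map(ps, sph, sch, labels = lab)
  sel <- select_informative_spheres(m)
  again <- sphere_mean_accuracy(ps, sph, sel$selected_centers, lab,
                                scheme_seed = 77)
  expect_equal(again, sel$mean_accuracy, tolerance = 1e-12)
})

test_that("within-run shuffles preserve per-run class counts", {
  lab <- c(rep("a", 12), rep("b", 8), rep("a", 6), rep("b", 14))
  run <- rep(1:2, each = 20)
  set.seed(5)
  for (i in 1:50) {
    perm <- slmvpa:::shuffle_within_run(lab, run)
    expect_equal(table(perm[run == 1]), table(lab[run == 1]))
    expect_equal(table(perm[run == 2]), table(lab[run == 2]))
  }
})

test_that("fixed-center nulls center on chance; reselected nulls carry the selection inflation", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$lowerV1$member_voxels,
                 gm$masks$lowerV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  set.seed(31)
  X <- matrix(rnorm(64 * length(vox)), 64)
  lab <- rep(rep(c("a", "b"), each = 16), 2)
  ps <- manual_pattern_set(X, vox, run = rep(1:2, each = 32), gm$grid)
  sch <- make_partitions(lab, ps$meta$run, seed = 13)
  m <- searchlight_accuracy_map(ps, sph, sch, labels = lab)
  sel <- select_informative_spheres(m)
  # sampling the permuted maps at the fixed true-label centers gives
  # chance-level null means on signal-free data ...
  null_fx <- subject_permutation_null(ps, sph, sel, lab, n_iter = 200,
                                      seed = 99, reselect = FALSE)
  expect_length(null_fx, 200)
  expect_lt(abs(mean(null_fx) - 0.5), 3 * sd(null_fx) / sqrt(200))
  # ... while reselecting per permutation reproduces the same selection
  # inflation the true statistic has, keeping the two comparable
  null_re <- subject_permutation_null(ps, sph, sel, lab, n_iter = 100,
                                      seed = 99)
  expect_gt(mean(null_re), 0.55)
  expect_lt(abs(mean(null_re) - sel$mean_accuracy), 0.08)
})

test_that("selection inflates the true mean while the group p stays calibrated", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$upperV1$member_voxels,
                 gm$masks$upperV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  run <- rep(1:2, each = 32)
  lab <- rep(rep(c("a", "b"), each = 16), 2)
  subject_stats <- function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(64 * length(vox)), 64)
    ps <- manual_pattern_set(X, vox, run = run, gm$grid)
    sch <- make_partitions(lab, run, seed = seed * 13)
    m <- searchlight_accuracy_map(ps, sph, sch, labels = lab)
    sel <- select_informative_spheres(m)
    null <- subject_permutation_null(ps, sph, sel, lab, n_iter = 49,
                                     seed = seed * 7)
    list(true = sel$mean_accuracy, null = null)
  }
  p_vals <- purrr::map_dbl(1:12, function(rep_i) {
    subs <- purrr::map(1:2, ~ subject_stats(rep_i * 100 + .x))
    # selection bias: the TRUE mean over selected spheres sits above 0.5
    # even though the data are signal-free ...
    expect_true(all(purrr::map_dbl(subs, "true") > 0.5))
    group_level_p(purrr::map_dbl(subs, "true"),
                  do.call(rbind, purrr::map(subs, "null")))$p_value
  })
  # ... but the reselected null carries the same inflation, so the
  # p-values stay spread out rather than collapsing to 0
  expect_gt(mean(p_vals), 0.2)
  expect_lt(mean(p_vals < 0.05), 0.35)
})

test_that("sphere-center overlap counts pairs, all-way and random baseline", {
  mk_set <- function(centers, id, n_spheres = 200) {
    structure(
      list(selected_centers = centers,
           selected_accuracies = rep(0.7, length(centers)),
           mean_accuracy = 0.7, n_selected = length(centers),
           n_surviving = n_spheres, n_spheres = n_spheres, empty = FALSE,
           analysis_id = id, subject_id = "s1",
           grid = volume_grid(c(12, 12, 12))),
      class = "top_sphere_set"
    )
  }
  a <- mk_set(1:10, "a"); b <- mk_set(1:10, "b"); c <- mk_set(101:110, "c")
  ov_same <- sphere_center_overlap(list(a, b))
  expect_equal(ov_same$pairs$overlap, 10)
  expect_equal(ov_same$all_way, 10)
  ov_disj <- sphere_center_overlap(list(a, c))
  expect_equal(ov_disj$pairs$overlap, 0)
  expect_equal(ov_disj$pairs$expected_random, 10 * 10 / 200)
  expect_error(sphere_center_overlap(list(a)), "at least 2")
  bad <- mk_set(1:10, "d"); bad$grid <- volume_grid(c(10, 10, 10))
  expect_error(sphere_center_overlap(list(a, bad)), "different grids")

  # two analyses driven by one planted region overlap far beyond the
  # hypergeometric expectation for random selection
  gm <- tiny_world()
  vox <- setdiff(gm$masks$lowerV1$member_voxels,
                 gm$masks$lowerV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  set.seed(17)
  xyz <- slmvpa:::voxel_coords_mm(gm$grid, vox)
  signal_cols <- order(rowSums(sweep(xyz, 2, xyz[1, ])^2))[1:30]
  run <- rep(1:2, each = 32)
  lab1 <- rep(rep(c("a", "b"), each = 16), 2)
  lab2 <- rep(c("u", "d"), 32)
  X <- matrix(rnorm(64 * length(vox)), 64)
  X[lab1 == "a", signal_cols] <- X[lab1 == "a", signal_cols] + 2.5
  X[lab2 == "u", signal_cols] <- X[lab2 == "u", signal_cols] + 2.5
  ps <- manual_pattern_set(X, vox, run = run, gm$grid)
  sels <- purrr::map(list(lab1, lab2), function(lv) {
    sch <- make_partitions(lv, run, seed = 23)
    m <- searchlight_accuracy_map(ps, sph, sch, labels = lv)
    select_informative_spheres(m, top_fraction = 0.1)
  })
  ov <- sphere_center_overlap(sels)
  k1 <- sels[[1]]$n_selected; k2 <- sels[[2]]$n_selected
  crit <- stats::qhyper(0.999, k1, length(vox) - k1, k2)
  expect_gt(ov$pairs$overlap, crit)
})

test_that("paired accuracy comparisons recover a known shift", {
  set.seed(3)
  a <- rnorm(16, 0.6, 0.02)
  b <- a - 0.03 + rnorm(16, 0, 0.005)
  res <- paired_accuracy_test(a, b)
  expect_equal(res$df, 15)
  expect_lt(abs(res$estimate - 0.03), 0.01)
  expect_lt(res$p_value, 1e-6)
})
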