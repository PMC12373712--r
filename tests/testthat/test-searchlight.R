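test_that("sphere membership matches exhaustive lattice enumeration", {
  grid <- volume_grid(c(9, 9, 9), voxel_size = 2.2)
  all_vox <- seq_len(prod(grid$dims))
  sph <- build_searchlights(all_vox, grid, radius_mm = 4.4)
  # interior center: (4,4,4) 0-based
  center_lin <- 1 + 4 + 9 * (4 + 9 * 4)
  s <- sph[[which(purrr::map_int(sph, "center") == center_lin)]]
  off <- oracle_sphere_offsets(4.4, 2.2)
  expect_equal(length(s$members), nrow(off)) # 33
  expect_equal(nrow(off), 33)
  want <- sort(1 + (4 + off$dx) + 9 * ((4 + off$dy) + 9 * (4 + off$dz)))
  expect_equal(sort(s$members), want)
  # boundary center: a strict subset of the voxel set, fewer members
  corner <- sph[[1]]
  expect_true(all(corner$members %in% all_vox))
  expect_lt(length(corner$members), 33)
  expect_true(corner$center %in% corner$members)
})

test_that("a radius under the voxel spacing leaves singleton spheres", {
  grid <- volume_grid(c(5, 5, 5), voxel_size = 2.2)
  sph <- build_searchlights(seq_len(125), grid, radius_mm = 2.0)
  expect_true(all(lengths(purrr::map(sph, "members")) == 1))
})

test_that("partitions are stratified, balanced, exhaustive and seeded", {
  labels <- rep(c("up", "down"), each = 40)
  chunks <- rep(1:2, 40)
  sch <- make_partitions(labels, chunks, seed = 3)
  expect_length(sch$splits, 16)
  for (rep_i in 1:4) {
    folds <- sch$fold[, rep_i]
    # test folds partition the trial set into quarters
    expect_equal(sort(unique(folds)), 1:4)
    expect_true(all(table(folds) == 20))
    # stratification: each fold holds 10 of each class
    expect_true(all(table(folds, labels) == 10))
  }
  for (sp in sch$splits) {
    expect_equal(sort(c(sp$test, setdiff(seq_along(labels), sp$test))),
                 seq_along(labels))
    expect_true(all(table(labels[sp$train]) ==
                      min(table(labels[sp$train]))))
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(sch$splits,
                   make_partitions(labels, chunks, seed = 3)$splits)
  expect_false(identical(sch$splits,
                         make_partitions(labels, chunks, seed = 4)$splits))
})

test_that("unbalanced classes are balanced by subsampling in training", {
  labels <- rep(c("a", "b"), c(48, 32))
  sch <- make_partitions(labels, rep(1, 80), seed = 1)
  for (sp in sch$splits) {
    tab <- table(labels[sp$train])
    expect_equal(unname(tab["a"]), unname(tab["b"]))
  }
})

test_that("degenerate label sets are rejected", {
  expect_error(make_partitions(rep("a", 20), rep(1, 20), seed = 1),
               "2 classes")
  expect_error(make_partitions(rep(c("a", "b"), c(17, 3)), rep(1, 20),
                               seed = 1), "cannot stratify")
})

test_that("the discriminant separates, regularizes and breaks ties deterministically", {
  # separable point masses
  expect_equal(
    lda_classify(matrix(c(-1, -1, 1, 1)), c("neg", "neg", "pos", "pos"),
                 matrix(c(0.9, -0.2))),
    c("pos", "neg")
  )
  # duplicated (perfectly collinear) features predict like one feature
  set.seed(42)
  x1 <- matrix(rnorm(40), 40, 1) + rep(c(-1, 1), each = 20)
  lab <- rep(c("a", "b"), each = 20)
  te1 <- matrix(rnorm(20), 20, 1)
  p1 <- lda_classify(x1, lab, te1)
  p2 <- lda_classify(cbind(x1, x1, x1), lab, cbind(te1, te1, te1))
  expect_equal(p1, p2)
  # exact tie goes to the first class in sorted order
  expect_equal(
    lda_classify(matrix(c(-1, 1, -1, 1), 2, 2, byrow = FALSE),
                 c("a", "b"), matrix(0, 1, 2)),
    "a"
  )
})

test_that("shuffled training labels give chance-level accuracy", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, 5)
  Xte <- matrix(rnorm(400 * 5), 400, 5)
  acc <- purrr::map_dbl(1:200, function(i) {
    lab <- sample(rep(c("a", "b"), 30))
    pred <- lda_classify(X, lab, Xte)
    mean(pred == sample(rep(c("a", "b"), 200)))
  })
  expect_lt(abs(mean(acc) - 0.5), 3 * sd(acc) / sqrt(200))
})

test_that("the R rule and the compiled sphere engine agree with MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(11)
  # well-conditioned, strongly separated: shrinkage is negligible and all
  # three routes must give identical predictions
  n <- 150
  Xtr <- rbind(matrix(rnorm(n * 3), n, 3) - 2,
               matrix(rnorm(n * 3), n, 3) + 2)
  lab <- rep(c("lo", "hi"), each = n)
  Xte <- rbind(matrix(rnorm(25 * 3), 25, 3) - 2,
               matrix(rnorm(25 * 3), 25, 3) + 2)
  ours <- lda_classify(Xtr, lab, Xte)
  mass <- as.character(predict(MASS::lda(Xtr, grouping = lab), Xte)$class)
  expect_equal(ours, mass)
})

test_that("accuracy concentrates on spheres holding the planted signal", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$lowerV1$member_voxels,
                 gm$masks$lowerV1$reappearance_voxels)
  grid <- gm$grid
  sph <- build_searchlights(vox, grid)
  set.seed(3)
  n_tr <- 64
  lab <- rep(rep(c("up", "down"), each = 16), 2)
  # class difference confined to the 30 voxels nearest the first voxel
  xyz <- slmvpa:::voxel_coords_mm(grid, vox)
  d2 <- rowSums(sweep(xyz, 2, xyz[1, ])^2)
  signal_cols <- order(d2)[1:30]
  X <- matrix(rnorm(n_tr * length(vox)), n_tr)
  X[lab == "up", signal_cols] <- X[lab == "up", signal_cols] + 1.5
  ps <- manual_pattern_set(X, vox, run = rep(1:2, each = 32), grid)
  sch <- make_partitions(lab, ps$meta$run, seed = 9)
  m <- searchlight_accuracy_map(ps, sph, sch, labels = lab)
  top10 <- m$center[order(-m$accuracy)[1:10]]
  expect_true(all(top10 %in% vox[signal_cols]))
  # and crank the signal: monotone in planted effect size
  med_acc <- purrr::map_dbl(c(0.3, 0.8, 1.5), function(cnr) {
    accs <- purrr::map_dbl(1:5, function(s) {
      set.seed(100 + s)
      X <- matrix(rnorm(n_tr * length(vox)), n_tr)
      X[lab == "up", signal_cols] <- X[lab == "up", signal_cols] + cnr
      psx <- manual_pattern_set(X, vox, run = rep(1:2, each = 32), grid)
      schx <- make_partitions(lab, psx$meta$run, seed = 200 + s)
      mx <- searchlight_accuracy_map(psx, sph, schx, labels = lab)
      median(mx$accuracy[match(vox[signal_cols], mx$center)])
    })
    mean(accs)
  })
  expect_true(all(diff(med_acc) >= 0))
})

test_that("random labels and constant features stay at chance", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$upperV1$member_voxels,
                 gm$masks$upperV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  set.seed(5)
  means <- purrr::map_dbl(1:10, function(s) {
    X <- matrix(rnorm(64 * length(vox)), 64)
    lab <- sample(rep(c("a", "b"), 32))
    ps <- manual_pattern_set(X, vox, run = rep(1:2, each = 32), gm$grid)
    sch <- make_partitions(lab, ps$meta$run, seed = s)
    mean(searchlight_accuracy_map(ps, sph, sch, labels = lab)$accuracy)
  })
  expect_lt(abs(mean(means) - 0.5), 2 * sd(means) / sqrt(10))
  # constant features carry no information anywhere
  Xc <- matrix(1, 64, length(vox))
  ps <- manual_pattern_set(Xc, vox, run = rep(1:2, each = 32), gm$grid)
  lab <- rep(c("a", "b"), 32)
  sch <- make_partitions(lab, ps$meta$run, seed = 1)
  m <- searchlight_accuracy_map(ps, sph, sch, labels = lab)
  expect_true(all(abs(m$accuracy - 0.5) < 0.26))
  expect_lt(abs(mean(m$accuracy) - 0.5), 0.05)
})

test_that("cross-phase transfer follows the shared-pattern correlation", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$lowerV1$member_voxels,
                 gm$masks$lowerV1$reappearance_voxels)
  sph <- build_searchlights(vox, gm$grid)
  lab <- rep(rep(c("up", "down"), each = 20), 2)
  run <- rep(1:2, each = 40)
  build_phase_sets <- function(rho, noise = 0.7, seed = 1) {
    set.seed(seed)
    pat_vis <- rnorm(length(vox))
    pat_ind <- rnorm(length(vox))
    pat_occ <- rho * pat_vis + sqrt(1 - rho^2) * pat_ind
    mk <- function(pat) {
      X <- matrix(rnorm(80 * length(vox), sd = noise), 80)
      X[lab == "up", ] <- X[lab == "up", ] +
        matrix(pat, sum(lab == "up"), length(vox), byrow = TRUE)
      X
    }
    list(vis = manual_pattern_set(mk(pat_vis), vox, run, gm$grid),
         occ = manual_pattern_set(mk(pat_occ), vox, run, gm$grid))
  }
  hi <- build_phase_sets(rho = 1)
  m_hi <- cross_phase_decode(hi$vis, hi$occ, sph, lab, lab, seed = 2)
  expect_gt(mean(m_hi$accuracy), 0.8)
  lo <- build_phase_sets(rho = 0)
  m_lo <- cross_phase_decode(lo$vis, lo$occ, sph, lab, lab, seed = 2)
  expect_lt(abs(mean(m_lo$accuracy) - 0.5), 0.06)
  # noiseless symmetric design: swapping train and test preserves the
  # sphere ranking
  nz <- build_phase_sets(rho = 1, noise = 1e-6, seed = 3)
  f <- cross_phase_decode(nz$vis, nz$occ, sph, lab, lab, seed = 4)
  b <- cross_phase_decode(nz$occ, nz$vis, sph, lab, lab, seed = 4)
  expect_equal(order(-f$accuracy, f$center), order(-b$accuracy, b$center))
  expect_error(
    cross_phase_decode(hi$vis,
                       manual_pattern_set(hi$occ$matrix[, -1],
                                          vox[-1], run, gm$grid),
                       sph, lab, lab, seed = 1),
    "different voxel sets"
  )
})

test_that("maps are invariant to run relabelings preserving the folds", {
  gm <- tiny_world()
  vox <- setdiff(gm$masks$V5$member_voxels, integer(0))
  sph <- build_searchlights(vox, gm$grid)
  set.seed(8)
  X <- matrix(rnorm(48 * length(vox)), 48)
  lab <- rep(c("a", "b"), 24)
  ps1 <- manual_pattern_set(X, vox, run = rep(1:2, each = 24), gm$grid)
  ps2 <- manual_pattern_set(X, vox, run = rep(2:1, each = 24), gm$grid)
  sch <- make_partitions(lab, ps1$meta$run, seed = 6)
  m1 <- searchlight_accuracy_map(ps1, sph, sch, labels = lab)
  m2 <- searchlight_accuracy_map(ps2, sph, sch, labels = lab)
  expect_identical(m1$accuracy, m2$accuracy)
})
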