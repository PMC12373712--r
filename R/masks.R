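#' Volume grid geometry
#'
#' Isotropic voxel lattice with 0-based indices and voxel-center world
#' coordinates in mm (`coord = index * voxel_size`).
#'
#' @param dims Integer triple `(nx, ny, nz)`.
#' @param voxel_size Isotropic voxel edge in mm.
#' @return A list of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = 2.2) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), voxel_size > 0)
  structure(list(dims = dims, voxel_size = voxel_size), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.1f mm isotropic\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size))
  invisible(x)
}

# linear (1-based) index <-> 0-based (i,j,k) triples
voxel_linear_index <- function(grid, ijk) {
  1L + ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3])
}

voxel_ijk <- function(grid, lin) {
  lin0 <- lin - 1L
  i <- lin0 %% grid$dims[1]
  j <- (lin0 %/% grid$dims[1]) %% grid$dims[2]
  k <- lin0 %/% (grid$dims[1] * grid$dims[2])
  cbind(i = i, j = j, k = k)
}

voxel_coords_mm <- function(grid, lin) {
  voxel_ijk(grid, lin) * grid$voxel_size
}

# Grow a compact blob of n voxels around a seed voxel by repeatedly adding
# the unclaimed voxel nearest (in mm) to the blob centroid.
grow_blob <- function(grid, seed_ijk, n, taken) {
  all_ijk <- voxel_ijk(grid, seq_len(prod(grid$dims)))
  d2 <- rowSums(sweep(all_ijk, 2, seed_ijk)^2)
  d2[taken] <- Inf
  ord <- order(d2, seq_along(d2)) # deterministic tie-break by index
  ord[seq_len(n)]
}

#' Synthesize disjoint ROI masks on a voxel grid
#'
#' Builds three compact, pairwise-disjoint blobs standing in for lower V1,
#' upper V1 and V5/hMT+. A spatially contiguous fraction of each V1 mask is
#' tagged as responsive to the stimulus reappearance; those voxels are meant
#' to be excluded before any pattern analysis.
#'
#' @param dims Grid dimensions `(nx, ny, nz)`; each region needs room for
#'   at least `min_voxels` voxels.
#' @param seed Integer seed (mask placement is deterministic given it).
#' @param voxel_size Voxel edge, mm.
#' @param n_voxels Target voxels per region.
#' @param min_voxels Sizing floor; an error is raised if the grid cannot
#'   hold `3 * min_voxels` voxels.
#' @param reappearance_fraction Fraction of each V1 mask tagged
#'   reappearance-responsive (0 disables tagging).
#' @return A list with `grid` (a [volume_grid()]) and `masks`, a named list
#'   of `roi_mask` objects (`region`, `member_voxels`, `reappearance_voxels`
#'   as 1-based linear indices).
#' @export
generate_grid_and_masks <- function(dims = c(20, 20, 20), seed = 1,
                                    voxel_size = 2.2, n_voxels = 180,
                                    min_voxels = 150,
                                    reappearance_fraction = 0.1) {
  grid <- volume_grid(dims, voxel_size)
  n_voxels <- max(n_voxels, min_voxels)
  if (prod(grid$dims) < 3 * n_voxels) {
    stop("grid of ", prod(grid$dims), " voxels cannot hold 3 regions of ",
         n_voxels, " voxels", call. = FALSE)
  }
  regions <- c("lowerV1", "upperV1", "V5")
  # seed points spread along the longest axis, jittered under the seed
  centers <- with_substream(seed, "masks/centers", {
    base <- rbind(
      c(0.25, 0.25, 0.5), c(0.25, 0.75, 0.5), c(0.75, 0.5, 0.5)
    )
    jit <- matrix(stats::runif(9, -0.05, 0.05), 3, 3)
    pmin(pmax(base + jit, 0), 1)
  })
  taken <- logical(prod(grid$dims))
  masks <- list()
  for (r in seq_along(regions)) {
    seed_ijk <- round(centers[r, ] * (grid$dims - 1))
    members <- grow_blob(grid, seed_ijk, n_voxels, which(taken))
    taken[members] <- TRUE
    reapp <- integer(0)
    if (reappearance_fraction > 0 && regions[r] != "V5") {
      n_re <- round(reappearance_fraction * length(members))
      if (n_re > 0) {
        # contiguous: grow from the member farthest from the blob centroid
        ijk <- voxel_ijk(grid, members)
        ctr <- colMeans(ijk)
        far <- members[which.max(rowSums(sweep(ijk, 2, ctr)^2))]
        far_ijk <- voxel_ijk(grid, far)[1, ]
        d2 <- rowSums(sweep(ijk, 2, far_ijk)^2)
        reapp <- members[order(d2, seq_along(d2))[seq_len(n_re)]]
      }
    }
    masks[[regions[r]]] <- structure(
      list(region = regions[r], member_voxels = sort(members),
           reappearance_voxels = sort(reapp)),
      class = "roi_mask"
    )
  }
  list(grid = grid, masks = masks)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels (%d reappearance-tagged)\n",
              x$region, length(x$member_voxels), length(x$reappearance_voxels)))
  invisible(x)
}

#' Write an ROI mask as NIfTI
#'
#' Member voxels get value 1, reappearance-tagged voxels value 2,
#' background 0.
#'
#' @param mask An `roi_mask`.
#' @param grid The [volume_grid()] it lives on.
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_mask_nifti <- function(mask, grid, path) {
  vol <- array(0L, dim = grid$dims)
  vol[mask$member_voxels] <- 1L
  vol[mask$reappearance_voxels] <- 2L
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask written by [write_mask_nifti()]
#'
#' @param path NIfTI path.
#' @param region Region label to attach.
#' @return A list with `grid` and the `roi_mask`.
#' @export
read_mask_nifti <- function(path, region = "roi") {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  grid <- volume_grid(dim(vol), RNifti::pixdim(img)[1])
  mask <- structure(
    list(region = region,
         member_voxels = which(vol > 0),
         reappearance_voxels = which(vol == 2)),
    class = "roi_mask"
  )
  list(grid = grid, mask = mask)
}
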