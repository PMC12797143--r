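#' Analysis voxel grids
#'
#' A `voxel_grid` fixes the discrete sampling of all volumetric objects in a
#' meta-analysis: the array shape, the voxel size, and the affine mapping
#' between 0-based voxel indices and world (mm) coordinates.  All maps,
#' masks and networks in a given analysis must share one grid.
#'
#' @param shape Integer vector of length 3, array dimensions.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to
#'   world mm.  When `NULL`, an isotropic grid centred on the origin is
#'   built from `voxel_size`.
#' @param voxel_size Isotropic voxel edge length in mm (default 2).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(20, 20, 20))
#' voxel_volume(g)
voxel_grid <- function(shape, affine = NULL, voxel_size = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop_ale("grid shape must be 3 positive integers")
  }
  if (is.null(affine)) {
    origin <- -(shape - 1) / 2 * voxel_size
    affine <- rbind(cbind(diag(rep(voxel_size, 3)), origin), c(0, 0, 0, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    stop_ale("grid affine must be an invertible 4x4 matrix")
  }
  vox <- apply(affine[1:3, 1:3], 2, function(col) sqrt(sum(col^2)))
  structure(
    list(shape = shape, affine = affine, voxel_size = vox),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(
    "<voxel_grid> ", paste(x$shape, collapse = " x "),
    " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
    " mm (", format(voxel_volume(x)), " mm^3/voxel)\n",
    sep = ""
  )
  invisible(x)
}

#' Standard MNI152 grid at 2 mm resolution
#'
#' The conventional 91 x 109 x 91 analysis grid with the standard
#' radiological-ordering affine (first axis flipped), on which results are
#' reported at 2 x 2 x 2 mm resolution.
#'
#' @return A `voxel_grid`.
#' @export
mni_grid <- function() {
  affine <- rbind(
    c(-2, 0, 0, 90),
    c(0, 2, 0, -126),
    c(0, 0, 2, -72),
    c(0, 0, 0, 1)
  )
  voxel_grid(c(91L, 109L, 91L), affine = affine)
}

#' Voxel volume of a grid in cubic mm
#' @param grid A `voxel_grid`.
#' @return Scalar volume of one voxel (8 mm^3 on the default 2 mm grid).
#' @export
voxel_volume <- function(grid) {
  prod(grid$voxel_size)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

# xyz: n x 3 world mm -> n x 3 real-valued 0-based voxel coordinates
world_to_voxel_cont <- function(xyz, grid) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  hom <- t(cbind(xyz, rep(1, n)))
  t(solve(grid$affine) %*% hom)[, 1:3, drop = FALSE]
}

# n x 3 integer 1-based voxel indices + inside flag
world_to_voxel_idx <- function(xyz, grid) {
  v <- round(world_to_voxel_cont(xyz, grid)) + 1
  inside <- v[, 1] >= 1 & v[, 1] <= grid$shape[1] &
    v[, 2] >= 1 & v[, 2] <= grid$shape[2] &
    v[, 3] >= 1 & v[, 3] <= grid$shape[3]
  list(ijk = matrix(as.integer(v), ncol = 3), inside = inside)
}

# ijk: n x 3 1-based -> n x 3 world mm at voxel centres
voxel_to_world_xyz <- function(ijk, grid) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  hom <- t(cbind(ijk - 1, rep(1, nrow(ijk))))
  t(grid$affine %*% hom)[, 1:3, drop = FALSE]
}

#' Map world coordinates to voxel indices
#'
#' Adds nearest-voxel indices (`i`, `j`, `k`, 1-based) and an `in_grid`
#' flag to a table of world-mm coordinates.  Out-of-bounds coordinates are
#' flagged, never dropped.
#'
#' @param data Data frame with numeric `x`, `y`, `z` columns (mm).
#' @param grid A `voxel_grid`.
#' @return The input as a tibble with `i`, `j`, `k`, `in_grid` appended.
#' @seealso [voxel_to_world()]
#' @export
world_to_voxel <- function(data, grid) {
  stopifnot(all(c("x", "y", "z") %in% names(data)))
  res <- world_to_voxel_idx(cbind(data$x, data$y, data$z), grid)
  out <- tibble::as_tibble(data)
  out$i <- res$ijk[, 1]
  out$j <- res$ijk[, 2]
  out$k <- res$ijk[, 3]
  out$in_grid <- res$inside
  out
}

#' Map voxel indices to world coordinates of voxel centres
#'
#' @param data Data frame with integer `i`, `j`, `k` columns (1-based).
#' @param grid A `voxel_grid`.
#' @return The input as a tibble with `x`, `y`, `z` (mm) appended.
#' @export
voxel_to_world <- function(data, grid) {
  stopifnot(all(c("i", "j", "k") %in% names(data)))
  xyz <- voxel_to_world_xyz(cbind(data$i, data$j, data$k), grid)
  out <- tibble::as_tibble(data)
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  out
}
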