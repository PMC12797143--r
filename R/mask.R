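#' Brain masks
#'
#' A `brain_mask` pairs a [voxel_grid()] with a logical volume marking the
#' voxels that belong to the analysis domain (conventionally, voxels with
#' at least 10% probability of containing grey matter).  ALE scores, null
#' distributions and cluster inference are all restricted to this domain.
#'
#' @param grid A `voxel_grid`.
#' @param inside Logical array with dimensions `grid$shape`.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(grid, inside) {
  if (!inherits(grid, "voxel_grid")) stop_ale("grid must be a voxel_grid")
  inside <- array(as.logical(inside), dim = grid$shape)
  if (anyNA(inside)) stop_ale("mask may not contain NA")
  if (!any(inside)) stop_ale("mask is empty")
  structure(list(grid = grid, inside = inside), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(
    "<brain_mask> ", sum(x$inside), " of ", prod(x$grid$shape),
    " voxels inside (", paste(x$grid$shape, collapse = " x "), " grid)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of in-mask voxels
#' @param mask A `brain_mask`.
#' @return Integer count.
#' @export
mask_size <- function(mask) sum(mask$inside)

# world-mm coordinates of all in-mask voxel centres, n x 3
mask_centres <- function(mask) {
  ijk <- which(mask$inside, arr.ind = TRUE)
  voxel_to_world_xyz(ijk, mask$grid)
}

#' Load a grey-matter mask from a probability volume
#'
#' Thresholds a tissue-probability map at `threshold` (inclusive), the
#' conventional grey-matter restriction for coordinate-based
#' meta-analysis.  Probability scaling (0-1 versus 0-100) is
#' auto-detected from the maximum value.
#'
#' @param volume Path to a NIfTI file, an `RNifti` image, or a numeric
#'   array (the latter requires `grid`).
#' @param threshold Inclusive probability cut-off as a fraction
#'   (default 0.10).
#' @param grid Optional `voxel_grid` when `volume` is a bare array.
#' @return A [brain_mask()].  The in-mask voxel count is reported via a
#'   message.
#' @export
load_gm_mask <- function(volume, threshold = 0.10, grid = NULL) {
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  if (inherits(volume, "niftiImage")) {
    grid <- grid_from_nifti(volume)
    prob <- array(as.numeric(volume), dim = grid$shape)
  } else {
    if (is.null(grid)) stop_ale("grid required when volume is an array")
    prob <- array(as.numeric(volume), dim = grid$shape)
  }
  if (anyNA(prob)) prob[is.na(prob)] <- 0
  mx <- max(prob)
  if (mx > 1.5) prob <- prob / 100
  if (any(prob < -1e-6) || max(prob) > 1 + 1e-6) {
    stop_ale("probability volume must lie in [0,1] or [0,100]")
  }
  inside <- prob >= threshold
  if (!any(inside)) stop_ale("grey-matter mask is empty after thresholding")
  m <- brain_mask(grid, inside)
  message("grey-matter mask: ", mask_size(m), " voxels at threshold >= ", threshold)
  m
}

grid_from_nifti <- function(img) {
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  aff <- matrix(as.numeric(aff), 4, 4)
  voxel_grid(dim(img)[1:3], affine = aff)
}

#' Write a volume to NIfTI-1 preserving the grid affine
#'
#' @param values Numeric or logical array on `grid`.
#' @param grid A `voxel_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(values, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume and its grid from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return List with elements `values` (array) and `grid` (`voxel_grid`).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  list(values = array(as.numeric(img), dim = grid$shape), grid = grid)
}

# nearest-neighbour resampling of a logical volume onto a target grid;
# label data must never be interpolated
resample_mask_nn <- function(values, src_grid, tgt_grid) {
  ijk_t <- as.matrix(expand.grid(
    i = seq_len(tgt_grid$shape[1]),
    j = seq_len(tgt_grid$shape[2]),
    k = seq_len(tgt_grid$shape[3])
  ))
  xyz <- voxel_to_world_xyz(ijk_t, tgt_grid)
  src <- world_to_voxel_idx(xyz, src_grid)
  out <- array(FALSE, dim = tgt_grid$shape)
  ok <- src$inside
  lin_src <- src$ijk[ok, 1] +
    (src$ijk[ok, 2] - 1L) * src_grid$shape[1] +
    (src$ijk[ok, 3] - 1L) * src_grid$shape[1] * src_grid$shape[2]
  out[ok] <- as.logical(values)[lin_src]
  out
}
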