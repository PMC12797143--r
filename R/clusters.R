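#' Thresholding specification
#'
#' Collects every tunable of the inference stage: the cluster-forming
#' voxel-level threshold, the cluster-level family-wise alpha, the Monte
#' Carlo budget, the neighbourhood used to connect voxels into clusters,
#' the minimum cluster volume, and the random seed.
#'
#' @param voxel_alpha Voxel-level cluster-forming threshold (default
#'   0.001).
#' @param cluster_alpha Cluster-level family-wise error rate (default
#'   0.05).
#' @param n_permutations Monte Carlo permutations for the max-cluster null
#'   (default 1000; inference runs should use at least 100).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+
#'   corners, default) neighbour connectivity.
#' @param min_cluster_mm3 Minimum cluster volume in cubic mm (default 100,
#'   i.e. at least 13 voxels at 2 mm resolution).
#' @param seed Integer seed for the Monte Carlo stage.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(voxel_alpha = 0.001, cluster_alpha = 0.05,
                           n_permutations = 1000, connectivity = 26,
                           min_cluster_mm3 = 100, seed = 1L) {
  stopifnot(
    voxel_alpha > 0, voxel_alpha <= 1,
    cluster_alpha > 0, cluster_alpha <= 1,
    n_permutations >= 1,
    connectivity %in% c(6, 18, 26),
    min_cluster_mm3 >= 0
  )
  structure(
    list(
      voxel_alpha = voxel_alpha, cluster_alpha = cluster_alpha,
      n_permutations = as.integer(n_permutations),
      connectivity = as.integer(connectivity),
      min_cluster_mm3 = min_cluster_mm3, seed = as.integer(seed)
    ),
    class = "threshold_spec"
  )
}

#' Smallest voxel count satisfying a minimum cluster volume
#'
#' @param min_mm3 Minimum volume in cubic mm (e.g. 100).
#' @param grid A [voxel_grid()].
#' @return Integer voxel count (13 for 100 mm^3 on a 2 mm grid).
#' @export
min_cluster_voxels <- function(min_mm3, grid) {
  as.integer(ceiling(min_mm3 / voxel_volume(grid)))
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1,
    stop_ale("connectivity must be 6, 18 or 26")
  )
  off[keep, , drop = FALSE]
}

# connected-component labelling of a logical 3-D array;
# returns an integer array, 0 = background
label_components <- function(supra, connectivity = 26) {
  array(
    .label_components_cpp(supra, dim(supra), as.integer(connectivity)),
    dim = dim(supra)
  )
}

# cluster tibble from a supra-threshold logical array; stat used for peaks
cluster_table <- function(supra, grid, stat = NULL, connectivity = 26,
                          min_voxels = 1L) {
  labels <- label_components(supra, connectivity)
  n_lab <- max(labels)
  if (n_lab == 0L) return(empty_cluster_table())
  lin <- which(labels > 0L)
  lab <- labels[lin]
  sizes <- tabulate(lab, n_lab)
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) return(empty_cluster_table())
  rows <- lapply(seq_along(keep), function(ci) {
    l <- keep[ci]
    vox <- lin[lab == l]
    if (is.null(stat)) {
      peak_lin <- vox[1]
      peak_stat <- NA_real_
    } else {
      peak_lin <- vox[which.max(stat[vox])]
      peak_stat <- stat[peak_lin]
    }
    xyz <- voxel_to_world_xyz(arrayInd(peak_lin, grid$shape), grid)
    tibble::tibble(
      cluster_id = ci,
      size_voxels = length(vox),
      volume_mm3 = length(vox) * voxel_volume(grid),
      peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
      peak_ale = peak_stat,
      voxels = list(vox)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$size_voxels), ]
  out$cluster_id <- seq_len(nrow(out))
  out
}

empty_cluster_table <- function() {
  tibble::tibble(
    cluster_id = integer(), size_voxels = integer(), volume_mm3 = numeric(),
    peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
    peak_ale = numeric(), voxels = list()
  )
}

#' Form clusters from a p-value volume
#'
#' Groups voxels with `p < voxel_alpha` into connected components under
#' the declared connectivity and discards components smaller than the
#' minimum cluster volume.  An empty result is valid.
#'
#' @param p_volume Numeric array of p-values (`NA` off-mask).
#' @param spec A [threshold_spec()].
#' @param grid The analysis [voxel_grid()].
#' @param stat Optional statistic array (e.g. ALE scores) used to locate
#'   cluster peaks.
#' @return Tibble with one row per retained cluster: `cluster_id`,
#'   `size_voxels`, `volume_mm3`, peak coordinates, `peak_ale`, and a
#'   `voxels` list-column of linear indices.
#' @export
form_clusters <- function(p_volume, spec, grid, stat = NULL) {
  # voxel_alpha = 1 is the degenerate threshold: every defined voxel passes
  supra <- !is.na(p_volume) &
    (p_volume < spec$voxel_alpha | spec$voxel_alpha >= 1)
  cluster_table(
    supra, grid, stat, spec$connectivity,
    min_cluster_voxels(spec$min_cluster_mm3, grid)
  )
}
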