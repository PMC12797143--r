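#' Minimum-statistic conjunction of thresholded networks
#'
#' Under the conjunction null (at least one effect absent), a voxel is
#' retained only if it is significant in every input network; its value is
#' the voxelwise minimum of the retained ALE scores.  Connected components
#' of the conjunction smaller than `min_cluster_mm3` are removed, matching
#' the minimum-volume rule of the single-network analyses.
#'
#' @param nets List of two or more `ale_network` objects on one grid.
#' @param min_cluster_mm3 Minimum conjunction cluster volume (default 100;
#'   set 0 to disable the filter).
#' @param connectivity Cluster connectivity (default 26).
#' @return Object of class `ale_conjunction`: `labels` (source paradigm
#'   labels), `grid`, `values` (minimum ALE, zero off the support),
#'   `significant`, `n_voxels`, and `n_voxels_unfiltered` (support size
#'   before the volume filter).
#' @export
min_conjunction <- function(nets, min_cluster_mm3 = 100, connectivity = 26) {
  if (length(nets) < 2) stop_ale("conjunction needs at least two networks")
  grid <- nets[[1]]$grid
  values <- nets[[1]]$ale
  significant <- nets[[1]]$significant
  for (n in nets[-1]) {
    if (!same_grid(n$grid, grid)) stop_ale("networks are on different grids")
    values <- pmin(values, n$ale)
    significant <- significant & n$significant
  }
  values <- array(values, dim = grid$shape)
  values[!significant] <- 0
  n_unfiltered <- sum(significant)
  min_vox <- min_cluster_voxels(min_cluster_mm3, grid)
  if (min_vox > 1L && n_unfiltered > 0L) {
    labels <- label_components(significant, connectivity)
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_vox)
    if (length(drop)) {
      significant[labels %in% drop] <- FALSE
      values[!significant] <- 0
    }
  }
  structure(
    list(
      labels = vapply(nets, function(n) n$paradigm, ""),
      grid = grid, values = values, significant = significant,
      n_voxels = sum(significant), n_voxels_unfiltered = n_unfiltered,
      min_cluster_mm3 = min_cluster_mm3
    ),
    class = "ale_conjunction"
  )
}

#' @export
print.ale_conjunction <- function(x, ...) {
  cat(
    "<ale_conjunction> ", paste(x$labels, collapse = " & "), ": ",
    x$n_voxels, " voxels (", x$n_voxels_unfiltered, " before the ",
    x$min_cluster_mm3, " mm^3 filter)\n",
    sep = ""
  )
  invisible(x)
}

#' Overlap statistics between two networks
#'
#' Voxel counts of each network, of their raw intersection, and of the
#' intersection after the minimum-cluster-volume conjunction filter, with
#' percentages of each network's volume (rounded half away from zero to
#' one decimal).  Headline overlap percentages conventionally use the raw
#' intersection; both counts are reported.
#'
#' @param net_a,net_b `ale_network` objects on one grid (percentages
#'   `pct_of_a` are relative to `net_a`, conventionally the
#'   motor-imagery-analogue network).
#' @param min_cluster_mm3 Volume filter used for the filtered counts.
#' @return One-row tibble: `label_a`, `label_b`, `n_a`, `n_b`,
#'   `n_overlap`, `pct_of_a`, `pct_of_b`, `n_overlap_filtered`,
#'   `pct_of_a_filtered`.
#' @export
overlap_stats <- function(net_a, net_b, min_cluster_mm3 = 100) {
  if (!same_grid(net_a$grid, net_b$grid)) {
    stop_ale("networks are on different grids")
  }
  n_a <- net_a$total_voxels
  n_b <- net_b$total_voxels
  n_overlap <- sum(net_a$significant & net_b$significant)
  conj <- min_conjunction(list(net_a, net_b), min_cluster_mm3)
  if (n_a == 0 || n_b == 0) {
    warning("empty network: overlap percentage undefined")
  }
  pct <- function(num, den) {
    if (den == 0) return(NaN)
    round_half_up(100 * num / den, 1)
  }
  tibble::tibble(
    label_a = net_a$paradigm, label_b = net_b$paradigm,
    n_a = n_a, n_b = n_b, n_overlap = n_overlap,
    pct_of_a = pct(n_overlap, n_a),
    pct_of_b = pct(n_overlap, n_b),
    n_overlap_filtered = conj$n_voxels,
    pct_of_a_filtered = pct(conj$n_voxels, n_a)
  )
}
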