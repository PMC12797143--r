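#' Monte Carlo null distribution of the maximum cluster size
#'
#' For each permutation, every experiment's foci are relocated to
#' uniformly random in-mask voxel centres (per-experiment focus and
#' subject counts preserved), the ALE map is recomputed, thresholded at
#' the voxel-level critical score, clustered, filtered at the minimum
#' cluster volume, and the largest surviving cluster size recorded.  The
#' voxel-level critical ALE score is derived once from the histogram null
#' of the observed dataset — the null histogram depends only on the
#' kernels and the mask, not on where the foci sit, so it is reused
#' across permutations (set `recompute_null = TRUE` to rebuild it from
#' each permutation's relocated maps instead).
#'
#' @param foci Foci tibble for one dataset (single paradigm, MNI space).
#' @param mask A [brain_mask()].
#' @param spec A [threshold_spec()]; `spec$seed` fixes the permutations.
#' @param bin_width Null histogram bin width.
#' @param recompute_null Rebuild the histogram null inside every
#'   permutation (slower; the literal per-permutation pipeline).
#' @return Sorted integer vector of `spec$n_permutations` maximum cluster
#'   sizes (0 when a permutation has no surviving cluster), with
#'   attributes `critical_ale` and `null` (the observed-data `ale_null`).
#' @export
fwe_max_cluster_null <- function(foci, mask, spec, bin_width = 1e-5,
                                 recompute_null = FALSE) {
  if (spec$n_permutations < 1) stop_ale("n_permutations must be >= 1")
  grid <- mask$grid
  obs <- ale_from_foci(foci, grid, mask)
  null <- null_from_tables(obs$ma_tables, bin_width)
  crit <- ale_critical(null, spec$voxel_alpha)
  min_vox <- min_cluster_voxels(spec$min_cluster_mm3, grid)
  # per-experiment focus counts and kernels, fixed across permutations
  exps <- split(seq_len(nrow(foci)), foci$study_id)
  n_foci <- lengths(exps)
  n_subj <- vapply(exps, function(r) foci$n_subjects[r[1]], 1L)
  mask_ijk <- which(mask$inside, arr.ind = TRUE)
  n_in <- nrow(mask_ijk)
  max_sizes <- integer(spec$n_permutations)
  withr::with_seed(spec$seed, {
    for (b in seq_len(spec$n_permutations)) {
      one_minus <- array(1, dim = grid$shape)
      tabs <- if (recompute_null) vector("list", length(exps)) else NULL
      for (e in seq_along(exps)) {
        ijk <- mask_ijk[sample.int(n_in, n_foci[e], replace = TRUE), ,
          drop = FALSE]
        ma <- ma_values_ijk(ijk, n_subj[e], grid)
        one_minus <- one_minus * (1 - ma)
        if (recompute_null) tabs[[e]] <- ma_value_table(ma[mask$inside])
      }
      ale <- 1 - one_minus
      crit_b <- crit
      if (recompute_null) {
        crit_b <- ale_critical(null_from_tables(tabs, bin_width),
          spec$voxel_alpha)
      }
      supra <- mask$inside & ale >= crit_b & (ale > 0 | spec$voxel_alpha >= 1)
      max_sizes[b] <- max_surviving_size(supra, spec$connectivity, min_vox)
    }
  })
  structure(sort(max_sizes), critical_ale = crit, null = null)
}

max_surviving_size <- function(supra, connectivity, min_vox) {
  if (!any(supra)) return(0L)
  labels <- label_components(supra, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  sizes <- sizes[sizes >= min_vox]
  if (!length(sizes)) 0L else max(sizes)
}

# empirical critical size: clusters at or above it are retained (>= rule)
critical_cluster_size <- function(max_sizes, cluster_alpha) {
  if (cluster_alpha >= 1) return(0L)
  n <- length(max_sizes)
  sorted <- sort(as.integer(max_sizes))
  sorted[min(n, max(1L, ceiling((1 - cluster_alpha) * n)))]
}

#' Threshold a dataset into a significant network
#'
#' Runs the full observed pipeline — MA maps, ALE combination, histogram
#' null, voxel-level cluster-forming threshold, minimum cluster volume,
#' Monte Carlo max-cluster null, cluster-level FWE retention — and
#' assembles the surviving clusters into a network with their ALE values
#' retained.  A cluster exactly at the critical size is retained.
#'
#' @param foci Foci tibble for one dataset (single paradigm, MNI space).
#' @param mask A [brain_mask()].
#' @param spec A [threshold_spec()].
#' @param bin_width Null histogram bin width (default `1e-5`).
#' @param recompute_null See [fwe_max_cluster_null()].
#' @param max_sizes Optional precomputed result of
#'   [fwe_max_cluster_null()] (skips the Monte Carlo stage).
#' @return Object of class `ale_network`: `paradigm`, `grid`,
#'   `significant` (logical array), `ale` (ALE scores, zero off the
#'   significant set), `clusters` (tibble), `total_voxels`, plus the
#'   thresholds used.  [tidy()] returns the cluster table, [glance()] the
#'   one-row summary.
#' @export
threshold_network <- function(foci, mask, spec = threshold_spec(),
                              bin_width = 1e-5, recompute_null = FALSE,
                              max_sizes = NULL) {
  foci <- as_ale_foci(foci)
  if (any(foci$space != "MNI")) stop_ale("foci must be MNI; run tal2mni() first")
  grid <- mask$grid
  paradigm <- unique(foci$paradigm)
  if (length(paradigm) != 1L) stop_ale("threshold_network expects one paradigm")
  obs <- ale_from_foci(foci, grid, mask)
  null <- null_from_tables(obs$ma_tables, bin_width)
  crit <- ale_critical(null, spec$voxel_alpha)
  supra <- mask$inside & obs$ale >= crit & (obs$ale > 0 | spec$voxel_alpha >= 1)
  min_vox <- min_cluster_voxels(spec$min_cluster_mm3, grid)
  clusters <- cluster_table(supra, grid, obs$ale, spec$connectivity, min_vox)
  crit_size <- 0L
  if (spec$cluster_alpha < 1 && nrow(clusters) > 0) {
    if (is.null(max_sizes)) {
      max_sizes <- fwe_max_cluster_null(foci, mask, spec, bin_width,
        recompute_null)
    }
    crit_size <- critical_cluster_size(max_sizes, spec$cluster_alpha)
    clusters <- clusters[clusters$size_voxels >= max(crit_size, min_vox), ]
    clusters$cluster_id <- seq_len(nrow(clusters))
  }
  significant <- array(FALSE, dim = grid$shape)
  for (vox in clusters$voxels) significant[vox] <- TRUE
  ale_kept <- array(0, dim = grid$shape)
  ale_kept[significant] <- obs$ale[significant]
  structure(
    list(
      paradigm = paradigm, grid = grid,
      significant = significant, ale = ale_kept,
      clusters = clusters, total_voxels = sum(significant),
      spec = spec, critical_ale = crit,
      critical_cluster_size = crit_size,
      null = null
    ),
    class = "ale_network"
  )
}

#' @export
print.ale_network <- function(x, ...) {
  cat(
    "<ale_network> ", x$paradigm, ": ", x$total_voxels, " voxels in ",
    nrow(x$clusters), " cluster(s); voxel p < ", x$spec$voxel_alpha,
    ", cluster FWE ", x$spec$cluster_alpha, "\n",
    sep = ""
  )
  invisible(x)
}

# build an ale_network directly from arrays (used by conjunction /
# volume-matching algebra and by tests)
network_from_values <- function(values, grid, paradigm = "network",
                                spec = NULL, connectivity = 26) {
  significant <- values > 0
  clusters <- cluster_table(significant, grid, values, connectivity, 1L)
  structure(
    list(
      paradigm = paradigm, grid = grid,
      significant = significant, ale = values * significant,
      clusters = clusters, total_voxels = sum(significant),
      spec = spec, critical_ale = NA_real_,
      critical_cluster_size = NA_integer_, null = NULL
    ),
    class = "ale_network"
  )
}
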