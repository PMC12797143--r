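# place a kernel centred on voxel ijk into vol under the max rule,
# clipping at the grid bounds; vol modified and returned
place_kernel_max <- function(vol, kern, ijk, shape) {
  kd <- dim(kern)
  r <- (kd - 1L) %/% 2L
  lo_v <- pmax(ijk - r, 1L)
  hi_v <- pmin(ijk + r, shape)
  if (any(lo_v > hi_v)) return(vol)
  lo_k <- lo_v - (ijk - r) + 1L
  hi_k <- lo_k + (hi_v - lo_v)
  sub <- vol[lo_v[1]:hi_v[1], lo_v[2]:hi_v[2], lo_v[3]:hi_v[3]]
  ksub <- kern[lo_k[1]:hi_k[1], lo_k[2]:hi_k[2], lo_k[3]:hi_k[3]]
  vol[lo_v[1]:hi_v[1], lo_v[2]:hi_v[2], lo_v[3]:hi_v[3]] <- pmax(sub, ksub)
  vol
}

place_kernel_union <- function(vol, kern, ijk, shape) {
  kd <- dim(kern)
  r <- (kd - 1L) %/% 2L
  lo_v <- pmax(ijk - r, 1L)
  hi_v <- pmin(ijk + r, shape)
  if (any(lo_v > hi_v)) return(vol)
  lo_k <- lo_v - (ijk - r) + 1L
  hi_k <- lo_k + (hi_v - lo_v)
  sub <- vol[lo_v[1]:hi_v[1], lo_v[2]:hi_v[2], lo_v[3]:hi_v[3]]
  ksub <- kern[lo_k[1]:hi_k[1], lo_k[2]:hi_k[2], lo_k[3]:hi_k[3]]
  vol[lo_v[1]:hi_v[1], lo_v[2]:hi_v[2], lo_v[3]:hi_v[3]] <-
    1 - (1 - sub) * (1 - ksub)
  vol
}

# MA values for one experiment directly as an array; foci given as an
# n x 3 matrix of MNI mm coordinates
ma_values <- function(xyz, n_subjects, grid, aggregate = "max",
                      truncate = 5, constants = ale_kernel_constants()) {
  kern <- ale_kernel_array(n_subjects, grid, truncate, constants)
  idx <- world_to_voxel_idx(xyz, grid)
  if (aggregate == "max") {
    return(array(
      .ma_max_map_cpp(grid$shape, kern, dim(kern), idx$ijk),
      dim = grid$shape
    ))
  }
  vol <- array(0, dim = grid$shape)
  for (f in seq_len(nrow(idx$ijk))) {
    vol <- place_kernel_union(vol, kern, idx$ijk[f, ], grid$shape)
  }
  vol
}

# MA map from 1-based voxel-index centres (permutation fast path)
ma_values_ijk <- function(ijk, n_subjects, grid, truncate = 5,
                          constants = ale_kernel_constants()) {
  kern <- ale_kernel_array(n_subjects, grid, truncate, constants)
  array(.ma_max_map_cpp(grid$shape, kern, dim(kern), ijk), dim = grid$shape)
}

#' Modelled activation (MA) map for one experiment
#'
#' Each focus contributes a 3-D Gaussian probability mass whose width is
#' set by the experiment's sample size ([kernel_sigma()]).  Within an
#' experiment, contributions are combined voxelwise by the maximum (the
#' revised, non-additive rule), so a focus reported twice changes nothing.
#' Kernels are truncated at `truncate` sigma.
#'
#' @param experiment Foci tibble for a single experiment: one `study_id`,
#'   all rows MNI-space, non-empty.
#' @param grid Analysis [voxel_grid()].
#' @param aggregate `"max"` (revised rule, default) or `"union"` (the
#'   older additive-style probabilistic union, for comparison only).
#' @param truncate Kernel support radius in sigmas (default 5).
#' @param constants Kernel constants, see [ale_kernel_constants()].
#' @return Object of class `ma_map`: list with `experiment_id`, `grid`,
#'   `values` (array of probabilities in `[0, 1]`).
#' @export
compute_ma_map <- function(experiment, grid, aggregate = c("max", "union"),
                           truncate = 5, constants = ale_kernel_constants()) {
  aggregate <- match.arg(aggregate)
  if (nrow(experiment) == 0L) stop_ale("experiment has no foci")
  if (length(unique(experiment$study_id)) != 1L) {
    stop_ale("compute_ma_map expects foci from a single experiment")
  }
  if (any(experiment$space != "MNI")) {
    stop_ale("all foci must be in MNI space; run tal2mni() first")
  }
  vol <- ma_values(
    cbind(experiment$x, experiment$y, experiment$z),
    experiment$n_subjects[1], grid, aggregate, truncate, constants
  )
  structure(
    list(
      experiment_id = experiment$study_id[1],
      n_subjects = experiment$n_subjects[1],
      grid = grid, values = vol
    ),
    class = "ma_map"
  )
}

#' @export
print.ma_map <- function(x, ...) {
  cat(
    "<ma_map> experiment ", x$experiment_id, ", n = ", x$n_subjects,
    ", max MA = ", signif(max(x$values), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Combine MA maps into an ALE map
#'
#' The ALE score at a voxel is the probability that at least one
#' experiment's true activation lies there, under independence:
#' `ALE = 1 - prod(1 - MA_i)`.  It is bounded by
#' `max(MA_i) <= ALE <= sum(MA_i)` and is invariant to experiment order.
#'
#' @param ma_maps List of `ma_map` objects on a common grid.
#' @return Object of class `ale_map`: list with `grid`, `values`,
#'   `n_experiments`.
#' @export
compute_ale_map <- function(ma_maps) {
  if (!length(ma_maps)) stop_ale("no MA maps supplied")
  grid <- ma_maps[[1]]$grid
  one_minus <- array(1, dim = grid$shape)
  for (m in ma_maps) {
    if (!same_grid(m$grid, grid)) stop_ale("MA maps are on different grids")
    one_minus <- one_minus * (1 - m$values)
  }
  structure(
    list(grid = grid, values = 1 - one_minus, n_experiments = length(ma_maps)),
    class = "ale_map"
  )
}

#' @export
print.ale_map <- function(x, ...) {
  cat(
    "<ale_map> ", x$n_experiments, " experiments, max ALE = ",
    signif(max(x$values), 4), "\n",
    sep = ""
  )
  invisible(x)
}

# streaming ALE over a dataset: returns the ALE array plus the per-
# experiment in-mask MA value tables needed by the histogram null,
# without keeping every MA array in memory
ale_from_foci <- function(foci, grid, mask = NULL, truncate = 5,
                          constants = ale_kernel_constants()) {
  exps <- split(seq_len(nrow(foci)), foci$study_id)
  one_minus <- array(1, dim = grid$shape)
  tables <- vector("list", length(exps))
  inside <- if (is.null(mask)) NULL else mask$inside
  for (e in seq_along(exps)) {
    rows <- exps[[e]]
    vol <- ma_values(
      cbind(foci$x[rows], foci$y[rows], foci$z[rows]),
      foci$n_subjects[rows[1]], grid, "max", truncate, constants
    )
    one_minus <- one_minus * (1 - vol)
    if (!is.null(inside)) tables[[e]] <- ma_value_table(vol[inside])
  }
  list(ale = 1 - one_minus, ma_tables = tables, experiment_ids = names(exps))
}

# distinct-value probability table of in-mask MA values (full precision;
# no round-trip through character names)
ma_value_table <- function(v) {
  uv <- sort(unique(v))
  counts <- tabulate(match(v, uv), nbins = length(uv))
  list(values = uv, probs = counts / length(v))
}
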