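#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a thresholded network into its cluster table
#'
#' @param x An `ale_network`.
#' @param ... Unused.
#' @return Tibble with one row per surviving cluster (id, size, volume,
#'   peak MNI coordinates, peak ALE score).
#' @method tidy ale_network
#' @export
tidy.ale_network <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' One-row summary of a thresholded network
#'
#' @param x An `ale_network`.
#' @param ... Unused.
#' @return One-row tibble: paradigm, total voxels, cluster count and the
#'   thresholds applied.
#' @method glance ale_network
#' @export
glance.ale_network <- function(x, ...) {
  tibble::tibble(
    paradigm = x$paradigm,
    total_voxels = x$total_voxels,
    n_clusters = nrow(x$clusters),
    voxel_alpha = if (is.null(x$spec)) NA_real_ else x$spec$voxel_alpha,
    cluster_alpha = if (is.null(x$spec)) NA_real_ else x$spec$cluster_alpha,
    critical_ale = x$critical_ale,
    critical_cluster_size = x$critical_cluster_size
  )
}

#' Tidy an ALE null histogram
#'
#' @param x An `ale_null`.
#' @param ... Unused.
#' @return Tibble with `score` (bin lower edge), `prob` and `surv`
#'   columns, zero-probability bins dropped.
#' @method tidy ale_null
#' @export
tidy.ale_null <- function(x, ...) {
  keep <- x$prob > 0
  tibble::tibble(
    score = (which(keep) - 1) * x$bin_width,
    prob = x$prob[keep],
    surv = x$surv[keep]
  )
}

#' One-row summary of an ALE null histogram
#' @param x An `ale_null`.
#' @param ... Unused.
#' @return One-row tibble with the bin width, bin count, combination
#'   method and experiment count.
#' @method glance ale_null
#' @export
glance.ale_null <- function(x, ...) {
  tibble::tibble(
    n_experiments = x$n_experiments,
    bin_width = x$bin_width,
    n_bins = length(x$prob),
    method = x$method,
    max_score = (length(x$prob) - 1) * x$bin_width
  )
}

#' Tidy a conjunction map
#' @param x An `ale_conjunction`.
#' @param ... Unused.
#' @return One-row tibble with the source labels and voxel counts before
#'   and after the minimum-volume filter.
#' @method tidy ale_conjunction
#' @export
tidy.ale_conjunction <- function(x, ...) {
  tibble::tibble(
    labels = paste(x$labels, collapse = " & "),
    n_voxels = x$n_voxels,
    n_voxels_unfiltered = x$n_voxels_unfiltered,
    min_cluster_mm3 = x$min_cluster_mm3
  )
}

#' Tidy a volume-match result
#' @param x A `volume_match`.
#' @param ... Unused.
#' @return One-row tibble: label, target and achieved voxel counts,
#'   applied threshold.
#' @method tidy volume_match
#' @export
tidy.volume_match <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    target_voxels = x$target_voxels,
    achieved_voxels = x$achieved_voxels,
    applied_threshold = x$applied_threshold
  )
}
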