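# long-format slice data for volumetric plots
slice_df <- function(values, grid, slices) {
  ks <- slices
  rows <- lapply(ks, function(k) {
    sl <- values[, , k]
    ij <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
      j = seq_len(grid$shape[2])))
    xyz <- voxel_to_world_xyz(cbind(ij, k), grid)
    tibble::tibble(
      x = xyz[, 1], y = xyz[, 2],
      z = round(xyz[1, 3], 1), value = as.vector(sl)
    )
  })
  dplyr::bind_rows(rows)
}

default_slices <- function(significant, shape, n = 6) {
  ks <- which(apply(significant, 3, any))
  if (!length(ks)) ks <- round(shape[3] / 2)
  unique(round(seq(min(ks), max(ks), length.out = min(n, length(ks)))))
}

#' Plot axial slices of a thresholded network
#'
#' Retained ALE values on a panel of axial slices spanning the
#' significant voxels.
#'
#' @param object An `ale_network`.
#' @param slices Integer vector of axial slice indices (default: up to 6
#'   slices spanning the significant set).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ale_network
#' @export
autoplot.ale_network <- function(object, slices = NULL, ...) {
  slices <- slices %||% default_slices(object$significant, object$grid$shape)
  df <- slice_df(object$ale, object$grid, slices)
  df$value[df$value == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey15", name = "ALE") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0(object$paradigm, " network (",
        object$total_voxels, " voxels)"),
      x = "x (mm)", y = "y (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a conjunction map's axial slices
#'
#' @param object An `ale_conjunction`.
#' @param slices Axial slice indices (default chosen from the support).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ale_conjunction
#' @export
autoplot.ale_conjunction <- function(object, slices = NULL, ...) {
  slices <- slices %||% default_slices(object$significant, object$grid$shape)
  df <- slice_df(object$values, object$grid, slices)
  df$value[df$value == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey15", name = "min ALE") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste(paste(object$labels, collapse = " & "), "conjunction"),
      x = "x (mm)", y = "y (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ALE null distribution's survival function
#'
#' @param object An `ale_null`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled survival probability against ALE
#'   score).
#' @method autoplot ale_null
#' @export
autoplot.ale_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "ALE score", y = "P(ALE >= score)",
      title = "Null distribution of ALE scores"
    ) +
    ggplot2::theme_minimal()
}

#' Diverging bar chart of a region overlap table
#'
#' Positive bars: regions of the imagery-analogue network overlapping
#' more with working memory; negative: more with execution.
#'
#' @param table Output of [region_overlap_table()] (or the reference
#'   counts passed through [region_overlap_derive()]).
#' @return A ggplot object.
#' @export
plot_region_overlap <- function(table) {
  df <- dplyr::mutate(table,
    area = factor(.data$area, levels = rev(.data$area[order(-.data$diff_overlap)])),
    direction = ifelse(.data$diff_overlap >= 0, "working memory", "execution")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff_overlap, y = .data$area,
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "overlap difference (voxels, WM - EX)", y = NULL,
      fill = "greater overlap with"
    ) +
    ggplot2::theme_minimal()
}
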