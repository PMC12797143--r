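#' Region templates
#'
#' A `region_template` is a named binary mask on the analysis grid,
#' typically an atlas area (Brodmann area, HMAT motor area, cerebellar
#' lobule, cytoarchitectonic parietal map).  Templates are supplied by the
#' user as NIfTI volumes; label data are resampled by nearest neighbour,
#' never interpolated.
#'
#' @param mask Logical array on `grid`, or a [brain_mask()].
#' @param name Unique area name (e.g. `"DLPFC"`, `"PMd"`).
#' @param grid A [voxel_grid()] (ignored when `mask` is a `brain_mask`).
#' @param source Free-text atlas provenance.
#' @return Object of class `region_template`.
#' @export
region_template <- function(mask, name, grid = NULL, source = NA_character_) {
  if (inherits(mask, "brain_mask")) {
    grid <- mask$grid
    mask <- mask$inside
  }
  if (is.null(grid)) stop_ale("grid required")
  mask <- array(as.logical(mask), dim = grid$shape)
  if (!any(mask)) stop_ale("region template '", name, "' is empty")
  structure(
    list(name = name, grid = grid, mask = mask, source = source),
    class = "region_template"
  )
}

#' @export
print.region_template <- function(x, ...) {
  cat(
    "<region_template> ", x$name, ": ", sum(x$mask), " voxels",
    if (!is.na(x$source)) paste0(" [", x$source, "]"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Load a region template from a NIfTI volume
#'
#' Non-zero voxels define the region.  If the volume's grid differs from
#' the analysis grid it is resampled by nearest neighbour.
#'
#' @param path NIfTI file.
#' @param name Area name.
#' @param grid Target analysis [voxel_grid()].
#' @param source Atlas provenance label.
#' @return A [region_template()].
#' @export
load_region_template <- function(path, name, grid, source = NA_character_) {
  vol <- read_volume_nifti(path)
  m <- vol$values > 0
  if (!same_grid(vol$grid, grid)) {
    m <- resample_mask_nn(m, vol$grid, grid)
  }
  region_template(m, name, grid, source)
}

#' Merge region templates by voxelwise union
#'
#' Used e.g. to build a DLPFC template as the union of the Brodmann
#' area 9 and area 46 templates.
#'
#' @param parts List of `region_template` objects on one grid.
#' @param name Name for the merged template.
#' @return A [region_template()] whose `source` lists the parts.
#' @export
merge_templates <- function(parts, name) {
  if (!length(parts)) stop_ale("no templates to merge")
  grid <- parts[[1]]$grid
  m <- array(FALSE, dim = grid$shape)
  for (p in parts) {
    if (!same_grid(p$grid, grid)) stop_ale("templates are on different grids")
    m <- m | p$mask
  }
  region_template(
    m, name, grid,
    source = paste("merge of", paste(vapply(parts, function(p) p$name, ""),
      collapse = " + "))
  )
}

#' Derived columns of a region overlap table
#'
#' From raw voxel counts — region-and-imagery (`vol_area_mi`), the triple
#' conjunctions with working memory (`vol_area_mi_wm`) and execution
#' (`vol_area_mi_ex`) — computes the percentage of the recruited region
#' shared with each paradigm (relative to `vol_area_mi`, rounded half
#' away from zero to one decimal), the overlap difference in voxels
#' (positive = greater working-memory overlap) and its percent form.
#'
#' @param counts Data frame with columns `vol_area_mi`, `vol_area_mi_wm`,
#'   `vol_area_mi_ex`.
#' @return The input tibble with `pct_wm`, `pct_ex`, `diff_overlap`,
#'   `diff_pct` appended.
#' @export
region_overlap_derive <- function(counts) {
  out <- tibble::as_tibble(counts)
  den <- out$vol_area_mi
  if (any(den == 0)) {
    warning("region with empty imagery overlap: percentages undefined")
  }
  pct <- function(num) ifelse(den > 0, round_half_up(100 * num / den, 1), NaN)
  out$pct_wm <- pct(out$vol_area_mi_wm)
  out$pct_ex <- pct(out$vol_area_mi_ex)
  out$diff_overlap <- out$vol_area_mi_wm - out$vol_area_mi_ex
  out$diff_pct <- pct(out$diff_overlap)
  out
}

#' Per-region overlap row
#'
#' Intersects one region template with the motor-imagery-analogue network
#' and with the triple conjunctions against execution and working memory,
#' returning the voxel counts and derived percentages.
#'
#' @param template A [region_template()].
#' @param mi,ex,wm `ale_network` objects on the template's grid (the
#'   imagery-analogue network supplies the percentage denominator).
#' @return One-row tibble: `area`, `total_volume`, `vol_area_mi`,
#'   `vol_area_mi_wm`, `vol_area_mi_ex`, `pct_wm`, `pct_ex`,
#'   `diff_overlap`, `diff_pct`.
#' @export
region_overlap_row <- function(template, mi, ex, wm) {
  for (n in list(mi, ex, wm)) {
    if (!same_grid(n$grid, template$grid)) {
      stop_ale("network grid does not match template grid")
    }
  }
  t_mi <- template$mask & mi$significant
  counts <- tibble::tibble(
    area = template$name,
    total_volume = sum(template$mask),
    vol_area_mi = sum(t_mi),
    vol_area_mi_wm = sum(t_mi & wm$significant),
    vol_area_mi_ex = sum(t_mi & ex$significant)
  )
  region_overlap_derive(counts)
}

#' Region overlap table across templates
#'
#' One [region_overlap_row()] per template, sorted by `diff_overlap`
#' descending.  With `volume_matched = TRUE` the three networks are first
#' reduced to the smallest network's volume with [match_all()], giving the
#' volume-matched variant of the table on the identical schema.
#'
#' @param templates List of [region_template()] objects.
#' @param mi,ex,wm `ale_network` objects.
#' @param volume_matched Apply [match_all()] to the three networks first.
#' @return Tibble with one row per template plus a `variant` column
#'   (`"full"` or `"volume_matched"`).
#' @export
region_overlap_table <- function(templates, mi, ex, wm,
                                 volume_matched = FALSE) {
  if (volume_matched) {
    target <- min(mi$total_voxels, ex$total_voxels, wm$total_voxels)
    mi <- match_volume(mi, target)$matched
    ex <- match_volume(ex, target)$matched
    wm <- match_volume(wm, target)$matched
  }
  rows <- dplyr::bind_rows(lapply(templates, region_overlap_row,
    mi = mi, ex = ex, wm = wm))
  rows$variant <- if (volume_matched) "volume_matched" else "full"
  rows[order(-rows$diff_overlap), ]
}
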