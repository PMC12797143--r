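ref_path <- function(file) {
  system.file("extdata", file, package = "aleoverlap", mustWork = TRUE)
}

#' Published per-paradigm dataset summary
#'
#' The per-paradigm paper/experiment/participant/focus counts of the
#' published three-paradigm meta-analytic comparison of movement
#' execution, motor imagery and working memory, including the printed
#' all-paradigms row.  Useful for checking [dataset_summary()] arithmetic
#' against the printed totals.
#'
#' @return Tibble with columns `paradigm`, `papers`, `experiments`,
#'   `participants`, `foci` (rows: the three paradigms plus `all`).
#' @export
reference_paradigm_summary <- function() {
  readr::read_tsv(ref_path("reference_paradigm_summary.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published per-region overlap counts
#'
#' The per-region voxel counts of the published comparison: for each of
#' 16 atlas areas, the template volume, its intersection with the motor
#' imagery network, the triple conjunctions with working memory and with
#' movement execution, and the printed derived values (overlap difference
#' and, where printed, percentages), for both the full-network and the
#' volume-matched variants.  [region_overlap_derive()] recomputes the
#' derived columns from the raw counts.
#'
#' @return Tibble, one row per area.
#' @export
reference_region_overlap <- function() {
  readr::read_tsv(ref_path("reference_region_overlap.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published headline network volumes and overlap percentages
#'
#' Whole-network voxel counts of the three published networks, the
#' headline overlap percentages of the imagery network with working
#' memory and execution, and the volume-matched variants.  These derive
#' from the full deposited coordinate data and full permutation budgets;
#' they are reference values, not desk-scale reproducible outputs.
#'
#' @return Tibble with columns `metric`, `value`.
#' @export
reference_headline_volumes <- function() {
  readr::read_tsv(ref_path("reference_headline_volumes.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
}
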