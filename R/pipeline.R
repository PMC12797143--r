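with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_ale("stage '", stage, "' failed: ", conditionMessage(e),
      class = "aleoverlap_stage_error"
    )
  })
}

#' Assemble or load a pipeline run configuration
#'
#' @param foci Path to the foci TSV/CSV (see [read_foci_table()]).
#' @param gm_mask Path to the grey-matter probability NIfTI.
#' @param out_dir Output directory (created if absent).
#' @param templates Named character vector of region-template NIfTI paths
#'   (optional).
#' @param threshold List of [threshold_spec()] arguments.
#' @param seed Integer master seed.
#' @param volume_matched Also emit volume-matched conjunctions and region
#'   tables.
#' @param filtered_overlap Use the volume-filtered conjunction count for
#'   headline overlap percentages (both counts are always reported).
#' @param resample_templates Allow nearest-neighbour resampling of
#'   templates onto the analysis grid; when `FALSE` (default) a grid
#'   mismatch is an error.
#' @param bin_width Null histogram bin width.
#' @return A `run_config` list, serialisable to YAML with
#'   [yaml::write_yaml()].
#' @export
run_config <- function(foci, gm_mask, out_dir, templates = NULL,
                       threshold = list(), seed = 1L,
                       volume_matched = TRUE, filtered_overlap = FALSE,
                       resample_templates = FALSE, bin_width = 1e-5) {
  structure(
    list(
      foci = foci, gm_mask = gm_mask, out_dir = out_dir,
      templates = templates, threshold = threshold, seed = as.integer(seed),
      volume_matched = isTRUE(volume_matched),
      filtered_overlap = isTRUE(filtered_overlap),
      resample_templates = isTRUE(resample_templates),
      bin_width = bin_width
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full meta-analysis pipeline
#'
#' Per-paradigm ALE networks (voxel-level cluster-forming threshold,
#' Monte Carlo cluster-level FWE, minimum cluster volume), pairwise and
#' triple minimum-statistic conjunctions against the imagery-analogue
#' network, overlap statistics, volume-matched variants, and — when
#' region templates are supplied — the per-region overlap tables.  All
#' volumes are written as NIfTI-1 with the analysis-grid affine, tables
#' as TSV, summaries as JSON; a run log records the seed, thresholds and
#' voxel counts.  Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config A [run_config()] (or path to its YAML file).
#' @return Invisibly, a list with the networks, conjunctions, overlap
#'   tables, volume-match results and region tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("aleoverlap ", as.character(utils::packageVersion("aleoverlap"))),
    paste0("seed: ", config$seed)
  )

  foci <- with_stage("read_foci", read_foci_table(config$foci))
  if (any(foci$space == "Talairach")) {
    n_tal <- sum(foci$space == "Talairach")
    foci <- with_stage("tal2mni", tal2mni(foci))
    log_lines <- c(log_lines, paste0("converted ", n_tal, " Talairach foci"))
  }
  mask <- with_stage("gm_mask",
    suppressMessages(load_gm_mask(config$gm_mask)))
  spec <- do.call(threshold_spec, config$threshold)
  log_lines <- c(log_lines, paste0(
    "voxel_alpha=", spec$voxel_alpha, " cluster_alpha=", spec$cluster_alpha,
    " n_permutations=", spec$n_permutations,
    " connectivity=", spec$connectivity,
    " min_cluster_mm3=", spec$min_cluster_mm3
  ))

  datasets <- with_stage("split_datasets", foci_datasets(foci))
  summary_tbl <- dataset_summary(foci)
  readr::write_tsv(summary_tbl, file.path(config$out_dir, "dataset_summary.tsv"),
    progress = FALSE)

  networks <- list()
  for (p in names(datasets)) {
    spec_p <- spec
    spec_p$seed <- config$seed + match(p, PARADIGM_LEVELS)
    networks[[p]] <- with_stage(paste0("ale_", p), {
      net <- threshold_network(datasets[[p]], mask, spec_p,
        bin_width = config$bin_width)
      write_volume_nifti(net$ale, net$grid,
        file.path(config$out_dir, paste0(p, "_network.nii.gz")))
      readr::write_tsv(tidy(net),
        file.path(config$out_dir, paste0(p, "_clusters.tsv")),
        progress = FALSE)
      log_lines <<- c(log_lines, paste0(
        p, ": ", net$total_voxels, " voxels, ", nrow(net$clusters),
        " clusters, critical ALE ", signif(net$critical_ale, 6),
        ", critical size ", net$critical_cluster_size
      ))
      net
    })
  }

  conj <- list()
  overlaps <- NULL
  if (length(networks) >= 2) {
    pairs <- utils::combn(names(networks), 2, simplify = FALSE)
    conj <- with_stage("conjunction", {
      out <- list()
      for (pr in pairs) {
        cj <- min_conjunction(networks[pr], spec$min_cluster_mm3)
        nm <- paste(pr, collapse = "_x_")
        write_volume_nifti(cj$values, cj$grid,
          file.path(config$out_dir, paste0("conj_", nm, ".nii.gz")))
        out[[nm]] <- cj
      }
      if (length(networks) == 3) {
        cj3 <- min_conjunction(networks, spec$min_cluster_mm3)
        write_volume_nifti(cj3$values, cj3$grid,
          file.path(config$out_dir, "conj_triple.nii.gz"))
        out$triple <- cj3
      }
      out
    })
    overlaps <- with_stage("overlap_stats", {
      tab <- dplyr::bind_rows(lapply(pairs, function(pr) {
        overlap_stats(networks[[pr[1]]], networks[[pr[2]]],
          spec$min_cluster_mm3)
      }))
      readr::write_tsv(tab, file.path(config$out_dir, "overlap_stats.tsv"),
        progress = FALSE)
      jsonlite::write_json(tab, file.path(config$out_dir, "overlap_stats.json"),
        auto_unbox = TRUE, digits = NA)
      tab
    })
  }

  matched <- NULL
  matched_overlaps <- NULL
  any_empty <- any(vapply(networks, function(n) n$total_voxels, 1L) == 0L)
  if (any_empty) {
    log_lines <- c(log_lines,
      "note: at least one network is empty; volume matching skipped")
  }
  if (config$volume_matched && length(networks) >= 2 && !any_empty) {
    matched <- with_stage("volume_match", {
      res <- match_all(networks)
      tab <- dplyr::bind_rows(lapply(res, tidy))
      readr::write_tsv(tab, file.path(config$out_dir, "volume_match.tsv"),
        progress = FALSE)
      for (r in res) {
        write_volume_nifti(r$matched$ale, r$matched$grid,
          file.path(config$out_dir,
            paste0(r$label, "_network_matched.nii.gz")))
      }
      res
    })
    matched_overlaps <- with_stage("volume_match_overlap", {
      mn <- lapply(matched, function(r) r$matched)
      pairs <- utils::combn(names(mn), 2, simplify = FALSE)
      tab <- dplyr::bind_rows(lapply(pairs, function(pr) {
        overlap_stats(mn[[pr[1]]], mn[[pr[2]]], spec$min_cluster_mm3)
      }))
      readr::write_tsv(tab,
        file.path(config$out_dir, "overlap_stats_matched.tsv"),
        progress = FALSE)
      tab
    })
  }

  region_tables <- NULL
  if (!is.null(config$templates) && length(networks) == 3) {
    templates <- with_stage("region_templates", {
      lapply(stats::setNames(names(config$templates), names(config$templates)),
        function(nm) {
          vol <- read_volume_nifti(config$templates[[nm]])
          if (!same_grid(vol$grid, mask$grid)) {
            if (!config$resample_templates) {
              stop_ale("template '", nm, "' grid does not match analysis grid")
            }
            return(region_template(
              resample_mask_nn(vol$values > 0, vol$grid, mask$grid),
              nm, mask$grid))
          }
          region_template(vol$values > 0, nm, mask$grid)
        })
    })
    region_tables <- with_stage("region_overlap", {
      full <- region_overlap_table(templates,
        mi = networks$imagery, ex = networks$execution,
        wm = networks$working_memory)
      out <- full
      if (config$volume_matched && !any_empty) {
        vm <- region_overlap_table(templates,
          mi = networks$imagery, ex = networks$execution,
          wm = networks$working_memory, volume_matched = TRUE)
        out <- dplyr::bind_rows(full, vm)
      }
      readr::write_tsv(out, file.path(config$out_dir, "region_overlap.tsv"),
        progress = FALSE)
      out
    })
  }

  summary <- list(
    seed = config$seed,
    networks = lapply(networks, function(n) glance(n)),
    overlaps = overlaps,
    matched_overlaps = matched_overlaps
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(
    networks = networks, conjunctions = conj, overlaps = overlaps,
    matched = matched, matched_overlaps = matched_overlaps,
    region_tables = region_tables, summary_table = summary_tbl
  ))
}
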