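#' Toy analysis mask for desk-scale simulation
#'
#' A spherical (default) or box mask centred in a small isotropic grid —
#' a stand-in analysis domain so the full pipeline runs in seconds.
#'
#' @param shape Grid dimensions (default `c(30, 30, 30)`).
#' @param voxel_size Voxel edge in mm (default 2).
#' @param type `"ball"` (inscribed sphere, default) or `"box"` (all
#'   voxels).
#' @return A [brain_mask()].
#' @export
toy_mask <- function(shape = c(30, 30, 30), voxel_size = 2,
                     type = c("ball", "box")) {
  type <- match.arg(type)
  grid <- voxel_grid(shape, voxel_size = voxel_size)
  if (type == "box") {
    return(brain_mask(grid, array(TRUE, dim = grid$shape)))
  }
  centre <- (shape + 1) / 2
  radius <- (min(shape) / 2 - 0.5) * voxel_size
  ijk <- as.matrix(expand.grid(
    i = seq_len(shape[1]), j = seq_len(shape[2]), k = seq_len(shape[3])
  ))
  d2 <- ((ijk[, 1] - centre[1])^2 + (ijk[, 2] - centre[2])^2 +
    (ijk[, 3] - centre[3])^2) * voxel_size^2
  brain_mask(grid, array(d2 <= radius^2, dim = shape))
}

#' Synthetic dataset configuration
#'
#' Defines the generative model for one paradigm's dataset: planted
#' ground-truth convergence loci that each experiment reports with some
#' probability (spatially jittered), plus uniform noise foci over the
#' in-mask voxel centres.  Defaults are desk-scale: 12 experiments of
#' 8-25 subjects reporting 5-15 noise foci each.
#'
#' @param mask A [brain_mask()] (the analysis domain).
#' @param n_experiments Number of experiments.
#' @param subjects_range Inclusive integer range for per-experiment
#'   subject counts.
#' @param noise_foci_range Inclusive integer range for per-experiment
#'   noise foci.
#' @param loci Optional matrix (k x 3) of ground-truth MNI coordinates.
#' @param reporting_probability Probability that an experiment reports
#'   each locus.
#' @param jitter_sd_mm Gaussian scatter (mm, per axis) of reported foci
#'   around their locus.
#' @param paradigm Paradigm label for the generated rows.
#' @param seed Integer seed; fixes the full output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(mask, n_experiments = 12, subjects_range = c(8, 25),
                       noise_foci_range = c(5, 15), loci = NULL,
                       reporting_probability = 0.8, jitter_sd_mm = 2,
                       paradigm = "imagery", seed = 1L) {
  stopifnot(
    inherits(mask, "brain_mask"),
    n_experiments >= 1,
    length(subjects_range) == 2, subjects_range[1] >= 1,
    length(noise_foci_range) == 2, noise_foci_range[1] >= 0,
    reporting_probability >= 0, reporting_probability <= 1,
    jitter_sd_mm >= 0
  )
  if (!is.null(loci)) loci <- matrix(as.numeric(loci), ncol = 3)
  structure(
    list(
      mask = mask, n_experiments = as.integer(n_experiments),
      subjects_range = as.integer(subjects_range),
      noise_foci_range = as.integer(noise_foci_range),
      loci = loci, reporting_probability = reporting_probability,
      jitter_sd_mm = jitter_sd_mm,
      paradigm = match.arg(paradigm, PARADIGM_LEVELS),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# snap points to the nearest in-mask voxel centre (used to clip jittered
# ground-truth foci back into the analysis domain)
snap_to_mask <- function(xyz, mask, centres) {
  idx <- world_to_voxel_idx(xyz, mask$grid)
  lin <- idx$ijk[, 1] + (idx$ijk[, 2] - 1L) * mask$grid$shape[1] +
    (idx$ijk[, 3] - 1L) * prod(mask$grid$shape[1:2])
  ok <- idx$inside
  ok[ok] <- mask$inside[lin[ok]]
  if (all(ok)) return(xyz)
  for (r in which(!ok)) {
    d2 <- (centres[, 1] - xyz[r, 1])^2 + (centres[, 2] - xyz[r, 2])^2 +
      (centres[, 3] - xyz[r, 3])^2
    xyz[r, ] <- centres[which.min(d2), ]
  }
  xyz
}

#' Generate a synthetic foci dataset
#'
#' Per experiment: a subject count drawn uniformly from
#' `subjects_range`; each ground-truth locus reported with probability
#' `reporting_probability` at the locus plus Gaussian jitter (clipped
#' back into the mask by snapping to the nearest in-mask voxel centre);
#' noise foci placed uniformly over in-mask voxel centres.  An experiment
#' that would end up with no foci receives one noise focus, keeping every
#' experiment non-empty.  Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A validated foci tibble (`ale_foci`) with experiment ids
#'   `sim<paradigm>001` ...; ground-truth foci carry jittered continuous
#'   coordinates, noise foci sit on voxel centres.
#' @export
generate_dataset <- function(config) {
  mask <- config$mask
  centres <- mask_centres(mask)
  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(config$n_experiments), function(e) {
      n_sub <- draw_int(1L, config$subjects_range)
      pts <- NULL
      if (!is.null(config$loci) && nrow(config$loci) > 0) {
        report <- stats::runif(nrow(config$loci)) < config$reporting_probability
        if (any(report)) {
          pts <- config$loci[report, , drop = FALSE] +
            matrix(stats::rnorm(3 * sum(report), sd = config$jitter_sd_mm),
              ncol = 3)
          pts <- snap_to_mask(pts, mask, centres)
        }
      }
      n_noise <- draw_int(1L, config$noise_foci_range)
      if (is.null(pts) && n_noise == 0L) n_noise <- 1L
      if (n_noise > 0L) {
        pts <- rbind(pts, centres[sample.int(nrow(centres), n_noise,
          replace = TRUE), , drop = FALSE])
      }
      tibble::tibble(
        study_id = sprintf("sim%s%03d", substr(config$paradigm, 1, 2), e),
        paradigm = config$paradigm,
        n_subjects = n_sub,
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        space = "MNI"
      )
    })
  })
  as_ale_foci(dplyr::bind_rows(rows))
}

# sample k well-separated in-mask voxel centres for ground-truth loci
sample_loci <- function(mask, k, min_dist_mm = 16) {
  centres <- mask_centres(mask)
  chosen <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(chosen) < k && tries < 20000L) {
    cand <- centres[sample.int(nrow(centres), 1L), , drop = FALSE]
    if (nrow(chosen) == 0 ||
      min(sqrt(rowSums((chosen - matrix(cand, nrow(chosen), 3,
        byrow = TRUE))^2))) >= min_dist_mm) {
      chosen <- rbind(chosen, cand)
    }
    tries <- tries + 1L
  }
  if (nrow(chosen) < k) {
    stop_ale("could not place ", k, " loci at least ", min_dist_mm,
      " mm apart in this mask")
  }
  chosen
}

#' Generate a three-paradigm trio with known shared structure
#'
#' Emulates the three-dataset design — execution, imagery, working
#' memory — with ground-truth convergence loci partially shared between
#' imagery and each of the other paradigms, so directional overlap
#' comparisons have a known expected ordering.  Experiment counts default
#' to a desk-scale echo of the real datasets' ordering (execution
#' smallest, working memory largest).
#'
#' @param seed Integer seed fixing loci, sharing and all datasets.
#' @param mask A [brain_mask()] (default [toy_mask()]).
#' @param n_loci Ground-truth loci in the imagery set (default 10).
#' @param shared_wm Fraction of imagery loci shared with working memory
#'   (default 0.6).
#' @param shared_ex Fraction of imagery loci shared with execution
#'   (default 0.3).
#' @param n_experiments Named integer vector of experiment counts.
#' @param reporting_probability,jitter_sd_mm,subjects_range,
#'   noise_foci_range Passed to each paradigm's [sim_config()].
#' @param min_locus_dist_mm Minimum pairwise distance between planted
#'   loci in mm (keeps convergence clusters separable).
#' @return Named list of three foci tibbles (`execution`, `imagery`,
#'   `working_memory`) with a `ground_truth` attribute listing each
#'   paradigm's loci.
#' @export
generate_paradigm_trio <- function(seed = 1L, mask = toy_mask(),
                                   n_loci = 10, shared_wm = 0.6,
                                   shared_ex = 0.3,
                                   n_experiments = c(
                                     execution = 7L, imagery = 13L,
                                     working_memory = 20L
                                   ),
                                   reporting_probability = 0.8,
                                   jitter_sd_mm = 2,
                                   subjects_range = c(8, 25),
                                   noise_foci_range = c(3, 8),
                                   min_locus_dist_mm = 14) {
  stopifnot(shared_wm >= 0, shared_wm <= 1, shared_ex >= 0, shared_ex <= 1)
  n_wm <- round(shared_wm * n_loci)
  n_ex <- round(shared_ex * n_loci)
  loci <- withr::with_seed(seed, {
    all_loci <- sample_loci(mask, n_loci + (n_loci - n_wm) + (n_loci - n_ex),
      min_dist_mm = min_locus_dist_mm)
    mi <- all_loci[seq_len(n_loci), , drop = FALSE]
    extra <- all_loci[-seq_len(n_loci), , drop = FALSE]
    wm <- rbind(
      mi[seq_len(n_wm), , drop = FALSE],
      extra[seq_len(n_loci - n_wm), , drop = FALSE]
    )
    # share the tail slice of the imagery loci so the wm- and ex-shared
    # sets are not nested inside one another
    ex_shared <- if (n_ex > 0) {
      mi[seq(n_loci - n_ex + 1, n_loci), , drop = FALSE]
    } else {
      mi[0, , drop = FALSE]
    }
    ex <- rbind(
      ex_shared,
      extra[seq(n_loci - n_wm + 1, length.out = n_loci - n_ex), , drop = FALSE]
    )
    list(imagery = mi, working_memory = wm, execution = ex)
  })
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  datasets <- list(
    execution = generate_dataset(sim_config(
      mask, n_experiments[["execution"]], subjects_range, noise_foci_range,
      loci$execution, reporting_probability, jitter_sd_mm,
      paradigm = "execution", seed = sub_seeds[1]
    )),
    imagery = generate_dataset(sim_config(
      mask, n_experiments[["imagery"]], subjects_range, noise_foci_range,
      loci$imagery, reporting_probability, jitter_sd_mm,
      paradigm = "imagery", seed = sub_seeds[2]
    )),
    working_memory = generate_dataset(sim_config(
      mask, n_experiments[["working_memory"]], subjects_range,
      noise_foci_range, loci$working_memory, reporting_probability,
      jitter_sd_mm, paradigm = "working_memory", seed = sub_seeds[3]
    ))
  )
  attr(datasets, "ground_truth") <- loci
  datasets
}
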