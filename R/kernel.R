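#' Empirical spatial-uncertainty constants for the ALE kernel
#'
#' The revised ALE algorithm models each reported focus as a 3-D Gaussian
#' whose width reflects two empirically estimated sources of spatial
#' uncertainty: between-template variability (from normalising the same
#' brains to different templates) and between-subject variability (from
#' localising the same task activation in different subjects).  Both are
#' expressed as mean Euclidean displacements (ED, mm); the subject
#' component shrinks with the square root of the sample size, so larger
#' experiments get tighter kernels.
#'
#' @param template_ed Between-template Euclidean displacement in mm
#'   (default 5.7).
#' @param subject_ed Between-subject Euclidean displacement in mm
#'   (default 11.6).
#' @return Named list of constants, accepted by [kernel_sigma()].
#' @export
ale_kernel_constants <- function(template_ed = 5.7, subject_ed = 11.6) {
  stopifnot(template_ed > 0, subject_ed > 0)
  list(template_ed = template_ed, subject_ed = subject_ed)
}

# mean Euclidean displacement of a 3-D isotropic Gaussian -> FWHM (mm):
# ED = 2 * sigma * sqrt(2/pi), FWHM = sigma * sqrt(8 ln 2)
ed_to_fwhm <- function(ed) ed / (2 * sqrt(2 / pi)) * sqrt(8 * log(2))

#' Sample-size-dependent Gaussian kernel width
#'
#' Per-axis standard deviation (and FWHM) of the modelled-activation
#' Gaussian for an experiment of `n_subjects` participants.  The
#' between-template and between-subject FWHM components add in quadrature,
#' the subject component scaled by `1/sqrt(n)`; sigma therefore decreases
#' monotonically in `n_subjects` towards the between-template floor.
#'
#' @param n_subjects Positive integer vector of sample sizes.
#' @param constants Uncertainty model from [ale_kernel_constants()].
#' @return Tibble with columns `n_subjects`, `sigma_mm`, `fwhm_mm`.
#' @export
#' @examples
#' kernel_sigma(c(10, 20, 50))
kernel_sigma <- function(n_subjects, constants = ale_kernel_constants()) {
  if (any(!is.finite(n_subjects)) || any(n_subjects < 1)) {
    stop_ale("n_subjects must be >= 1")
  }
  fwhm_t <- ed_to_fwhm(constants$template_ed)
  fwhm_s <- ed_to_fwhm(constants$subject_ed) / sqrt(n_subjects)
  fwhm <- sqrt(fwhm_t^2 + fwhm_s^2)
  tibble::tibble(
    n_subjects = as.integer(n_subjects),
    sigma_mm = fwhm / sqrt(8 * log(2)),
    fwhm_mm = fwhm
  )
}

.kernel_cache <- new.env(parent = emptyenv())

# discretised 3-D Gaussian probability-mass kernel on the grid spacing,
# truncated at `truncate` sigma; separable product of 1-D masses
ale_kernel_array <- function(n_subjects, grid, truncate = 5,
                             constants = ale_kernel_constants()) {
  key <- paste(n_subjects, paste(signif(grid$voxel_size, 10), collapse = ","),
    truncate, constants$template_ed, constants$subject_ed,
    sep = "|"
  )
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  sigma <- kernel_sigma(n_subjects, constants)$sigma_mm
  axes <- lapply(grid$voxel_size, function(vs) {
    r <- max(1L, floor(truncate * sigma / vs))
    d <- (-r:r) * vs
    stats::dnorm(d, sd = sigma) * vs
  })
  kern <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  .kernel_cache[[key]] <- kern
  kern
}
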