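# cache for parsed transform matrices
.lancaster_cache <- new.env(parent = emptyenv())

#' Lancaster coordinate transform matrices
#'
#' Affine matrices mapping between ICBM/MNI and Talairach coordinates,
#' fitted empirically per normalisation pipeline ("spm", "fsl", or the
#' "pooled" fit).  The published fits map ICBM to Talairach; the
#' Talairach-to-MNI direction is the matrix inverse.  Constants are
#' shipped as a versioned plain-text table under `inst/extdata`.
#'
#' @param variant One of `"spm"`, `"fsl"`, `"pooled"`.
#' @param direction `"tal2mni"` (default) or `"mni2tal"`.
#' @return A 4x4 affine matrix.
#' @export
lancaster_matrix <- function(variant = c("spm", "fsl", "pooled"),
                             direction = c("tal2mni", "mni2tal")) {
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  key <- "icbm2tal"
  if (is.null(.lancaster_cache[[key]])) {
    path <- system.file("extdata", "lancaster_icbm2tal.tsv",
      package = "aleoverlap", mustWork = TRUE
    )
    tab <- utils::read.delim(path)
    mats <- lapply(split(tab, tab$variant), function(d) {
      d <- d[order(d$row), ]
      rbind(as.matrix(d[, c("c1", "c2", "c3", "c4")]), c(0, 0, 0, 1))
    })
    .lancaster_cache[[key]] <- lapply(mats, unname)
  }
  m <- .lancaster_cache[[key]][[variant]]
  if (direction == "mni2tal") m else solve(m)
}

tal2mni_xyz <- function(xyz, variant = "spm") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  m <- lancaster_matrix(variant, "tal2mni")
  hom <- t(cbind(xyz, rep(1, nrow(xyz))))
  t(m %*% hom)[, 1:3, drop = FALSE]
}

#' Convert Talairach foci to MNI space
#'
#' Applies the Lancaster affine (inverse of the fitted ICBM-to-Talairach
#' transform) to every row tagged `space == "Talairach"` and retags it
#' `"MNI"`.  Rows already in MNI are returned unchanged; if no row needs
#' conversion the call is a no-op with a warning, not an error.
#'
#' @param data Foci tibble (or any data frame with `x`, `y`, `z`, `space`).
#' @param variant Lancaster fit to use; `"spm"` by default, matching
#'   SPM-normalised source literatures.
#' @return The tibble with converted coordinates, all rows MNI-tagged.
#' @export
#' @examples
#' foci <- tibble::tibble(
#'   study_id = "a2000", paradigm = "imagery", n_subjects = 12L,
#'   x = 10, y = -20, z = 40, space = "Talairach"
#' )
#' tal2mni(foci)
tal2mni <- function(data, variant = c("spm", "fsl", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(all(c("x", "y", "z", "space") %in% names(data)))
  out <- tibble::as_tibble(data)
  is_tal <- out$space == "Talairach"
  if (!any(is_tal)) {
    warning("no Talairach rows to convert; returning input unchanged")
    return(out)
  }
  xyz <- tal2mni_xyz(cbind(out$x, out$y, out$z)[is_tal, , drop = FALSE], variant)
  out$x[is_tal] <- xyz[, 1]
  out$y[is_tal] <- xyz[, 2]
  out$z[is_tal] <- xyz[, 3]
  out$space[is_tal] <- "MNI"
  out
}
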