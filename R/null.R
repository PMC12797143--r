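#' Analytic ALE null distribution by non-linear histogram integration
#'
#' Under spatial independence, the null ALE score at a voxel is the union
#' `1 - prod(1 - M_i)` of one MA value drawn independently from each
#' experiment's within-mask MA-value distribution.  This function builds
#' that distribution as a discretised histogram.  When the exact joint
#' support is small (toy problems) the union is combined exactly over all
#' distinct value combinations and binned once at the end; otherwise the
#' standard sequential binned integration is used, with scores floored
#' into bins so the survival function errs conservative.
#'
#' @param ma_maps List of `ma_map` objects (see [compute_ma_map()]), or
#'   the `ma_tables` element of an internal streaming result.
#' @param mask A [brain_mask()] restricting the null to the analysis
#'   domain (grey matter).
#' @param bin_width Histogram bin width in ALE-score units (default
#'   `1e-5`).
#' @param max_exact Largest exact joint-support size before switching to
#'   sequential binned integration (default `2e5`).
#' @return Object of class `ale_null`: `bin_width`, `prob` (probability
#'   per bin, bin `b` covering scores in `[(b-1)w, bw)`), `surv`
#'   (`surv[b] = P(score >= (b-1) w)`), `method` (`"exact"` or
#'   `"binned"`), `n_experiments`.
#' @seealso [ale_p_values()], [ale_critical()]
#' @export
build_null <- function(ma_maps, mask, bin_width = 1e-5, max_exact = 2e5) {
  if (bin_width <= 0) stop_ale("bin_width must be positive")
  if (!length(ma_maps)) stop_ale("no MA maps supplied")
  tables <- lapply(ma_maps, function(m) {
    if (inherits(m, "ma_map")) {
      if (!same_grid(m$grid, mask$grid)) stop_ale("MA map grid does not match mask")
      ma_value_table(m$values[mask$inside])
    } else {
      m
    }
  })
  null_from_tables(tables, bin_width, max_exact)
}

null_from_tables <- function(tables, bin_width, max_exact = 2e5) {
  sizes <- vapply(tables, function(t) length(t$values), 1)
  exact <- prod(sizes) <= max_exact
  if (exact) {
    # exact combine over all value combinations, bin once at the end
    vals <- 1 - tables[[1]]$values
    probs <- tables[[1]]$probs
    for (t in tables[-1]) {
      vals <- as.vector(outer(vals, 1 - t$values))
      probs <- as.vector(outer(probs, t$probs))
    }
    scores <- 1 - vals
    bins <- floor(scores / bin_width + 1e-12)
    nb <- max(bins) + 1L
    prob <- as.numeric(rowsum(probs, bins, reorder = TRUE))
    idx <- sort(unique(bins)) + 1L
    dense <- numeric(nb)
    dense[idx] <- prob
  } else {
    # sequential integration on the bin grid; bin values are lower edges
    # so every floor rounds scores down (conservative tail)
    max_ale <- 1 - prod(vapply(tables, function(t) 1 - max(t$values), 1))
    nb <- floor(max_ale / bin_width + 1e-12) + 1L
    qs <- lapply(tables, function(t) {
      b <- floor(t$values / bin_width + 1e-12)
      p <- as.numeric(rowsum(t$probs, b, reorder = TRUE))
      list(bins = sort(unique(b)), probs = p)
    })
    dense <- numeric(nb)
    first <- qs[[1]]
    dense[first$bins + 1L] <- first$probs
    for (q in qs[-1]) {
      dense <- .null_combine_cpp(dense, q$bins, q$probs, bin_width)
    }
  }
  total <- sum(dense)
  if (abs(total - 1) > 1e-9) {
    stop_ale("null histogram probabilities do not sum to 1 (", format(total), ")")
  }
  dense <- dense / total
  structure(
    list(
      bin_width = bin_width,
      prob = dense,
      surv = rev(cumsum(rev(dense))),
      method = if (exact) "exact" else "binned",
      n_experiments = length(tables)
    ),
    class = "ale_null"
  )
}

#' @export
print.ale_null <- function(x, ...) {
  cat(
    "<ale_null> ", x$n_experiments, " experiments, ", length(x$prob),
    " bins of width ", format(x$bin_width), " (", x$method, ")\n",
    sep = ""
  )
  invisible(x)
}

null_bin <- function(score, null) {
  pmin(floor(score / null$bin_width + 1e-12), length(null$prob) - 1L)
}

#' Tail probability of observed ALE scores under the null
#'
#' `p = P(null ALE >= observed)`, evaluated by flooring the observed score
#' into its histogram bin and reading the survival function, which is
#' conservative.  Scores above the null's top bin get the smallest
#' positive tail probability, with a warning.
#'
#' @param ale An `ale_map` (or bare numeric array on the mask's grid).
#' @param null An `ale_null` built from the same experiment set.
#' @param mask A [brain_mask()]; p-values are `NA` outside it.
#' @return Numeric array of p-values in `(0, 1]`, `NA` off-mask.
#' @export
ale_p_values <- function(ale, null, mask) {
  values <- if (inherits(ale, "ale_map")) ale$values else ale
  values <- array(as.numeric(values), dim = mask$grid$shape)
  p <- array(NA_real_, dim = mask$grid$shape)
  score <- values[mask$inside]
  top <- (length(null$prob) - 1) * null$bin_width
  over <- score >= top + null$bin_width
  if (any(over)) {
    warning(sum(over), " ALE score(s) above the null's top bin; assigned ",
      "the smallest positive tail probability")
  }
  bins <- null_bin(score, null)
  pv <- null$surv[bins + 1L]
  min_pos <- min(null$surv[null$surv > 0])
  pv[over | pv <= 0] <- min_pos
  p[mask$inside] <- pv
  p
}

#' Critical ALE score for a voxel-level alpha
#'
#' Smallest score threshold `t` such that a voxel with ALE `>= t` has a
#' null tail probability below `alpha` under the (conservative, floored)
#' survival function.
#'
#' @param null An `ale_null`.
#' @param alpha Voxel-level probability threshold (e.g. 0.001).
#' @return Scalar ALE score; `Inf` if no bin reaches below `alpha`.
#' @export
ale_critical <- function(null, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  # degenerate threshold: alpha = 1 disables voxel-level selection
  if (alpha >= 1) return(-Inf)
  b <- which(null$surv < alpha)
  if (!length(b)) return(Inf)
  (b[1] - 1L) * null$bin_width
}
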