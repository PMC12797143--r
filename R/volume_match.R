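#' Match a network's volume to a target voxel count
#'
#' Iteratively raising the retention threshold over the network's ALE
#' values shrinks its volume; the threshold whose surviving voxel count is
#' closest to `target_voxels` is applied.  Candidate thresholds are the
#' sorted distinct retained values (plus "above the maximum", giving an
#' empty network), which reproduces or beats any fixed-step sweep.  Ties
#' in `|count - target|` resolve toward the smaller volume.  When all
#' retained values are distinct the match is exact.
#'
#' @param net An `ale_network`.
#' @param target_voxels Positive integer target volume.
#' @return Object of class `volume_match`: `label`, `target_voxels`,
#'   `achieved_voxels`, `applied_threshold`, `matched` (the reduced
#'   `ale_network`).
#' @export
match_volume <- function(net, target_voxels) {
  if (!is_scalar_number(target_voxels) || target_voxels < 1) {
    stop_ale("target_voxels must be a positive integer")
  }
  target_voxels <- as.integer(target_voxels)
  if (net$total_voxels < 1) stop_ale("network is empty")
  vals <- net$ale[net$significant]
  if (target_voxels >= net$total_voxels) {
    if (target_voxels > net$total_voxels) {
      warning("target exceeds network volume; returning the network unchanged")
    }
    return(new_volume_match(net, target_voxels, net$total_voxels, min(vals), net))
  }
  cand <- sort(unique(vals), decreasing = TRUE)
  counts <- cumsum(tabulate(match(vals, cand), nbins = length(cand)))
  # prepend the empty-network candidate (threshold above the maximum)
  cand <- c(Inf, cand)
  counts <- c(0L, counts)
  err <- abs(counts - target_voxels)
  best <- which(err == min(err))
  best <- best[which.min(counts[best])] # tie -> smaller volume
  thr <- cand[best]
  kept <- array(net$ale >= thr & net$significant, dim = net$grid$shape)
  values <- array(0, dim = net$grid$shape)
  values[kept] <- net$ale[kept]
  matched <- network_from_values(values, net$grid, net$paradigm, net$spec)
  new_volume_match(net, target_voxels, counts[best], thr, matched)
}

new_volume_match <- function(net, target, achieved, threshold, matched) {
  structure(
    list(
      label = net$paradigm, target_voxels = as.integer(target),
      achieved_voxels = as.integer(achieved),
      applied_threshold = threshold, matched = matched
    ),
    class = "volume_match"
  )
}

#' @export
print.volume_match <- function(x, ...) {
  cat(
    "<volume_match> ", x$label, ": ", x$achieved_voxels, " voxels (target ",
    x$target_voxels, ") at threshold ", signif(x$applied_threshold, 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' Volume-match a set of networks to the smallest
#'
#' The smallest network's volume is the target; every larger network is
#' reduced with [match_volume()]; the smallest is passed through
#' unchanged.
#'
#' @param nets Named or unnamed list of two or more `ale_network` objects.
#' @return List of `volume_match` results in input order, named by
#'   paradigm label.
#' @export
match_all <- function(nets) {
  if (length(nets) < 2) stop_ale("match_all needs at least two networks")
  target <- min(vapply(nets, function(n) n$total_voxels, 1L))
  out <- lapply(nets, match_volume, target_voxels = target)
  names(out) <- vapply(out, function(r) r$label, "")
  out
}
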