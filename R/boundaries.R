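# Species-boundary threshold optimization.
#
# For a candidate threshold t, a "false positive" is a conspecific sequence
# pair whose distance exceeds t (the pair would be split into two species),
# and a "false negative" is a heterospecific pair whose distance is <= t
# (the pair would be lumped).  Scanning t across a grid yields two
# cumulative error curves whose sum is minimized at the optimal boundary.

#' False-positive / false-negative error curves across a threshold grid
#'
#' Counts, for every threshold `t` in `seq(0, max_threshold, grid_step)`,
#' the conspecific pairs with `d > t` (false positives) and the
#' heterospecific pairs with `d <= t` (false negatives; with
#' `merge_at_threshold = FALSE` the comparison is strict `d < t`).  Pairs
#' with undefined distances are excluded from both counts with a message.
#'
#' @param mat a `k2p_dist` from [distance_matrix()]
#' @param dataset the matching [marker_dataset()]
#' @param grid_step threshold grid step on the K2P scale (default 0.0001,
#'   i.e. 0.01%, fine enough to resolve boundaries quoted to two decimals
#'   of a percent)
#' @param max_threshold top of the scanned grid (default 0.15)
#' @param merge_at_threshold logical; if `TRUE` (default) a heterospecific
#'   pair exactly at the threshold counts as lumped (`d <= t`)
#' @return object of class `threshold_scan`: list with `scan` (data frame of
#'   `threshold`, `fp`, `fn`, `total`), `optimal`, `ties` (all thresholds
#'   attaining the minimum), `n_conspecific`, `n_heterospecific`,
#'   `n_undefined`
#' @export
error_curves <- function(mat, dataset, grid_step = 1e-4, max_threshold = 0.15,
                         merge_at_threshold = TRUE) {
  stopifnot(inherits(mat, "k2p_dist"), inherits(dataset, "marker_dataset"))
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > max_threshold) {
    stop("empty or invalid threshold grid")
  }
  pt <- .conspecific_pairs(mat, dataset)
  n_undef <- sum(pt$undefined)
  if (n_undef) message(sprintf("error_curves: excluded %d undefined pair(s)", n_undef))
  pt <- pt[!pt$undefined, , drop = FALSE]
  dc <- sort(pt$d[pt$sp1 == pt$sp2])
  dh <- sort(pt$d[pt$sp1 != pt$sp2])
  if (!length(dc) || !length(dh)) {
    stop("need at least one conspecific and one heterospecific pair with defined distance")
  }
  thresholds <- (0:floor(max_threshold / grid_step + 1e-9)) * grid_step
  # counts of d <= t via binary search on the sorted pair distances
  fp <- length(dc) - findInterval(thresholds, dc)
  fn <- if (merge_at_threshold) {
    findInterval(thresholds, dh)
  } else {
    findInterval(thresholds, dh, left.open = TRUE)
  }
  total <- fp + fn
  ties <- thresholds[total == min(total)]
  structure(list(scan = data.frame(threshold = thresholds, fp = fp, fn = fn,
                                   total = total),
                 optimal = ties[1L],
                 ties = ties,
                 n_conspecific = length(dc),
                 n_heterospecific = length(dh),
                 n_undefined = n_undef,
                 merge_at_threshold = merge_at_threshold),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  i <- which(x$scan$threshold == x$optimal)
  cat(sprintf(paste0("threshold_scan: %d thresholds in [0, %g]; optimal boundary %.4f ",
                     "(%.2f%%) with FP=%d, FN=%d%s\n"),
              nrow(x$scan), max(x$scan$threshold), x$optimal, 100 * x$optimal,
              x$scan$fp[i], x$scan$fn[i],
              if (length(x$ties) > 1L) sprintf("; %d tied thresholds", length(x$ties)) else ""))
  invisible(x)
}

#' Optimal species-boundary threshold of a scan
#'
#' The threshold minimizing the sum of false positives and false negatives;
#' ties are broken toward the smallest threshold (the full tie set is kept
#' in the scan object).
#'
#' @param scan a [error_curves()] result
#' @return the optimal threshold (K2P scale)
#' @export
optimal_threshold <- function(scan) {
  stopifnot(inherits(scan, "threshold_scan"))
  scan$ties[1L]
}

#' Write a threshold scan as TSV
#'
#' @param scan a [error_curves()] result
#' @param path output path
#' @return invisibly, `path`
#' @export
write_threshold_scan <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  write_tsv(scan$scan, path)
  invisible(path)
}
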