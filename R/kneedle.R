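#' Knee/elbow detection on a curve (kneedle)
#'
#' Offline knee detection: min-max normalize both axes, flip the curve so it
#' is increasing and concave, form the difference curve `y - x`, and declare
#' a knee at a local maximum of the difference curve whose value stays above
#' a sensitivity-adjusted threshold until the curve next rises.  No smoothing
#' is applied: the curves used here (aggregation heights over a handful of
#' cluster counts) are short and exact.
#'
#' @param y Curve values.
#' @param x Curve positions (default `seq_along(y)`).
#' @param sensitivity Threshold multiplier S; larger values demand a more
#'   pronounced knee.
#' @param curve `"convex"` or `"concave"` shape of the input.
#' @param direction `"decreasing"` or `"increasing"` trend of the input.
#' @return The x-position of the knee, or `NA` if no knee passes the
#'   threshold.
#' @examples
#' kneedle(1 / (1:10))  # convex decreasing
#' @export
kneedle <- function(y, x = seq_along(y), sensitivity = 1,
                    curve = c("convex", "concave"),
                    direction = c("decreasing", "increasing")) {
  curve <- match.arg(curve)
  direction <- match.arg(direction)
  n <- length(y)
  if (n < 3) stop("need at least 3 points")
  if (length(x) != n) stop("x and y must have equal length")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  dy <- diff(y)
  if (direction == "decreasing" && any(dy > 0))
    stop("curve is not monotone decreasing")
  if (direction == "increasing" && any(dy < 0))
    stop("curve is not monotone increasing")
  xn <- (x - min(x)) / (max(x) - min(x))
  if (max(y) == min(y)) return(NA_real_)
  yn <- (y - min(y)) / (max(y) - min(y))
  # transform to an increasing concave curve
  flipped <- FALSE
  if (curve == "convex") yn <- 1 - yn
  if ((curve == "convex") == (direction == "increasing")) {
    # transformed trend is still decreasing: reverse the order
    yn <- rev(yn)
    flipped <- TRUE
  }
  d <- yn - xn
  # local maxima of the difference curve
  lm_idx <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) d[i] >= d[i - 1] else d[i] > d[i + 1]
    right <- if (i < n) d[i] >= d[i + 1] else d[i] > d[i - 1]
    i > 1 && i < n && left && right
  }, logical(1)))
  if (!length(lm_idx)) return(NA_real_)
  threshold_drop <- sensitivity * mean(diff(xn))
  for (i in lm_idx) {
    thr <- d[i] - threshold_drop
    j <- i + 1
    while (j <= n && d[j] <= d[i]) {
      if (d[j] < thr) {
        knee <- if (flipped) x[n + 1 - i] else x[i]
        return(knee)
      }
      j <- j + 1
    }
    if (j > n && d[n] < thr) {
      knee <- if (flipped) x[n + 1 - i] else x[i]
      return(knee)
    }
  }
  NA_real_
}

#' Suggest a number of variable clusters from the aggregation heights
#'
#' Runs [kneedle()] on the curve of aggregation heights versus number of
#' clusters (a decreasing, typically convex curve) and returns the knee as
#' the suggested number of clusters.
#'
#' @param tree A [varclust()] object.
#' @param sensitivity Kneedle sensitivity.
#' @return Suggested number of clusters, or `NA` when the curve has no knee.
#' @export
suggest_k <- function(tree, sensitivity = 1) {
  ah <- aggregation_heights(tree)
  # heights are not always strictly monotone (small inversions are possible);
  # the knee is sought on the isotone envelope
  h <- rev(cummax(rev(ah$height)))
  kneedle(h, ah$k, sensitivity = sensitivity,
          curve = "convex", direction = "decreasing")
}
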