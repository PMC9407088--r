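# Pixel-level fusion of registered slices: direct average, gradual-in /
# gradual-out weighted average, and the symmetric mask-weighted mean.

fused_slice <- function(data, support) {
  structure(list(data = data, support = support), class = "fused_slice")
}

#' Direct-average fusion of two masked slices
#'
#' Pixels covered by only one image keep that image's value; pixels in
#' the overlap take the plain average `(f1 + f2) / 2`; uncovered pixels
#' are 0 with support 0.
#'
#' @param f1,f2 2D matrices of equal shape.
#' @param mask1,mask2 Coverage masks (non-zero = covered); default full.
#' @return A `fused_slice`: `data` and `support` (count of contributing
#'   images per pixel).
#' @export
direct_average <- function(f1, f2,
                           mask1 = matrix(1, nrow(f1), ncol(f1)),
                           mask2 = matrix(1, nrow(f2), ncol(f2))) {
  if (!all(dim(f1) == dim(f2))) stop("slice shapes differ")
  m1 <- mask1 > 0; m2 <- mask2 > 0
  data <- matrix(0, nrow(f1), ncol(f1))
  both <- m1 & m2
  data[m1 & !m2] <- f1[m1 & !m2]
  data[m2 & !m1] <- f2[m2 & !m1]
  data[both] <- (f1[both] + f2[both]) / 2
  fused_slice(data, m1 + m2)
}

#' Gradual-in/gradual-out weighted-average fusion
#'
#' Non-overlap pixels behave as in [direct_average()]. In the overlap the
#' weights ramp linearly along the first (x) axis:
#' `w1 = (x2 - x) / (x2 - x1)` and `w2 = 1 - w1`, where `x1`, `x2` are
#' the overlap's minimum and maximum x coordinate, so the first image
#' owns the low-x side and the second the high-x side and
#' `w1 + w2 = 1` with both in [0, 1]. A single-column overlap uses
#' `w1 = w2 = 0.5`.
#'
#' @inheritParams direct_average
#' @return A `fused_slice`.
#' @export
weighted_average <- function(f1, f2,
                             mask1 = matrix(1, nrow(f1), ncol(f1)),
                             mask2 = matrix(1, nrow(f2), ncol(f2))) {
  if (!all(dim(f1) == dim(f2))) stop("slice shapes differ")
  m1 <- mask1 > 0; m2 <- mask2 > 0
  data <- matrix(0, nrow(f1), ncol(f1))
  both <- m1 & m2
  data[m1 & !m2] <- f1[m1 & !m2]
  data[m2 & !m1] <- f2[m2 & !m1]
  if (any(both)) {
    xs <- (row(f1) - 1L)[both]
    x1 <- min(xs); x2 <- max(xs)
    w1 <- if (x1 == x2) rep(0.5, length(xs)) else (x2 - xs) / (x2 - x1)
    data[both] <- w1 * f1[both] + (1 - w1) * f2[both]
  }
  fused_slice(data, m1 + m2)
}

#' Fuse a registered slice sequence into one slice
#'
#' Method `"weighted"` folds the non-excluded frames in temporal order
#' through [weighted_average()] (the literal sequential reading of the
#' gradual-in/gradual-out rule); `"direct"` folds through
#' [direct_average()]; `"mean"` computes the mask-weighted per-pixel mean
#' of all frames in one symmetric pass and is the statistically preferred
#' variant for near-fully-overlapping registered slices. Pixels no frame
#' covered fall back to the reference frame's value where its mask is 1,
#' else 0.
#'
#' @param reg A `registered_sequence` from [register_sequence()].
#' @param method `"weighted"`, `"direct"` or `"mean"`.
#' @return A `fused_slice`; `support` counts contributing frames (for the
#'   fold methods) or sums mask weights (for `"mean"`).
#' @export
fuse_sequence <- function(reg, method = c("weighted", "direct", "mean")) {
  stopifnot(inherits(reg, "registered_sequence"))
  method <- match.arg(method)
  use <- setdiff(seq_along(reg$warped), reg$excluded)
  if (length(use) == 0) stop("no usable frames to fuse")
  frames <- reg$warped[use]
  masks <- reg$masks[use]
  shape <- dim(frames[[1L]])

  if (method == "mean") {
    num <- matrix(0, shape[1], shape[2])
    den <- matrix(0, shape[1], shape[2])
    for (i in seq_along(frames)) {
      num <- num + frames[[i]] * masks[[i]]
      den <- den + masks[[i]]
    }
    data <- matrix(0, shape[1], shape[2])
    cov <- den > 0
    data[cov] <- num[cov] / den[cov]
    out <- fused_slice(data, den)
  } else {
    combine <- if (method == "weighted") weighted_average else direct_average
    data <- frames[[1L]]
    mask <- masks[[1L]] > 0
    support <- (masks[[1L]] > 0) + 0
    if (length(frames) > 1) for (i in 2:length(frames)) {
      fs <- combine(data, frames[[i]], mask, masks[[i]])
      data <- fs$data
      support <- support + (masks[[i]] > 0)
      mask <- mask | (masks[[i]] > 0)
    }
    out <- fused_slice(data, support)
  }
  # uncovered pixels fall back to the reference frame
  uncov <- out$support == 0
  if (any(uncov)) {
    refv <- reg$warped[[1L]]; refm <- reg$masks[[1L]] > 0
    out$data[uncov & refm] <- refv[uncov & refm]
  }
  out
}
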