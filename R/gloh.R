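# GLOH (gradient location and orientation histogram) descriptor on a
# log-polar spatial grid: 1 central disc + 2 annuli x 8 sectors = 17
# spatial bins, each holding an 8-bin orientation histogram -> 136 values.

#' Compute the 136-dimensional GLOH descriptor of one keypoint
#'
#' Samples gradients of the keypoint's Gaussian-pyramid level over a
#' log-polar grid centred on the keypoint and rotated so the dominant
#' orientation maps to angle zero. Ring radii are `{6, 11, 15}` pixels
#' scaled by `sigma / base_sigma` (making the descriptor scale-covariant):
#' the central disc (r <= 6u) is one undivided bin, and the middle
#' (6u-11u) and outer (11u-15u) annuli are split into 8 sectors
#' counter-clockwise from angle 0. Per spatial bin an 8-bin histogram of
#' gradient orientation relative to the keypoint orientation is
#' accumulated, magnitude-weighted, with linear soft-assignment between
#' adjacent sectors and adjacent orientation bins. Bins are concatenated
#' centre first, then middle ring, then outer ring; the vector is
#' L2-normalised, clipped at 0.2 and re-normalised.
#'
#' @param gp The `gaussian_pyramid` the keypoint came from.
#' @param kp A keypoint (one row of [detect_features()] output, or an
#'   `oriented_keypoint`).
#' @param radii The three ring radii in pixels at unit scale.
#' @return Numeric vector of length 136 with attribute `flagged = TRUE`
#'   when the window carried no gradient energy (all-zero vector).
#' @export
compute_descriptor <- function(gp, kp, radii = c(6, 11, 15)) {
  stopifnot(inherits(gp, "gaussian_pyramid"), length(radii) == 3)
  G <- gp$octaves[[kp$octave + 1L]]
  w <- dim(G)[1]; h <- dim(G)[2]; L <- dim(G)[3]
  u <- kp$sigma_oct / gp$base_sigma
  r1 <- radii[1] * u; r2 <- radii[2] * u; r3 <- radii[3] * u
  lg <- min(max(as.integer(round(kp$level_interp)) + 1L, 1L), L)
  rad <- as.integer(ceiling(r3))
  ci <- as.integer(round(kp$x_oct)) + 1L
  cj <- as.integer(round(kp$y_oct)) + 1L
  xi <- max(2L, ci - rad):min(w - 1L, ci + rad)
  yj <- max(2L, cj - rad):min(h - 1L, cj + rad)

  vec <- numeric(136)
  if (length(xi) < 1 || length(yj) < 1) {
    attr(vec, "flagged") <- TRUE
    return(vec)
  }
  gx <- (G[xi + 1L, yj, lg] - G[xi - 1L, yj, lg]) / 2
  gy <- (G[xi, yj + 1L, lg] - G[xi, yj - 1L, lg]) / 2
  mag <- c(sqrt(gx^2 + gy^2))
  px <- matrix(xi - 1L - kp$x_oct, length(xi), length(yj))
  py <- matrix(yj - 1L - kp$y_oct, length(xi), length(yj), byrow = TRUE)
  rho <- c(sqrt(px^2 + py^2))
  keep <- rho <= r3 & mag > 0
  if (!any(keep)) {
    attr(vec, "flagged") <- TRUE
    return(vec)
  }
  mag <- mag[keep]; rho <- rho[keep]
  phi <- wrap_deg(atan2(c(py)[keep], c(px)[keep]) * 180 / pi - kp$orientation)
  theta <- wrap_deg(atan2(c(gy)[keep], c(gx)[keep]) * 180 / pi -
                      kp$orientation)
  ring <- ifelse(rho <= r1, 0L, ifelse(rho <= r2, 1L, 2L))

  # orientation soft-assignment: 8 bins of 45 deg, centres at 45k + 22.5
  oc <- theta / 45 - 0.5
  o_lo <- floor(oc)
  o_fr <- oc - o_lo
  o_bin1 <- (as.integer(o_lo) %% 8L) + 1L
  o_bin2 <- (as.integer(o_lo + 1) %% 8L) + 1L

  idx <- integer(0); wts <- numeric(0)
  add <- function(spatial, obin, wgt) {
    idx <<- c(idx, (spatial - 1L) * 8L + obin)
    wts <<- c(wts, wgt)
  }
  cen <- ring == 0L
  if (any(cen)) {
    add(1L, o_bin1[cen], mag[cen] * (1 - o_fr[cen]))
    add(1L, o_bin2[cen], mag[cen] * o_fr[cen])
  }
  ann <- !cen
  if (any(ann)) {
    # angular soft-assignment between adjacent sectors of the same ring
    sc <- phi[ann] / 45 - 0.5
    s_lo <- floor(sc)
    s_fr <- sc - s_lo
    s_bin1 <- (as.integer(s_lo) %% 8L) + 1L
    s_bin2 <- (as.integer(s_lo + 1) %% 8L) + 1L
    base <- 1L + (ring[ann] - 1L) * 8L   # 1 -> bins 2..9, 2 -> bins 10..17
    m <- mag[ann]; f1 <- o_fr[ann]
    b1 <- o_bin1[ann]; b2 <- o_bin2[ann]
    add(base + s_bin1, b1, m * (1 - s_fr) * (1 - f1))
    add(base + s_bin1, b2, m * (1 - s_fr) * f1)
    add(base + s_bin2, b1, m * s_fr * (1 - f1))
    add(base + s_bin2, b2, m * s_fr * f1)
  }
  acc <- rowsum(wts, group = idx)
  vec[as.integer(rownames(acc))] <- acc

  nrm <- sqrt(sum(vec^2))
  if (nrm == 0) {
    attr(vec, "flagged") <- TRUE
    return(vec)
  }
  vec <- vec / nrm
  vec <- pmin(vec, 0.2)
  vec <- vec / sqrt(sum(vec^2))
  attr(vec, "flagged") <- FALSE
  vec
}

#' Compute descriptors for a keypoint table
#'
#' Order-preserving, deterministic map of [compute_descriptor()] over the
#' rows of a keypoint data frame.
#'
#' @param gp The `gaussian_pyramid` the keypoints came from.
#' @param keypoints Data frame from [detect_features()].
#' @param radii Ring radii passed through.
#' @return Numeric matrix with one 136-column row per keypoint (0-row
#'   matrix for an empty input); attribute `flagged` is a logical vector.
#' @export
describe_all <- function(gp, keypoints, radii = c(6, 11, 15)) {
  n <- nrow(keypoints)
  out <- matrix(0, nrow = n, ncol = 136)
  flagged <- logical(n)
  for (r in seq_len(n)) {
    d <- compute_descriptor(gp, keypoints[r, ], radii)
    out[r, ] <- d
    flagged[r] <- isTRUE(attr(d, "flagged"))
  }
  attr(out, "flagged") <- flagged
  out
}

#' Detect keypoints and compute their descriptors in one pass
#'
#' Convenience wrapper that builds the pyramid once and returns both the
#' keypoint table and the descriptor matrix.
#'
#' @param slice Numeric matrix.
#' @param params A [feature_params()] list.
#' @return List with `keypoints` (data frame) and `descriptors`
#'   (n x 136 matrix).
#' @export
compute_slice_features <- function(slice, params = feature_params()) {
  kp <- detect_features(slice, params, keep_pyramid = TRUE)
  gp <- attr(kp, "pyramid")
  attr(kp, "pyramid") <- NULL
  list(keypoints = kp, descriptors = describe_all(gp, kp))
}
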