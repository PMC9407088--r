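# Keypoint detection: scale-space extrema, sub-pixel refinement, edge
# rejection and dominant-orientation assignment.

#' Detection parameters
#'
#' Bundles the tunables of the feature detector. `contrast_threshold` is on
#' the [0, 1] intensity scale that [detect_features()] normalises slices to.
#'
#' @param intervals_s Scales per octave doubling.
#' @param base_sigma Base blur in pixels.
#' @param num_octaves Octave count or `NULL` for the automatic rule.
#' @param border Pixels excluded at each octave border.
#' @param contrast_threshold Minimum interpolated |DoG| response.
#' @param edge_r Principal-curvature ratio bound `r`; keypoints with
#'   `Tr(H)^2 / Det(H) >= (r + 1)^2 / r` are rejected as edge responses.
#' @param max_refine_attempts Re-centering attempts during sub-pixel fitting.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(intervals_s = 3L, base_sigma = 1.6,
                           num_octaves = NULL, border = 5L,
                           contrast_threshold = 0.03, edge_r = 10,
                           max_refine_attempts = 5L) {
  stopifnot(border >= 1, contrast_threshold >= 0, edge_r > 1)
  structure(list(intervals_s = as.integer(intervals_s),
                 base_sigma = base_sigma, num_octaves = num_octaves,
                 border = as.integer(border),
                 contrast_threshold = contrast_threshold, edge_r = edge_r,
                 max_refine_attempts = as.integer(max_refine_attempts)),
            class = "feature_params")
}

#' Locate integer-grid scale-space extrema
#'
#' A DoG sample is a candidate when it is strictly greater (or strictly
#' smaller) than all 26 neighbours in its 3 x 3 x 3 scale-space cube;
#' plateaus are discarded by the strict inequality. Only interior DoG levels
#' are searched and positions closer than `border` pixels to an octave edge
#' are skipped.
#'
#' @param dog A `dog_pyramid`.
#' @param border Minimum 0-based distance from the octave edge (>= 1).
#' @return Data frame with 0-based columns `octave`, `level`, `x`, `y`.
#' @export
detect_extrema <- function(dog, border = 5L) {
  stopifnot(inherits(dog, "dog_pyramid"), border >= 1)
  out <- list()
  for (o in seq_along(dog$octaves)) {
    D <- dog$octaves[[o]]
    w <- dim(D)[1]; h <- dim(D)[2]; L <- dim(D)[3]
    if (L < 3) stop("each octave needs at least 3 DoG levels")
    b <- as.integer(border)
    xi <- (b + 1L):(w - b); yi <- (b + 1L):(h - b)
    if (length(xi) < 1 || length(yi) < 1) next
    for (l in 2:(L - 1L)) {
      cur <- D[xi, yi, l]
      nbmax <- array(-Inf, dim(cur)); nbmin <- array(Inf, dim(cur))
      for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
        if (dz == 0 && dx == 0 && dy == 0) next
        nb <- D[xi + dx, yi + dy, l + dz]
        nbmax <- pmax(nbmax, nb)
        nbmin <- pmin(nbmin, nb)
      }
      # the magnitude floor guards against roundoff-level "extrema" on
      # numerically flat fields (e.g. a constant image blurred in floats)
      hit <- which((cur > nbmax | cur < nbmin) & abs(cur) > 1e-12,
                   arr.ind = TRUE)
      if (nrow(hit) > 0)
        out[[length(out) + 1L]] <- data.frame(
          octave = o - 1L, level = l - 1L,
          x = xi[hit[, 1]] - 1L, y = yi[hit[, 2]] - 1L)
    }
  }
  if (length(out) == 0)
    return(data.frame(octave = integer(0), level = integer(0),
                      x = integer(0), y = integer(0)))
  do.call(rbind, out)
}

#' Sub-pixel keypoint refinement
#'
#' Fits a 3D quadric to the DoG neighbourhood by central finite differences
#' and solves for the offset of the extremum. If any offset component
#' exceeds 0.5 the integer centre moves one sample in that direction and
#' the fit is repeated (up to `max_attempts`); candidates that fail to
#' converge, leave the valid interior, have a singular Hessian, or whose
#' interpolated |DoG| response falls below `contrast_threshold` are
#' rejected.
#'
#' @param dog A `dog_pyramid`.
#' @param candidate One row of [detect_extrema()] output (or a list with
#'   0-based `octave`, `level`, `x`, `y`).
#' @param contrast_threshold Minimum interpolated |DoG| value.
#' @param max_attempts Maximum re-centering attempts.
#' @return A list of class `keypoint` with full-resolution 0-based `x`, `y`,
#'   absolute `sigma`, `octave`, `level`, octave-frame coordinates
#'   (`x_oct`, `y_oct`, `level_interp`, `sigma_oct`) and `response`;
#'   or `NULL` with attribute `reason` when rejected.
#' @export
refine_keypoint <- function(dog, candidate, contrast_threshold = 0.03,
                            max_attempts = 5L) {
  stopifnot(inherits(dog, "dog_pyramid"))
  o <- as.integer(candidate$octave) + 1L
  D <- dog$octaves[[o]]
  w <- dim(D)[1]; h <- dim(D)[2]; L <- dim(D)[3]
  i <- as.integer(candidate$x) + 1L
  j <- as.integer(candidate$y) + 1L
  l <- as.integer(candidate$level) + 1L

  reject <- function(reason) NULL
  off <- g <- NULL
  ok <- FALSE
  for (attempt in seq_len(max_attempts)) {
    if (i < 2L || i > w - 1L || j < 2L || j > h - 1L || l < 2L || l > L - 1L)
      return(reject("out_of_bounds"))
    g <- c((D[i + 1, j, l] - D[i - 1, j, l]) / 2,
           (D[i, j + 1, l] - D[i, j - 1, l]) / 2,
           (D[i, j, l + 1] - D[i, j, l - 1]) / 2)
    dxx <- D[i + 1, j, l] - 2 * D[i, j, l] + D[i - 1, j, l]
    dyy <- D[i, j + 1, l] - 2 * D[i, j, l] + D[i, j - 1, l]
    dss <- D[i, j, l + 1] - 2 * D[i, j, l] + D[i, j, l - 1]
    dxy <- (D[i + 1, j + 1, l] - D[i + 1, j - 1, l] -
            D[i - 1, j + 1, l] + D[i - 1, j - 1, l]) / 4
    dxs <- (D[i + 1, j, l + 1] - D[i + 1, j, l - 1] -
            D[i - 1, j, l + 1] + D[i - 1, j, l - 1]) / 4
    dys <- (D[i, j + 1, l + 1] - D[i, j + 1, l - 1] -
            D[i, j - 1, l + 1] + D[i, j - 1, l - 1]) / 4
    H <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3)
    off <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(reject("singular_hessian"))
    if (all(abs(off) <= 0.5)) { ok <- TRUE; break }
    step <- ifelse(off > 0.5, 1L, ifelse(off < -0.5, -1L, 0L))
    i <- i + step[1]; j <- j + step[2]; l <- l + step[3]
  }
  if (!ok) return(reject("no_convergence"))
  val <- D[i, j, l] + 0.5 * sum(g * off)
  if (abs(val) < contrast_threshold) return(reject("low_contrast"))

  k <- dog$k_factor
  scale_mult <- 2^(o - 1L)
  x_oct <- (i - 1L) + off[1]
  y_oct <- (j - 1L) + off[2]
  level_interp <- (l - 1L) + off[3]
  sigma_oct <- dog$base_sigma * k^level_interp
  structure(list(
    x = x_oct * scale_mult, y = y_oct * scale_mult,
    sigma = sigma_oct * scale_mult, octave = o - 1L, level = l - 1L,
    x_oct = x_oct, y_oct = y_oct, level_interp = level_interp,
    sigma_oct = sigma_oct, response = abs(val)), class = "keypoint")
}

#' Edge-response filter
#'
#' Computes the 2 x 2 spatial Hessian of the DoG at the keypoint sample and
#' keeps the keypoint iff `Det(H) > 0` and
#' `Tr(H)^2 / Det(H) < (r + 1)^2 / r`, the principal-curvature-ratio bound
#' that removes responses lying along edges.
#'
#' @param dog A `dog_pyramid`.
#' @param kp A `keypoint`.
#' @param r Curvature ratio bound (> 1); the default 10 gives bound 12.1.
#' @return `TRUE` to keep the keypoint.
#' @export
edge_response_filter <- function(dog, kp, r = 10) {
  stopifnot(inherits(dog, "dog_pyramid"), r > 1)
  D <- dog$octaves[[kp$octave + 1L]]
  w <- dim(D)[1]; h <- dim(D)[2]; L <- dim(D)[3]
  i <- as.integer(round(kp$x_oct)) + 1L
  j <- as.integer(round(kp$y_oct)) + 1L
  l <- kp$level + 1L
  if (i < 2L || i > w - 1L || j < 2L || j > h - 1L || l < 1L || l > L)
    return(FALSE)
  dxx <- D[i + 1, j, l] - 2 * D[i, j, l] + D[i - 1, j, l]
  dyy <- D[i, j + 1, l] - 2 * D[i, j, l] + D[i, j - 1, l]
  dxy <- (D[i + 1, j + 1, l] - D[i + 1, j - 1, l] -
          D[i - 1, j + 1, l] + D[i - 1, j - 1, l]) / 4
  tr <- dxx + dyy
  det <- dxx * dyy - dxy^2
  det > 0 && (tr^2 / det) < (r + 1)^2 / r
}

#' Assign the dominant gradient orientation
#'
#' Builds a 36-bin (10 degrees per bin) histogram of gradient direction over
#' the disc of radius `3 * sigma` around the keypoint (in its octave),
#' weighting each sample by gradient magnitude and a Gaussian falloff of
#' width `1.5 * sigma`. The orientation is the centre of the tallest bin
#' after parabolic interpolation over its two neighbours; exactly one
#' orientation is assigned per keypoint.
#'
#' @param gp The `gaussian_pyramid` the keypoint was detected in.
#' @param kp A `keypoint`.
#' @param nbins Histogram bin count (36 = 10 degrees per bin).
#' @return The keypoint with fields `orientation` (degrees in [0, 360)) and
#'   `low_confidence` (`TRUE` when the window had no gradient energy).
#' @export
assign_orientation <- function(gp, kp, nbins = 36L) {
  stopifnot(inherits(gp, "gaussian_pyramid"))
  G <- gp$octaves[[kp$octave + 1L]]
  w <- dim(G)[1]; h <- dim(G)[2]; L <- dim(G)[3]
  lg <- min(max(as.integer(round(kp$level_interp)) + 1L, 1L), L)
  sig <- kp$sigma_oct
  rad <- max(1L, as.integer(ceiling(3 * sig)))
  ci <- as.integer(round(kp$x_oct)) + 1L
  cj <- as.integer(round(kp$y_oct)) + 1L
  xi <- max(2L, ci - rad):min(w - 1L, ci + rad)
  yj <- max(2L, cj - rad):min(h - 1L, cj + rad)
  gx <- (G[xi + 1L, yj, lg] - G[xi - 1L, yj, lg]) / 2
  gy <- (G[xi, yj + 1L, lg] - G[xi, yj - 1L, lg]) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- wrap_deg(atan2(gy, gx) * 180 / pi)
  d2 <- outer((xi - 1L - kp$x_oct)^2, (yj - 1L - kp$y_oct)^2, "+")
  wt <- mag * exp(-d2 / (2 * (1.5 * sig)^2))
  wt[d2 > (3 * sig)^2] <- 0

  kp$low_confidence <- FALSE
  if (all(wt == 0)) {
    kp$orientation <- 0
    kp$low_confidence <- TRUE
    class(kp) <- c("oriented_keypoint", "keypoint")
    return(kp)
  }
  bin <- as.integer(floor(theta / (360 / nbins))) %% nbins + 1L
  hst <- numeric(nbins)
  acc <- rowsum(c(wt), group = c(bin))
  hst[as.integer(rownames(acc))] <- acc

  p <- which.max(hst)
  lft <- hst[(p - 2L) %% nbins + 1L]
  rgt <- hst[p %% nbins + 1L]
  den <- lft - 2 * hst[p] + rgt
  frac <- if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (lft - rgt) / den))
  kp$orientation <- wrap_deg(((p - 1L) + 0.5 + frac) * (360 / nbins))
  class(kp) <- c("oriented_keypoint", "keypoint")
  kp
}

#' Detect oriented keypoints on a 2D slice
#'
#' Full detection pipeline: the slice is min-max normalised to [0, 1],
#' Gaussian and DoG pyramids are built, 26-neighbour extrema are located,
#' refined to sub-pixel precision, filtered by contrast and edge response,
#' and assigned a single dominant orientation. The result is deterministic
#' for a fixed input and parameter set; keypoints are sorted by
#' (y, x, sigma).
#'
#' @param slice Numeric matrix with finite entries.
#' @param params A [feature_params()] list.
#' @param keep_pyramid Attach the Gaussian pyramid as attribute `pyramid`
#'   (needed to compute descriptors without rebuilding it).
#' @return Data frame with one row per keypoint: full-resolution 0-based
#'   `x`, `y`, absolute `sigma`, `orientation` (degrees), `response`,
#'   `octave`, `level`, octave-frame coordinates and `low_confidence`.
#' @export
detect_features <- function(slice, params = feature_params(),
                            keep_pyramid = FALSE) {
  if (!is.matrix(slice) || any(!is.finite(slice)))
    stop("slice must be a finite numeric matrix")
  empty <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      orientation = numeric(0), response = numeric(0),
                      octave = integer(0), level = integer(0),
                      x_oct = numeric(0), y_oct = numeric(0),
                      level_interp = numeric(0), sigma_oct = numeric(0),
                      low_confidence = logical(0))
  norm <- normalize01(slice)
  gp <- build_gaussian_pyramid(norm, params$intervals_s, params$base_sigma,
                               params$num_octaves)
  dog <- build_dog_pyramid(gp)
  cand <- detect_extrema(dog, params$border)
  if (keep_pyramid) attr(empty, "pyramid") <- gp
  if (nrow(cand) == 0) return(empty)

  kps <- list()
  for (r in seq_len(nrow(cand))) {
    kp <- refine_keypoint(dog, cand[r, ], params$contrast_threshold,
                          params$max_refine_attempts)
    if (is.null(kp)) next
    if (!edge_response_filter(dog, kp, params$edge_r)) next
    kp <- assign_orientation(gp, kp)
    kps[[length(kps) + 1L]] <- kp
  }
  if (length(kps) == 0) return(empty)
  df <- do.call(rbind, lapply(kps, function(k)
    data.frame(x = k$x, y = k$y, sigma = k$sigma,
               orientation = k$orientation, response = k$response,
               octave = k$octave, level = k$level, x_oct = k$x_oct,
               y_oct = k$y_oct, level_interp = k$level_interp,
               sigma_oct = k$sigma_oct, low_confidence = k$low_confidence)))
  # refinement can converge to the same extremum from several candidates
  key <- sprintf("%d_%.2f_%.2f_%.2f", df$octave, df$x, df$y, df$sigma)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$y, df$x, df$sigma), , drop = FALSE]
  rownames(df) <- NULL
  if (keep_pyramid) attr(df, "pyramid") <- gp
  df
}
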