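# Planar transform estimation: direct linear transform homography fit,
# affine/rigid alternatives, projection error, and RANSAC with the
# adaptive iteration bound k = log(1 - p) / log(1 - w^m).

#' Identity planar transform
#' @return 3 x 3 identity matrix.
#' @export
identity_transform <- function() diag(3)

# Hartley normalisation: translate to zero mean, scale to RMS sqrt(2).
normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  rms <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  s <- if (rms > 0) sqrt(2) / rms else 1
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

# Any 3 of the points (near-)collinear? Triangle-area test with tolerance
# scaled by the squared bounding-box span.
any_collinear_triple <- function(pts, tol_factor = 1e-6) {
  n <- nrow(pts)
  span <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  tol <- tol_factor * span^2
  cmb <- utils::combn(n, 3)
  for (i in seq_len(ncol(cmb))) {
    p <- pts[cmb[, i], , drop = FALSE]
    area <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
    if (area < tol) return(TRUE)
  }
  FALSE
}

#' Fit a projective homography from point correspondences
#'
#' Normalised direct linear transform: both point sets are translated to
#' zero mean and scaled to RMS distance sqrt(2) before solving, and the
#' solution is denormalised afterwards. With exactly 4 non-degenerate
#' pairs the fit interpolates; with more it is the least-squares solution.
#'
#' @param src,dst n x 2 matrices of 0-based pixel coordinates (n >= 4);
#'   the returned matrix maps `src` into `dst` coordinates.
#' @return 3 x 3 matrix normalised so `[3, 3] == 1`, mapping
#'   `(x, y, 1)'` source pixels to destination pixels.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4 || nrow(dst) != nrow(src))
    stop("need at least 4 source/destination pairs of equal count")
  if (nrow(src) == 4 && any_collinear_triple(src))
    degenerate_error("3 of the 4 source points are collinear")
  Ts <- normalizing_transform(src)
  Td <- normalizing_transform(dst)
  sn <- t(Ts %*% rbind(t(src), 1))[, 1:2, drop = FALSE]
  dn <- t(Td %*% rbind(t(dst), 1))[, 1:2, drop = FALSE]
  n <- nrow(sn)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- sn[i, 1]; y <- sn[i, 2]; u <- dn[i, 1]; v <- dn[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12 || abs(det(H)) < 1e-12)
    degenerate_error("degenerate configuration: homography not invertible")
  H / H[3, 3]
}

#' Fit an affine transform (least squares)
#'
#' @inheritParams fit_homography
#' @return 3 x 3 matrix with last row (0, 0, 1).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3 || nrow(dst) != nrow(src))
    stop("need at least 3 source/destination pairs of equal count")
  if (nrow(src) == 3 && any_collinear_triple(src))
    degenerate_error("the 3 source points are collinear")
  X <- cbind(src, 1)
  coef <- tryCatch(qr.solve(X, dst), error = function(e)
    degenerate_error("degenerate configuration for affine fit"))
  M <- rbind(t(coef), c(0, 0, 1))
  dimnames(M) <- NULL
  M
}

#' Fit a rigid (rotation + translation) transform
#'
#' Closed-form Kabsch/Procrustes solution without scaling; the physically
#' apt model for within-subject in-plane head motion.
#'
#' @inheritParams fit_homography
#' @return 3 x 3 matrix whose upper-left 2 x 2 block is a rotation.
#' @export
fit_rigid <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2 || nrow(dst) != nrow(src))
    stop("need at least 2 source/destination pairs of equal count")
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2, cs); Dm <- sweep(dst, 2, cd)
  H <- t(S) %*% Dm
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t0 <- cd - as.vector(R %*% cs)
  if (any(!is.finite(R))) degenerate_error("degenerate rigid configuration")
  M <- rbind(cbind(R, t0), c(0, 0, 1))
  dimnames(M) <- NULL
  M
}

# Model dispatch used by ransac(); minimal sample sizes 4 / 3 / 2.
fit_transform <- function(src, dst, model = c("homography", "affine", "rigid")) {
  switch(match.arg(model),
         homography = fit_homography(src, dst),
         affine = fit_affine(src, dst),
         rigid = fit_rigid(src, dst))
}

minimal_sample_size <- function(model) {
  switch(model, homography = 4L, affine = 3L, rigid = 2L,
         stop("unknown model"))
}

#' One-sided transfer error of correspondences under a transform
#'
#' Euclidean distance between each projected source point and its
#' destination point. Points mapped to infinity (homogeneous w ~ 0) get
#' error `Inf` and can never be inliers.
#'
#' @param model 3 x 3 planar transform.
#' @param src,dst n x 2 coordinate matrices.
#' @return Numeric vector of pixel errors.
#' @export
projection_error <- function(model, src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  p <- model %*% rbind(t(src), 1)
  w <- p[3, ]
  bad <- abs(w) < 1e-12
  w[bad] <- 1
  err <- sqrt((p[1, ] / w - dst[, 1])^2 + (p[2, ] / w - dst[, 2])^2)
  err[bad] <- Inf
  err
}

#' Adaptive RANSAC iteration bound
#'
#' `k = log(1 - p) / log(1 - w^m)`: the number of random minimal samples
#' needed so that, with inlier fraction `w` and sample size `m`, at least
#' one all-inlier sample is drawn with probability `p`.
#'
#' @param p Success confidence in (0, 1).
#' @param w Inlier fraction in (0, 1]; `w = 1` returns 0 (every sample is
#'   all-inlier) and `w = 0` returns `Inf` (callers cap it).
#' @param m Minimal sample size (>= 1).
#' @return The (real-valued) bound; callers take the ceiling.
#' @export
required_iterations <- function(p, w, m) {
  stopifnot(p > 0, p < 1, w >= 0, w <= 1, m >= 1)
  if (w >= 1) return(0)
  if (w == 0) return(Inf)
  log(1 - p) / log(1 - w^m)
}

#' Robust planar-transform estimation by RANSAC
#'
#' Repeatedly samples `m` non-collinear correspondences, fits a candidate
#' transform, and counts inliers whose transfer error is below `TR`
#' pixels. After each improvement the inlier fraction `w = f / n` updates
#' the adaptive bound `k = log(1 - p) / log(1 - w^m)`; iteration stops
#' once the iteration count reaches `min(ceiling(k), max_iterations)` or
#' the best inlier count reaches `critical_fraction * n`. The final model
#' is refit by least squares on the best inlier set. Fully reproducible
#' for a fixed seed.
#'
#' @param matches A `match_set` from [match_features()].
#' @param keypoints_ref,keypoints_mov Keypoint data frames (columns `x`,
#'   `y`) the match indices refer to; the model maps to-register pixels
#'   into reference pixels.
#' @param TR Inlier threshold in pixels.
#' @param p Confidence for the adaptive bound.
#' @param max_iterations Hard iteration cap.
#' @param critical_fraction Early-exit inlier fraction.
#' @param model Transform family: projective `"homography"` (minimal
#'   sample 4), `"affine"` (3) or `"rigid"` (2).
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return A `ransac_result`: `model` (3 x 3), `inliers` (indices into
#'   `matches$pairs`), `iterations_used`, `final_k`.
#' @export
ransac <- function(matches, keypoints_ref, keypoints_mov, TR = 2.0,
                   p = 0.995, max_iterations = 2000L,
                   critical_fraction = 0.8,
                   model = c("homography", "affine", "rigid"), seed = 0L) {
  stopifnot(inherits(matches, "match_set"))
  model <- match.arg(model)
  m <- minimal_sample_size(model)
  pairs <- matches$pairs
  n <- nrow(pairs)
  if (n < m)
    ransac_failure(sprintf("need at least %d matches for model '%s', got %d",
                           m, model, n))
  src <- cbind(keypoints_mov$x[pairs$mov], keypoints_mov$y[pairs$mov])
  dst <- cbind(keypoints_ref$x[pairs$ref], keypoints_ref$y[pairs$ref])

  with_seed(seed, {
    best <- integer(0)
    k <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      idx <- sample.int(n, m)
      cand <- tryCatch(fit_transform(src[idx, , drop = FALSE],
                                     dst[idx, , drop = FALSE], model),
                       fmritemplate_degenerate = function(e) NULL)
      if (!is.null(cand)) {
        err <- projection_error(cand, src, dst)
        inl <- which(err < TR)
        if (length(inl) > length(best)) {
          best <- inl
          w <- length(best) / n
          k <- required_iterations(p, w, m)
        }
      }
      if (length(best) >= critical_fraction * n) break
      if (it >= min(ceiling(k), max_iterations)) break
    }
    # a minimal sample always fits itself exactly, so consensus is only
    # meaningful beyond m points; require a margin above that (and at
    # least 10% of the candidates) before accepting a model
    min_consensus <- max(m + 2L, ceiling(0.1 * n))
    if (length(best) < min_consensus)
      ransac_failure(sprintf(
        "no consensus: best inlier count %d of %d (need %d) after %d iterations",
        length(best), n, min_consensus, it))
    final <- fit_transform(src[best, , drop = FALSE],
                           dst[best, , drop = FALSE], model)
    structure(list(model = final, inliers = best, iterations_used = it,
                   final_k = k), class = "ransac_result")
  })
}
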