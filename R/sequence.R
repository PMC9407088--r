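# Sequential registration of a slice sequence: adjacent-frame transform
# estimation, recursive composition into the first frame's space, and
# inverse warping.

#' Registration parameters
#'
#' @param feature A [feature_params()] list.
#' @param match_threshold Ratio-test threshold.
#' @param TR RANSAC inlier threshold in pixels.
#' @param ransac_p RANSAC confidence.
#' @param max_iterations RANSAC iteration cap.
#' @param critical_fraction RANSAC early-exit inlier fraction.
#' @param model Transform family (`"homography"`, `"affine"`, `"rigid"`).
#' @param min_matches Minimum accepted matches before attempting RANSAC.
#' @param seed Base RNG seed; pair `i` uses `seed + i`.
#' @return A list of class `registration_params`.
#' @export
registration_params <- function(feature = feature_params(),
                                match_threshold = 0.9, TR = 2.0,
                                ransac_p = 0.995, max_iterations = 2000L,
                                critical_fraction = 0.8,
                                model = "homography", min_matches = 8L,
                                seed = 0L) {
  structure(list(feature = feature, match_threshold = match_threshold,
                 TR = TR, ransac_p = ransac_p,
                 max_iterations = as.integer(max_iterations),
                 critical_fraction = critical_fraction, model = model,
                 min_matches = as.integer(min_matches),
                 seed = as.integer(seed)),
            class = "registration_params")
}

#' Estimate pairwise transforms between adjacent frames
#'
#' For every consecutive frame pair (i, i + 1): detect and describe
#' features on both, match with the ratio test, and estimate the planar
#' transform by RANSAC. Element `i` of the result maps frame `i + 1`
#' pixel coordinates into frame `i` coordinates. Adjacent frames are
#' registered (rather than every frame to frame 1) because temporal
#' neighbours share the most feature structure. When estimation fails for
#' a pair, the identity is recorded and frame `i + 1` is flagged
#' excluded; the layer is never aborted.
#'
#' @param frames List of 2D matrices in temporal order (>= 2).
#' @param params A [registration_params()] list.
#' @param features Optional precomputed per-frame output of
#'   [compute_slice_features()] (avoids re-detection).
#' @return List with `pairwise` (list of 3 x 3 matrices, length
#'   `length(frames) - 1`), `excluded` (1-based positions of frames whose
#'   incoming transform failed), and `details` (per-pair data frame with
#'   keypoint, match and inlier counts).
#' @export
register_adjacent_pairs <- function(frames, params = registration_params(),
                                    features = NULL) {
  t_n <- length(frames)
  if (t_n < 2) stop("need at least 2 frames")
  if (is.null(features))
    features <- lapply(frames, compute_slice_features, params = params$feature)
  pairwise <- vector("list", t_n - 1L)
  excluded <- integer(0)
  details <- data.frame(pair = seq_len(t_n - 1L), n_ref = 0L, n_mov = 0L,
                        n_matches = 0L, n_inliers = 0L, ok = FALSE)
  for (i in seq_len(t_n - 1L)) {
    ref <- features[[i]]; mov <- features[[i + 1L]]
    details$n_ref[i] <- nrow(ref$keypoints)
    details$n_mov[i] <- nrow(mov$keypoints)
    pairwise[[i]] <- identity_transform()
    if (nrow(ref$keypoints) < 2 || nrow(mov$keypoints) < 2) {
      excluded <- c(excluded, i + 1L)
      next
    }
    ms <- match_features(ref$descriptors, mov$descriptors,
                         params$match_threshold)
    details$n_matches[i] <- nrow(ms$pairs)
    if (nrow(ms$pairs) < max(params$min_matches,
                             minimal_sample_size(params$model))) {
      excluded <- c(excluded, i + 1L)
      next
    }
    rr <- tryCatch(
      ransac(ms, ref$keypoints, mov$keypoints, TR = params$TR,
             p = params$ransac_p, max_iterations = params$max_iterations,
             critical_fraction = params$critical_fraction,
             model = params$model, seed = params$seed + i),
      fmritemplate_ransac_failure = function(e) NULL)
    if (is.null(rr)) {
      excluded <- c(excluded, i + 1L)
      next
    }
    pairwise[[i]] <- rr$model
    details$n_inliers[i] <- length(rr$inliers)
    details$ok[i] <- TRUE
  }
  list(pairwise = pairwise, excluded = excluded, details = details)
}

#' Compose pairwise transforms into first-frame space
#'
#' `cumulative[[1]]` is the identity and `cumulative[[i]]` is the matrix
#' product `T1 x T2 x ... x T(i-1)` of the pairwise maps, so it takes
#' frame `i` pixel coordinates into frame 1 coordinates (each `T(j)` maps
#' frame `j + 1` into frame `j`).
#'
#' @param pairwise List of 3 x 3 matrices from
#'   [register_adjacent_pairs()].
#' @return List of `length(pairwise) + 1` cumulative 3 x 3 matrices, with
#'   attribute `noninvertible` holding 1-based frame positions whose
#'   cumulative product lost invertibility.
#' @export
compose_to_reference <- function(pairwise) {
  t_n <- length(pairwise) + 1L
  cum <- vector("list", t_n)
  cum[[1L]] <- identity_transform()
  bad <- integer(0)
  for (i in 2:t_n) {
    cum[[i]] <- cum[[i - 1L]] %*% pairwise[[i - 1L]]
    if (!is.finite(det(cum[[i]])) || abs(det(cum[[i]])) < 1e-12)
      bad <- c(bad, i)
  }
  attr(cum, "noninvertible") <- bad
  cum
}

#' Warp a frame into reference coordinates
#'
#' Inverse warping with bilinear interpolation: each output pixel
#' `(x, y)` samples the source frame at `transform^{-1} (x, y, 1)'`.
#' Samples falling outside the source get value 0 and mask 0.
#'
#' @param frame Source 2D matrix.
#' @param transform 3 x 3 transform mapping source pixels into output
#'   pixels (both 0-based).
#' @param out_shape Output `c(width, height)`; defaults to the frame's.
#' @return List with `warped` and `mask` matrices of shape `out_shape`.
#' @export
warp_slice <- function(frame, transform, out_shape = dim(frame)) {
  Tinv <- solve(transform)
  W <- out_shape[1]; H <- out_shape[2]
  Ws <- nrow(frame); Hs <- ncol(frame)
  X <- rep.int(0:(W - 1L), H)
  Y <- rep(0:(H - 1L), each = W)
  p <- Tinv %*% rbind(X, Y, 1)
  wj <- p[3, ]
  okw <- abs(wj) > 1e-12
  wj[!okw] <- 1
  sx <- p[1, ] / wj
  sy <- p[2, ] / wj
  valid <- okw & sx >= 0 & sx <= Ws - 1L & sy >= 0 & sy <= Hs - 1L
  x0 <- pmax(0L, pmin(as.integer(floor(sx)), Ws - 1L))
  y0 <- pmax(0L, pmin(as.integer(floor(sy)), Hs - 1L))
  x1 <- pmin(x0 + 1L, Ws - 1L)
  y1 <- pmin(y0 + 1L, Hs - 1L)
  fx <- sx - x0; fy <- sy - y0
  fx[!valid] <- 0; fy[!valid] <- 0
  v <- (1 - fx) * (1 - fy) * frame[cbind(x0 + 1L, y0 + 1L)] +
       fx * (1 - fy)       * frame[cbind(x1 + 1L, y0 + 1L)] +
       (1 - fx) * fy       * frame[cbind(x0 + 1L, y1 + 1L)] +
       fx * fy             * frame[cbind(x1 + 1L, y1 + 1L)]
  v[!valid] <- 0
  list(warped = matrix(v, W, H), mask = matrix(as.numeric(valid), W, H))
}

#' Register a slice sequence into first-frame space
#'
#' Runs [register_adjacent_pairs()], composes the chain with
#' [compose_to_reference()], and warps every frame into the first
#' (reference) frame's pixel grid. Deterministic for a fixed seed.
#'
#' @param seq A `slice_sequence` (see [extract_slice_sequences()]) or a
#'   plain list of 2D matrices.
#' @param params A [registration_params()] list.
#' @return A `registered_sequence`: `layer_index`, `warped` (list),
#'   `masks` (list), `cumulative`, `pairwise`, `excluded` (1-based frame
#'   positions), `frame_ids`, `details`.
#' @export
register_sequence <- function(seq, params = registration_params()) {
  if (inherits(seq, "slice_sequence")) {
    frames <- seq$frames
    layer_index <- seq$layer_index
    frame_ids <- seq$frame_ids
  } else {
    frames <- seq
    layer_index <- NA_integer_
    frame_ids <- seq_along(frames) - 1L
  }
  if (length(frames) < 2) stop("need at least 2 frames")
  rap <- register_adjacent_pairs(frames, params)
  if (length(rap$excluded) == length(frames) - 1L)
    stop(sprintf("registration failed for every frame pair of layer %s",
                 layer_index))
  cum <- compose_to_reference(rap$pairwise)
  excluded <- sort(unique(c(rap$excluded, attr(cum, "noninvertible"))))
  out_shape <- dim(frames[[1L]])
  warped <- masks <- vector("list", length(frames))
  warped[[1L]] <- frames[[1L]]
  masks[[1L]] <- matrix(1, out_shape[1], out_shape[2])
  for (i in 2:length(frames)) {
    wr <- warp_slice(frames[[i]], cum[[i]], out_shape)
    warped[[i]] <- wr$warped
    masks[[i]] <- wr$mask
  }
  structure(list(layer_index = layer_index, warped = warped, masks = masks,
                 cumulative = cum, pairwise = rap$pairwise,
                 excluded = excluded, frame_ids = frame_ids,
                 details = rap$details),
            class = "registered_sequence")
}
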