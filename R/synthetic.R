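# Seeded synthetic phantoms with known ground-truth motion, so every
# stage of the pipeline is testable without any imaging data.

#' Phantom motion/noise specification
#'
#' Defaults emulate a resting-state acquisition after scanner
#' stabilisation: sub-voxel to few-voxel in-plane drift (translations up
#' to 2 px, rotations up to 2 degrees, scale within 2 percent), additive
#' Gaussian noise at 2 percent of the intensity range, and optional
#' unstable leading frames with low-frequency intensity drift. Motion
#' follows a bounded random walk, which gives adjacent frames the high
#' mutual similarity that motivates adjacent-pair registration.
#'
#' @param t Number of time frames.
#' @param max_translation Translation bound per axis, pixels.
#' @param max_rotation Rotation bound, degrees.
#' @param max_scale Scale deviation bound (0.02 = +/- 2 percent).
#' @param noise_sigma Additive Gaussian noise SD, intensity units.
#' @param content_drift Per-frame SD of a slowly accumulating smooth
#'   intensity field (a random walk in image content, emulating BOLD
#'   fluctuation and slow scanner drift); 0 disables it. With a positive
#'   value, temporally close frames share more content than distant
#'   ones — the regime in which adjacent-frame matching outperforms
#'   matching everything to the first frame.
#' @param n_unstable Leading frames given extra intensity drift.
#' @param outlier_frames 1-based frame positions given a large motion
#'   jump (for motion-scrubbing tests).
#' @param random_walk Use a bounded random walk (`TRUE`) or independent
#'   per-frame draws.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(t = 10L, max_translation = 2, max_rotation = 2,
                         max_scale = 0.02, noise_sigma = 0.02,
                         content_drift = 0, n_unstable = 0L,
                         outlier_frames = integer(0),
                         random_walk = TRUE, seed = 1L) {
  stopifnot(t >= 2, max_translation >= 0, max_rotation >= 0, max_scale >= 0,
            noise_sigma >= 0, content_drift >= 0, n_unstable >= 0)
  structure(list(t = as.integer(t), max_translation = max_translation,
                 max_rotation = max_rotation, max_scale = max_scale,
                 noise_sigma = noise_sigma, content_drift = content_drift,
                 n_unstable = as.integer(n_unstable),
                 outlier_frames = as.integer(outlier_frames),
                 random_walk = isTRUE(random_walk), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build a planar transform from motion parameters
#'
#' Rotation (degrees) and isotropic scale about the image centre,
#' followed by translation in pixels; maps source pixels to transformed
#' pixels (0-based coordinates).
#'
#' @param dx,dy Translation in pixels.
#' @param theta_deg Rotation in degrees (counter-clockwise).
#' @param scale Isotropic scale factor.
#' @param centre `c(cx, cy)` rotation centre in 0-based pixels.
#' @return 3 x 3 transform matrix.
#' @export
motion_transform <- function(dx = 0, dy = 0, theta_deg = 0, scale = 1,
                             centre = c(0, 0)) {
  th <- theta_deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_part <- c(dx, dy) + centre - as.vector(R %*% centre)
  M <- rbind(cbind(R, t_part), c(0, 0, 1))
  dimnames(M) <- NULL
  M
}

#' Generate a textured brain-like phantom volume
#'
#' A head-shaped ellipse whose interior carries concentric ring structure,
#' a dark ventricle-like core, smoothed random texture at two spatial
#' scales, and dense jittered-grid Gaussian blobs at the scales the
#' detector responds to (plus a sparse coarse population for higher
#' octaves). At the in-plane size the pipeline targets (96 x 96) every
#' layer yields a dense keypoint set (around 45-60 keypoints with default
#' detector settings). Values lie in [0, 1] (the composite is clipped,
#' which preserves local contrast); output is deterministic for a fixed
#' seed.
#'
#' @param w,h In-plane dimensions (>= 32).
#' @param z Number of layers.
#' @param seed RNG seed.
#' @return 3D array (w, h, z).
#' @export
make_textured_phantom <- function(w = 96L, h = 96L, z = 4L, seed = 1L) {
  stopifnot(w >= 32, h >= 32, z >= 1)
  with_seed(seed, {
    vol <- array(0, dim = c(w, h, z))
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    X <- matrix(0:(w - 1), w, h)
    Y <- matrix(0:(h - 1), w, h, byrow = TRUE)
    for (k in seq_len(z)) {
      ry_f <- 0.40 + 0.04 * sin(pi * k / (z + 1))
      rx <- 0.46 * w; ry <- ry_f * h
      U <- (X - cx) / rx
      V <- (Y - cy) / ry
      e <- U^2 + V^2
      inside <- e <= 1
      img <- matrix(0.04, w, h)
      img[inside] <- 0.5
      # concentric "tissue" rings
      img[inside] <- img[inside] + 0.10 * sin(10 * pi * sqrt(e[inside]))
      # dark interior ventricle-like ellipse
      vent <- (U^2 / 0.09 + V^2 / 0.04) <= 1
      img[vent] <- img[vent] - 0.2
      # smoothed random texture at two scales
      for (sg in c(1, 2)) {
        tex <- gaussian_blur(matrix(stats::rnorm(w * h), w, h), sg)
        img[inside] <- img[inside] + 0.15 * (tex / stats::sd(tex))[inside]
      }
      # jittered-grid blobs: random sign and scale, covering the interior
      add_blobs <- function(img, spacing, sig_lo, sig_hi, amp_lo, amp_hi) {
        gx <- seq(3, w - 4, by = spacing)
        gy <- seq(3, h - 4, by = spacing)
        ctr <- expand.grid(x = gx, y = gy)
        ctr$x <- ctr$x + stats::runif(nrow(ctr), -spacing / 2, spacing / 2)
        ctr$y <- ctr$y + stats::runif(nrow(ctr), -spacing / 2, spacing / 2)
        keep <- ((ctr$x - cx) / rx)^2 + ((ctr$y - cy) / ry)^2 <= 1.05
        ctr <- ctr[keep, , drop = FALSE]
        n <- nrow(ctr)
        amp <- stats::runif(n, amp_lo, amp_hi) * sample(c(-1, 1), n, TRUE)
        sg <- stats::runif(n, sig_lo, sig_hi)
        for (b in seq_len(n))
          img <- img + amp[b] * exp(-((X - ctr$x[b])^2 + (Y - ctr$y[b])^2) /
                                      (2 * sg[b]^2))
        img
      }
      img <- add_blobs(img, 4, 1.1, 2.4, 0.3, 0.6)
      img <- add_blobs(img, 10, 3.0, 5.0, 0.25, 0.45)
      vol[, , k] <- pmax(0, pmin(1, img))
    }
    vol
  })
}

#' Animate a phantom with known per-frame motion
#'
#' Each frame applies one sampled in-plane transform (shared across the
#' layers of the volume, as rigid head motion is) to the clean volume and
#' adds Gaussian noise. The first `n_unstable` frames additionally get a
#' decaying low-frequency intensity drift; `outlier_frames` get a large
#' extra translation jump. All ground truth is recorded.
#'
#' @param clean 3D clean volume from [make_textured_phantom()].
#' @param spec A [phantom_spec()].
#' @return List with `sequence` (an `fmri_sequence` with identity
#'   affine) and `truth` (list: `clean_volume`, `per_frame_transforms` —
#'   one 3 x 3 matrix per frame mapping clean pixels to frame pixels —
#'   `motion_parameters` data frame, and `dropped_frames`, the planned
#'   outlier positions).
#' @export
animate_phantom <- function(clean, spec = phantom_spec()) {
  stopifnot(length(dim(clean)) == 3, inherits(spec, "phantom_spec"))
  d <- dim(clean)
  t_n <- spec$t
  with_seed(spec$seed, {
    centre <- c((d[1] - 1) / 2, (d[2] - 1) / 2)
    par <- matrix(0, t_n, 4,
                  dimnames = list(NULL, c("dx", "dy", "theta", "scale")))
    bounds <- c(spec$max_translation, spec$max_translation,
                spec$max_rotation, spec$max_scale)
    state <- c(0, 0, 0, 0)
    for (i in seq_len(t_n)) {
      if (i > 1) {
        if (spec$random_walk) {
          state <- state + stats::runif(4, -bounds / 4, bounds / 4)
          state <- pmax(-bounds, pmin(bounds, state))
        } else {
          state <- stats::runif(4, -bounds, bounds)
        }
      }
      par[i, ] <- state
    }
    jump <- 6 * spec$max_translation + 8
    par[spec$outlier_frames, "dx"] <-
      par[spec$outlier_frames, "dx"] + jump

    transforms <- lapply(seq_len(t_n), function(i)
      motion_transform(par[i, "dx"], par[i, "dy"], par[i, "theta"],
                       1 + par[i, "scale"], centre))

    data <- array(0, dim = c(d, t_n))
    drift <- gaussian_blur(matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]), 8)
    drift <- drift / max(abs(drift))
    content <- matrix(0, d[1], d[2])
    for (i in seq_len(t_n)) {
      if (spec$content_drift > 0 && i > 1) {
        step <- gaussian_blur(matrix(stats::rnorm(d[1] * d[2]),
                                     d[1], d[2]), 4)
        content <- content + spec$content_drift * step / stats::sd(step)
      }
      base <- if (spec$content_drift > 0) clean + c(content) else clean
      for (k in seq_len(d[3]))
        data[, , k, i] <- warp_slice(base[, , k], transforms[[i]])$warped
      if (spec$n_unstable > 0 && i <= spec$n_unstable) {
        fade <- (spec$n_unstable - i + 1) / spec$n_unstable
        for (k in seq_len(d[3]))
          data[, , k, i] <- data[, , k, i] + 0.3 * fade * drift
      }
      if (spec$noise_sigma > 0)
        data[, , , i] <- data[, , , i] +
          stats::rnorm(prod(d), sd = spec$noise_sigma)
    }
    list(sequence = fmri_sequence(data),
         truth = list(clean_volume = clean,
                      per_frame_transforms = transforms,
                      motion_parameters = as.data.frame(par),
                      dropped_frames = spec$outlier_frames))
  })
}

#' Generate a labelled correspondence set for robust-estimation tests
#'
#' Inliers are uniform source points mapped by `transform` plus Gaussian
#' positional jitter; outliers are independent uniform pairs. Labels are
#' returned for recovery scoring.
#'
#' @param n_inliers,n_outliers Pair counts (>= 0).
#' @param transform 3 x 3 ground-truth transform.
#' @param noise_px Positional jitter SD on inlier destinations, pixels.
#' @param seed RNG seed.
#' @param domain `c(lo, hi)` coordinate range points are drawn from.
#' @return List with `src`, `dst` (n x 2 matrices) and `inlier`
#'   (logical vector).
#' @export
make_correspondence_set <- function(n_inliers, n_outliers,
                                    transform = identity_transform(),
                                    noise_px = 0, seed = 1L,
                                    domain = c(0, 95)) {
  stopifnot(n_inliers >= 0, n_outliers >= 0)
  with_seed(seed, {
    n <- n_inliers + n_outliers
    src <- matrix(stats::runif(2 * n, domain[1], domain[2]), n, 2)
    dst <- matrix(0, n, 2)
    if (n_inliers > 0) {
      s <- src[seq_len(n_inliers), , drop = FALSE]
      p <- transform %*% rbind(t(s), 1)
      dst[seq_len(n_inliers), ] <- cbind(p[1, ] / p[3, ], p[2, ] / p[3, ]) +
        matrix(stats::rnorm(2 * n_inliers, sd = noise_px), n_inliers, 2)
    }
    if (n_outliers > 0)
      dst[n_inliers + seq_len(n_outliers), ] <-
        matrix(stats::runif(2 * n_outliers, domain[1], domain[2]),
               n_outliers, 2)
    list(src = src, dst = dst,
         inlier = c(rep(TRUE, n_inliers), rep(FALSE, n_outliers)))
  })
}
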