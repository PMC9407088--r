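# Template construction: preprocessing conventions (leading-frame
# discard, high-motion frame exclusion), per-layer registration and
# fusion, and stacking into the final 3D template.

#' Template-build configuration
#'
#' @param n_discard Leading frames dropped before any processing (the
#'   unstable pre-steady-state volumes).
#' @param motion_limit_mm,motion_limit_deg Per-frame motion-table limits
#'   for frame exclusion.
#' @param k_mad Proxy-rule sensitivity: without a motion table, frames
#'   whose mean absolute difference to the previous retained frame
#'   exceeds `median + k_mad * MAD` of all adjacent-frame differences
#'   are excluded.
#' @param feature A [feature_params()] list.
#' @param match_threshold Ratio-test threshold.
#' @param TR RANSAC inlier threshold, pixels.
#' @param ransac_p RANSAC confidence.
#' @param max_iterations RANSAC iteration cap.
#' @param critical_fraction RANSAC early-exit inlier fraction.
#' @param model Transform family.
#' @param min_matches Minimum matches before RANSAC is attempted.
#' @param fusion_method `"weighted"`, `"direct"` or `"mean"`.
#' @param seed Base seed; layer `k` (0-based) registers with seed
#'   `seed + k`.
#' @return A list of class `build_config`.
#' @export
build_config <- function(n_discard = 4L, motion_limit_mm = 2,
                         motion_limit_deg = 2, k_mad = 5,
                         feature = feature_params(), match_threshold = 0.9,
                         TR = 2.0, ransac_p = 0.995, max_iterations = 2000L,
                         critical_fraction = 0.8, model = "homography",
                         min_matches = 8L, fusion_method = "weighted",
                         seed = 0L) {
  stopifnot(n_discard >= 0, motion_limit_mm > 0, motion_limit_deg > 0,
            k_mad > 0)
  structure(list(n_discard = as.integer(n_discard),
                 motion_limit_mm = motion_limit_mm,
                 motion_limit_deg = motion_limit_deg, k_mad = k_mad,
                 feature = feature, match_threshold = match_threshold,
                 TR = TR, ransac_p = ransac_p,
                 max_iterations = as.integer(max_iterations),
                 critical_fraction = critical_fraction, model = model,
                 min_matches = as.integer(min_matches),
                 fusion_method = fusion_method, seed = as.integer(seed)),
            class = "build_config")
}

#' Drop unstable leading frames
#'
#' @param seq An `fmri_sequence`.
#' @param n Number of leading frames to remove (`n < frame_count - 1`).
#' @return The sequence without its first `n` frames; `frame_ids`
#'   bookkeeping is retained.
#' @export
drop_unstable_frames <- function(seq, n) {
  stopifnot(inherits(seq, "fmri_sequence"))
  n <- as.integer(n)
  if (n < 0 || n >= seq$frame_count - 1L)
    stop(sprintf("n must be in [0, %d), got %d", seq$frame_count - 1L, n))
  if (n == 0L) return(seq)
  keep <- (n + 1L):seq$frame_count
  fmri_sequence(seq$data[, , , keep, drop = FALSE], seq$affine,
                seq$frame_ids[keep])
}

#' Exclude frames with excessive head motion
#'
#' With a motion-parameter table (one row per frame: 3 translations in
#' mm, 3 rotations in degrees), any frame whose absolute translation or
#' rotation exceeds the limits is dropped. Without a table, a
#' data-driven proxy is used: the mean absolute intensity difference of
#' each frame to the previous retained frame is compared against
#' `median + k_mad * MAD` of all adjacent-frame differences, and
#' offending frames are dropped.
#'
#' @param seq An `fmri_sequence`.
#' @param motion_table Numeric matrix with 6 columns and one row per
#'   frame, or `NULL` for the proxy rule.
#' @param limit_mm,limit_deg Motion limits.
#' @param k_mad Proxy sensitivity in MAD units.
#' @return The sequence with offending frames removed; attribute
#'   `excluded_frame_ids` lists their original ids.
#' @export
exclude_high_motion_frames <- function(seq, motion_table = NULL,
                                       limit_mm = 2, limit_deg = 2,
                                       k_mad = 5) {
  stopifnot(inherits(seq, "fmri_sequence"))
  t_n <- seq$frame_count
  if (!is.null(motion_table)) {
    motion_table <- as.matrix(motion_table)
    if (nrow(motion_table) != t_n)
      stop(sprintf("motion table has %d rows but the sequence has %d frames",
                   nrow(motion_table), t_n))
    if (ncol(motion_table) != 6)
      stop("motion table must have 6 columns")
    bad <- apply(abs(motion_table[, 1:3, drop = FALSE]) > limit_mm, 1, any) |
      apply(abs(motion_table[, 4:6, drop = FALSE]) > limit_deg, 1, any)
  } else {
    diffs <- vapply(2:t_n, function(i)
      mean(abs(seq$data[, , , i] - seq$data[, , , i - 1L])), numeric(1))
    thr <- stats::median(diffs) + k_mad * stats::mad(diffs)
    bad <- logical(t_n)
    last <- 1L
    for (i in 2:t_n) {
      d <- mean(abs(seq$data[, , , i] - seq$data[, , , last]))
      if (d > thr) bad[i] <- TRUE else last <- i
    }
  }
  if (sum(!bad) < 2) stop("fewer than 2 frames would remain")
  if (!any(bad)) {
    attr(seq, "excluded_frame_ids") <- integer(0)
    return(seq)
  }
  out <- fmri_sequence(seq$data[, , , !bad, drop = FALSE], seq$affine,
                       seq$frame_ids[!bad])
  attr(out, "excluded_frame_ids") <- seq$frame_ids[bad]
  out
}

#' Build the subject-specific 3D template
#'
#' Applies the preprocessing conventions (leading-frame discard and
#' high-motion exclusion), then, for every z layer, registers the slice
#' sequence into first-frame space and fuses it; the fused slices are
#' stacked in z order into a `template_volume` carrying the source
#' affine. Layers are processed independently, so the spatial shape of
#' the template always equals the spatial shape of the input. The run is
#' deterministic for a fixed seed.
#'
#' @param seq An `fmri_sequence`.
#' @param cfg A [build_config()].
#' @param motion_table Optional motion-parameter matrix (pre-discard row
#'   count must match the input frame count).
#' @param verbose Print one progress line per layer.
#' @return A `template_volume`; `provenance` records the configuration,
#'   retained frame ids and a per-layer log (pair counts, mean inlier
#'   count, excluded frame positions).
#' @export
build_template <- function(seq, cfg = build_config(), motion_table = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(seq, "fmri_sequence"), inherits(cfg, "build_config"))
  if (!is.null(motion_table)) {
    motion_table <- as.matrix(motion_table)
    if (nrow(motion_table) != seq$frame_count)
      stop("motion table rows must match the input frame count")
  }
  seq <- drop_unstable_frames(seq, cfg$n_discard)
  if (!is.null(motion_table))
    motion_table <- motion_table[(cfg$n_discard + 1L):nrow(motion_table), ,
                                 drop = FALSE]
  seq <- exclude_high_motion_frames(seq, motion_table,
                                    cfg$motion_limit_mm,
                                    cfg$motion_limit_deg, cfg$k_mad)
  if (seq$frame_count < 2) stop("fewer than 2 retained frames")

  slices <- extract_slice_sequences(seq)
  d <- dim(seq$data)
  out <- array(0, dim = d[1:3])
  layer_log <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    params <- registration_params(
      feature = cfg$feature, match_threshold = cfg$match_threshold,
      TR = cfg$TR, ransac_p = cfg$ransac_p,
      max_iterations = cfg$max_iterations,
      critical_fraction = cfg$critical_fraction, model = cfg$model,
      min_matches = cfg$min_matches,
      seed = (cfg$seed + k - 1L) %% .Machine$integer.max)
    reg <- tryCatch(register_sequence(slices[[k]], params),
                    error = function(e)
                      stop(sprintf("layer %d: %s", k - 1L,
                                   conditionMessage(e))))
    fused <- fuse_sequence(reg, cfg$fusion_method)
    out[, , k] <- fused$data
    layer_log[[k]] <- list(layer = k - 1L,
                           pairs = nrow(reg$details),
                           mean_inliers = mean(reg$details$n_inliers),
                           excluded = reg$excluded)
    if (verbose)
      message(sprintf("layer %d/%d: %d pairs, mean inliers %.1f, %d excluded",
                      k, d[3], nrow(reg$details),
                      mean(reg$details$n_inliers), length(reg$excluded)))
  }
  template_volume(out, seq$affine,
                  provenance = list(config = cfg,
                                    frame_ids = seq$frame_ids,
                                    layers = layer_log))
}
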