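# One-to-one descriptor matching with the nearest/second-nearest ratio
# test, and the matching-similarity statistic.

#' Euclidean distance between two descriptor vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("descriptor lengths differ (%d vs %d)", length(a), length(b)))
  sqrt(sum((a - b)^2))
}

#' Match descriptors with the ratio test
#'
#' For every to-register descriptor the nearest and second-nearest
#' reference descriptors are found by exhaustive Euclidean search; the
#' candidate is accepted iff `nearest / second_nearest < threshold`
#' (default 0.9). One-to-one correspondence is enforced by keeping, per
#' reference index, only the accepted candidate with the smallest
#' distance, ties broken by the lower to-register index. The result is
#' deterministic.
#'
#' @param ref_desc,mov_desc Descriptor matrices (rows = descriptors) for
#'   the reference and to-register slice.
#' @param threshold Ratio-test threshold in (0, 1]; matches require the
#'   distance ratio to be strictly below it.
#' @return A `match_set`: list with `pairs` (data frame `ref`, `mov`,
#'   `distance`, `ratio`; 1-based row indices), `n_ref`, `n_mov`,
#'   `threshold`.
#' @export
match_features <- function(ref_desc, mov_desc, threshold = 0.9) {
  if (is.null(dim(ref_desc))) ref_desc <- matrix(ref_desc, nrow = 1)
  if (is.null(dim(mov_desc))) mov_desc <- matrix(mov_desc, nrow = 1)
  n_ref <- nrow(ref_desc); n_mov <- nrow(mov_desc)
  empty <- structure(list(
    pairs = data.frame(ref = integer(0), mov = integer(0),
                       distance = numeric(0), ratio = numeric(0)),
    n_ref = n_ref, n_mov = n_mov, threshold = threshold),
    class = "match_set")
  if (n_ref < 2) {
    warning("fewer than 2 reference descriptors: ratio test undefined")
    return(empty)
  }
  if (n_mov < 1) return(empty)

  d2 <- outer(rowSums(mov_desc^2), rowSums(ref_desc^2), "+") -
    2 * tcrossprod(mov_desc, ref_desc)
  # cancellation in the expansion leaves ~1e-15 residue on identical
  # vectors; clamp so identical descriptors are at distance exactly 0
  d2[d2 < 1e-12] <- 0
  d <- sqrt(d2)

  cand <- vector("list", n_mov)
  for (j in seq_len(n_mov)) {
    ord <- order(d[j, ])           # stable: ties resolved by lower ref index
    d1 <- d[j, ord[1]]; d2n <- d[j, ord[2]]
    ratio <- if (d2n == 0) { if (d1 == 0) 0 else Inf } else d1 / d2n
    if (is.finite(ratio) && ratio < threshold)
      cand[[j]] <- data.frame(ref = ord[1], mov = j, distance = d1,
                              ratio = ratio)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) return(empty)

  # one-to-one: per reference index keep the smallest distance, then the
  # lower to-register index
  cand <- cand[order(cand$ref, cand$distance, cand$mov), , drop = FALSE]
  cand <- cand[!duplicated(cand$ref), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(pairs = cand, n_ref = n_ref, n_mov = n_mov,
                 threshold = threshold), class = "match_set")
}

#' Matching-similarity statistic
#'
#' Percentage of matched feature points relative to the smaller of the two
#' keypoint counts: `100 * n_matches / min(n_ref, n_mov)`, reported to two
#' decimals. Used to compare adjacent-frame matching against matching every
#' frame directly to a fixed reference.
#'
#' @param n_ref,n_mov Keypoint counts on the two slices (positive).
#' @param n_matches Accepted match count, at most `min(n_ref, n_mov)`.
#' @return Percentage rounded to 2 decimals.
#' @export
matching_similarity <- function(n_ref, n_mov, n_matches) {
  if (n_ref <= 0 || n_mov <= 0) stop("keypoint counts must be positive")
  if (n_matches > min(n_ref, n_mov))
    stop("n_matches cannot exceed min(n_ref, n_mov)")
  round(100 * n_matches / min(n_ref, n_mov), 2)
}

#' Match-count sweep over ratio thresholds
#'
#' Runs [match_features()] (ratio test plus the identical one-to-one
#' pruning) at each threshold and reports the accepted match count; with
#' the acceptance rule fixed, counts are monotone non-decreasing in the
#' threshold.
#'
#' @param ref_desc,mov_desc Descriptor matrices.
#' @param thresholds Numeric vector of ratio thresholds.
#' @return Data frame with columns `threshold`, `match_count`.
#' @export
threshold_sweep <- function(ref_desc, mov_desc,
                            thresholds = c(0.2, 0.4, 0.6, 0.8, 0.9, 1.0)) {
  counts <- vapply(thresholds, function(th)
    nrow(match_features(ref_desc, mov_desc, th)$pairs), integer(1))
  data.frame(threshold = thresholds, match_count = counts)
}
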