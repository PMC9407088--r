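# Shared fixtures (built once per run) and independent brute-force
# oracles used across the suite.

.fix <- new.env()

# 96 x 96 x 2 textured phantom; both layers carry a dense keypoint set.
fix_phantom <- function() {
  if (is.null(.fix$phantom))
    .fix$phantom <- make_textured_phantom(96, 96, 2, seed = 3)
  .fix$phantom
}

fix_features <- function(layer = 1) {
  key <- paste0("feat", layer)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- compute_slice_features(fix_phantom()[, , layer])
  .fix[[key]]
}

# --- independent oracles -------------------------------------------------

# exhaustive-search matcher: all-pairs distances via the scalar distance
# function, ratio test, then per-reference minimum with low-mov tie-break
oracle_match <- function(ref, mov, threshold) {
  n_ref <- nrow(ref); n_mov <- nrow(mov)
  acc <- NULL
  for (j in seq_len(n_mov)) {
    d <- vapply(seq_len(n_ref), function(i)
      euclidean_distance(ref[i, ], mov[j, ]), numeric(1))
    ord <- order(d)
    d1 <- d[ord[1]]; d2 <- d[ord[2]]
    ratio <- if (d2 == 0) { if (d1 == 0) 0 else Inf } else d1 / d2
    if (is.finite(ratio) && ratio < threshold)
      acc <- rbind(acc, data.frame(ref = ord[1], mov = j, distance = d1))
  }
  if (is.null(acc)) return(acc)
  acc <- acc[order(acc$ref, acc$distance, acc$mov), ]
  acc[!duplicated(acc$ref), ]
}

# per-pixel loop MSE
oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

# covariance-formula Pearson correlation
oracle_ncc <- function(a, b) {
  x <- as.vector(a); y <- as.vector(b)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# fold-left 3x3 chain product
oracle_chain <- function(mats) {
  out <- diag(3)
  for (m in mats) out <- out %*% m
  out
}

# sampled 2D Gaussian kernel image (closed form), unit mass
oracle_gaussian_image <- function(n, centre, sigma) {
  x <- 0:(n - 1)
  gx <- exp(-(x - centre[1])^2 / (2 * sigma^2))
  gy <- exp(-(x - centre[2])^2 / (2 * sigma^2))
  k <- outer(gx, gy)
  k / sum(k)
}

# corners of a w x h pixel grid (0-based)
grid_corners <- function(w, h)
  rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))

apply_transform <- function(M, pts) {
  p <- M %*% rbind(t(pts), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}
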