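test_that("homography fitting is exact on minimal and clean data", {
  # unit square under a pure translation
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- fit_homography(sq, sq + matrix(rep(c(3, -2), each = 4), 4))
  want <- diag(3); want[1, 3] <- 3; want[2, 3] <- -2
  expect_equal(H, want, tolerance = 1e-9)

  # random known homographies recovered from noiseless points
  set.seed(41)
  for (rep in 1:5) {
    Hgt <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    Hgt[3, 3] <- 1
    src <- matrix(runif(2 * 12, 0, 95), 12, 2)
    dst <- apply_transform(Hgt, src)
    Hfit <- fit_homography(src, dst)
    expect_lt(max(abs(Hfit - Hgt)) / max(abs(Hgt)), 1e-6)
  }

  # collinear minimal samples are rejected with a classed signal
  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 1))
  expect_error(fit_homography(bad, bad), class = "fmritemplate_degenerate")
})

test_that("affine and rigid fits recover their generating transforms", {
  set.seed(43)
  src <- matrix(runif(20, 0, 95), 10, 2)
  A <- rbind(c(1.02, -0.05, 3), c(0.04, 0.98, -2), c(0, 0, 1))
  expect_equal(fit_affine(src, apply_transform(A, src)), A, tolerance = 1e-9)

  R <- motion_transform(4, -3, 12, 1, c(40, 40))
  Rfit <- fit_rigid(src, apply_transform(R, src))
  expect_equal(Rfit, R, tolerance = 1e-9)
  # rotation block stays orthonormal even under noise
  noisy <- apply_transform(R, src) + matrix(rnorm(20, sd = 0.3), 10, 2)
  Rn <- fit_rigid(src, noisy)[1:2, 1:2]
  expect_equal(crossprod(Rn), diag(2), tolerance = 1e-9)
})

test_that("projection error matches the closed form and flags infinities", {
  sq <- matrix(runif(16, 0, 50), 8, 2)
  expect_equal(projection_error(identity_transform(), sq, sq), rep(0, 8))
  Tt <- motion_transform(2.5, -1.5)
  expect_equal(projection_error(Tt, sq, sq +
    matrix(rep(c(2.5, -1.5), each = 8), 8)), rep(0, 8), tolerance = 1e-12)

  set.seed(47)
  H <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3); H[3, 3] <- 1
  src <- matrix(runif(12, 0, 50), 6, 2)
  dst <- matrix(runif(12, 0, 50), 6, 2)
  manual <- vapply(1:6, function(i) {
    p <- H %*% c(src[i, ], 1)
    sqrt((p[1] / p[3] - dst[i, 1])^2 + (p[2] / p[3] - dst[i, 2])^2)
  }, numeric(1))
  expect_equal(projection_error(H, src, dst), manual, tolerance = 1e-12)

  # a point mapped to the plane at infinity can never be an inlier
  Hbad <- diag(3); Hbad[3, ] <- c(-1, 0, 10)   # w = 0 at x = 10
  expect_equal(projection_error(Hbad, rbind(c(10, 5)), rbind(c(0, 0))), Inf)
})

test_that("the adaptive iteration bound follows its closed form", {
  expect_equal(required_iterations(0.995, 0.5, 4),
               log(1 - 0.995) / log(1 - 0.5^4))
  expect_equal(required_iterations(0.995, 0.5, 4), 82.1, tolerance = 0.01)
  expect_equal(required_iterations(0.99, 1, 4), 0)
  expect_equal(required_iterations(0.99, 0, 4), Inf)
  ws <- seq(0.1, 0.9, by = 0.1)
  ks <- vapply(ws, required_iterations, numeric(1), p = 0.995, m = 4)
  expect_true(all(diff(ks) < 0))
})

test_that("RANSAC recovers planted transforms from contaminated matches", {
  mk_matchset <- function(cs) {
    n <- nrow(cs$src)
    structure(list(pairs = data.frame(ref = seq_len(n), mov = seq_len(n),
                                      distance = 0, ratio = 0),
                   n_ref = n, n_mov = n, threshold = 0.9),
              class = "match_set")
  }
  Hgt <- motion_transform(3, -2, 2, 1.01, c(48, 48))
  fails <- 0
  for (sd in 1:20) {
    cs <- make_correspondence_set(80, 20, Hgt, noise_px = 0, seed = sd)
    kp_ref <- data.frame(x = cs$dst[, 1], y = cs$dst[, 2])
    kp_mov <- data.frame(x = cs$src[, 1], y = cs$src[, 2])
    rr <- tryCatch(ransac(mk_matchset(cs), kp_ref, kp_mov, TR = 2, seed = sd),
                   fmritemplate_ransac_failure = function(e) NULL)
    if (is.null(rr)) { fails <- fails + 1; next }
    err <- projection_error(rr$model, cs$src[cs$inlier, ], cs$dst[cs$inlier, ])
    if (max(err) >= 2) fails <- fails + 1
    if (mean(which(cs$inlier) %in% rr$inliers) < 0.95) fails <- fails + 1
  }
  expect_equal(fails, 0)

  # all-exact-inlier input: the bound collapses to zero immediately
  cs <- make_correspondence_set(40, 0, Hgt, noise_px = 0, seed = 5)
  rr <- ransac(mk_matchset(cs), data.frame(x = cs$dst[, 1], y = cs$dst[, 2]),
               data.frame(x = cs$src[, 1], y = cs$src[, 2]), TR = 2, seed = 1)
  expect_equal(rr$final_k, 0)
  expect_lte(rr$iterations_used, 2)
  expect_length(rr$inliers, 40)

  # pure outliers: failure signal, never a spurious model
  cs0 <- make_correspondence_set(0, 60, Hgt, seed = 9)
  expect_error(
    ransac(mk_matchset(cs0), data.frame(x = cs0$dst[, 1], y = cs0$dst[, 2]),
           data.frame(x = cs0$src[, 1], y = cs0$src[, 2]), TR = 0.5,
           max_iterations = 500, seed = 3),
    class = "fmritemplate_ransac_failure")

  # fixed seed reproduces the result bit for bit
  cs <- make_correspondence_set(50, 10, Hgt, noise_px = 0.2, seed = 11)
  kr <- data.frame(x = cs$dst[, 1], y = cs$dst[, 2])
  km <- data.frame(x = cs$src[, 1], y = cs$src[, 2])
  r1 <- ransac(mk_matchset(cs), kr, km, TR = 2, seed = 7)
  r2 <- ransac(mk_matchset(cs), kr, km, TR = 2, seed = 7)
  expect_identical(r1, r2)
  expect_gte(length(r1$inliers), 4)
})
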