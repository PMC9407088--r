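test_that("pyramid structure follows the sigma ladder and octave rules", {
  img <- fix_phantom()[, , 1]
  gp <- build_gaussian_pyramid(img)          # s = 3, base 1.6, auto octaves
  expect_length(gp$octaves, 4)               # floor(log2(96)) - 2
  expect_equal(dim(gp$octaves[[1]])[3], 6)   # s + 3 levels
  expect_equal(dim(gp$octaves[[2]])[1:2], c(48, 48))
  k <- 2^(1 / 3)
  expect_equal(gp$k_factor, k)
  expect_equal(gp$sigmas[[1]], 1.6 * k^(0:5))
  expect_equal(gp$sigmas[[3]], 1.6 * 4 * k^(0:5))
  expect_true(all(diff(gp$sigmas[[1]]) > 0))

  dog <- build_dog_pyramid(gp)
  expect_equal(dim(dog$octaves[[1]])[3], 5)  # s + 2 levels
  expect_equal(dog$octaves[[2]],
               gp$octaves[[2]][, , 2:6] - gp$octaves[[2]][, , 1:5])

  expect_error(build_gaussian_pyramid(matrix(0, 8, 8)), "16")
  expect_error(build_gaussian_pyramid(matrix(rnorm(32 * 32), 32), num_octaves = 5),
               "too small")
})

test_that("constant images blur to themselves and give empty detections", {
  flat <- matrix(0.7, 48, 48)
  gp <- build_gaussian_pyramid(flat)
  for (o in seq_along(gp$octaves))
    expect_equal(max(abs(gp$octaves[[o]] - 0.7)), 0, tolerance = 1e-12)
  dog <- build_dog_pyramid(gp)
  expect_lt(max(abs(dog$octaves[[1]])), 1e-12)
  expect_equal(nrow(detect_extrema(dog, 2)), 0)
  expect_equal(nrow(detect_features(flat)), 0)
})

test_that("blur of an impulse matches the closed-form Gaussian kernel", {
  n <- 65L
  img <- matrix(0, n, n); img[33, 33] <- 1
  gp <- build_gaussian_pyramid(img, num_octaves = 1)
  for (j in c(1, 3, 5)) {
    sig <- gp$sigmas[[1]][j]
    oracle <- oracle_gaussian_image(n, c(32, 32), sig)
    expect_lt(sqrt(mean((gp$octaves[[1]][, , j] - oracle)^2)), 1e-3)
  }
  # DoG of the impulse ~ difference of the two closed-form kernels
  dog <- build_dog_pyramid(gp)
  do <- oracle_gaussian_image(n, c(32, 32), gp$sigmas[[1]][3]) -
    oracle_gaussian_image(n, c(32, 32), gp$sigmas[[1]][2])
  expect_lt(sqrt(mean((dog$octaves[[1]][, , 2] - do)^2)), 1e-3)
})

test_that("extrema agree with a brute-force 26-neighbour scan", {
  set.seed(11)
  img <- gaussian_blur(matrix(rnorm(36 * 36), 36, 36), 1)
  gp <- build_gaussian_pyramid(img, num_octaves = 1)
  dog <- build_dog_pyramid(gp)
  got <- detect_extrema(dog, 1)

  D <- dog$octaves[[1]]
  w <- dim(D)[1]; h <- dim(D)[2]; L <- dim(D)[3]
  exp_rows <- NULL
  for (l in 2:(L - 1)) for (i in 2:(w - 1)) for (j in 2:(h - 1)) {
    nb <- D[(i - 1):(i + 1), (j - 1):(j + 1), (l - 1):(l + 1)]
    c0 <- D[i, j, l]
    if (c0 > max(nb[-14]) || c0 < min(nb[-14]))
      exp_rows <- rbind(exp_rows, c(0, l - 1, i - 1, j - 1))
  }
  expect_equal(nrow(got), nrow(exp_rows))
  expect_equal(unname(as.matrix(got)), unname(exp_rows))

  # a single bright blob yields a candidate at its centre, at the level
  # whose scale matches the blob
  x <- 0:63
  blob <- outer(exp(-(x - 30)^2 / (2 * 9)), exp(-(x - 34)^2 / (2 * 9)))
  gb <- build_gaussian_pyramid(blob, num_octaves = 1)
  cb <- detect_extrema(build_dog_pyramid(gb), 2)
  expect_gt(nrow(cb), 0)
  near <- cb[abs(cb$x - 30) <= 1 & abs(cb$y - 34) <= 1, ]
  expect_gt(nrow(near), 0)

  # plateaus are excluded by the strict inequality
  flat3 <- structure(list(octaves = list(array(1, dim = c(12, 12, 3))),
                          sigmas = list(c(1.6, 2, 2.5)), k_factor = 2^(1/3),
                          base_sigma = 1.6, intervals = 1L),
                     class = "dog_pyramid")
  expect_equal(nrow(detect_extrema(flat3, 1)), 0)
})

test_that("sub-pixel refinement recovers analytic quadratic extrema", {
  # synthetic DoG: separable concave quadratic with a known fractional peak
  x0 <- 10.3; y0 <- 7.8; l0 <- 1.25
  D <- array(0, dim = c(21, 15, 3))
  for (l in 0:2) for (i in 0:20) for (j in 0:14)
    D[i + 1, j + 1, l + 1] <- 1 -
      0.02 * (i - x0)^2 - 0.03 * (j - y0)^2 - 0.05 * (l - l0)^2
  dog <- structure(list(octaves = list(D), sigmas = list(c(1.6, 2, 2.5)),
                        k_factor = 2^(1/3), base_sigma = 1.6, intervals = 1L),
                   class = "dog_pyramid")
  kp <- refine_keypoint(dog, list(octave = 0, level = 1, x = 10, y = 8),
                        contrast_threshold = 0.01)
  expect_equal(kp$x, x0, tolerance = 1e-9)
  expect_equal(kp$y, y0, tolerance = 1e-9)
  expect_equal(kp$level_interp, l0, tolerance = 1e-9)

  # symmetric blob: offset ~ 0, position unchanged within 0.1 px
  x <- 0:63
  blob <- outer(exp(-(x - 32)^2 / 18), exp(-(x - 32)^2 / 18))
  gb <- build_gaussian_pyramid(blob, num_octaves = 1)
  db <- build_dog_pyramid(gb)
  cand <- detect_extrema(db, 2)
  cand <- cand[cand$x == 32 & cand$y == 32, ][1, ]
  kpb <- refine_keypoint(db, cand, contrast_threshold = 0)
  expect_lt(abs(kpb$x - 32), 0.1)
  expect_lt(abs(kpb$y - 32), 0.1)

  # below-threshold responses are rejected
  expect_null(refine_keypoint(dog, list(octave = 0, level = 1, x = 10, y = 8),
                              contrast_threshold = 10))
})

test_that("edge filter keeps isotropic blobs and rejects straight edges", {
  # isotropic blob: curvature ratio at the minimum 4 < 12.1 for r = 10
  x <- 0:63
  blob <- outer(exp(-(x - 32)^2 / 18), exp(-(x - 32)^2 / 18))
  gb <- build_gaussian_pyramid(blob, num_octaves = 1)
  db <- build_dog_pyramid(gb)
  cand <- detect_extrema(db, 2)
  cand <- cand[cand$x == 32 & cand$y == 32, ][1, ]
  kpb <- refine_keypoint(db, cand, contrast_threshold = 0)
  expect_true(edge_response_filter(db, kpb, r = 10))

  # ideal straight step edge: one principal curvature vanishes
  edge <- matrix(0, 64, 64); edge[33:64, ] <- 1
  ge <- build_gaussian_pyramid(edge, num_octaves = 1)
  de <- build_dog_pyramid(ge)
  fake <- list(octave = 0, level = 2, x_oct = 32, y_oct = 32)
  expect_false(edge_response_filter(de, fake, r = 10))

  # keep-rate is monotone non-decreasing in r
  img <- fix_phantom()[, , 1]
  gp <- build_gaussian_pyramid(normalize01(img))
  dog <- build_dog_pyramid(gp)
  cand <- detect_extrema(dog, 5)
  kps <- Filter(Negate(is.null), lapply(seq_len(nrow(cand)), function(r)
    refine_keypoint(dog, cand[r, ], 0.03)))
  kept <- vapply(c(2, 5, 10, 20, 50), function(r)
    sum(vapply(kps, edge_response_filter, logical(1), dog = dog, r = r)),
    numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("dominant orientation follows the gradient and its quantisation", {
  # ramp at a known angle -> single occupied 10-degree bin
  n <- 64
  G <- array(0, dim = c(n, n, 3))
  mk_kp <- function() list(octave = 0, level = 1, x_oct = 32, y_oct = 32,
                           level_interp = 1, sigma_oct = 2)
  gp_of <- function(img) structure(
    list(octaves = list(array(rep(img, 3), dim = c(n, n, 3))),
         sigmas = list(c(1.6, 2, 2.5)), k_factor = 2^(1/3),
         base_sigma = 1.6, intervals = 1L), class = "gaussian_pyramid")
  X <- matrix(0:(n - 1), n, n); Y <- matrix(0:(n - 1), n, n, byrow = TRUE)

  ok <- assign_orientation(gp_of(X), mk_kp())   # gradient along +x
  expect_lt(min(abs(c(ok$orientation, ok$orientation - 360))), 10)

  # rotating the pattern by 90 degrees rotates the orientation by 90
  ok90 <- assign_orientation(gp_of(Y), mk_kp())
  expect_lt(abs(ok90$orientation - (ok$orientation + 90)) %% 360, 10 + 1e-9)

  # a ramp at 17 deg lands in the [10, 20) bin whose centre is 15 deg
  r17 <- cos(17 * pi / 180) * X + sin(17 * pi / 180) * Y
  expect_equal(assign_orientation(gp_of(r17), mk_kp())$orientation, 15)
  # and at 23 deg in the [20, 30) bin centred at 25 deg
  r23 <- cos(23 * pi / 180) * X + sin(23 * pi / 180) * Y
  expect_equal(assign_orientation(gp_of(r23), mk_kp())$orientation, 25)

  # no gradient energy: flagged low-confidence with orientation 0
  oz <- assign_orientation(gp_of(matrix(1, n, n)), mk_kp())
  expect_true(oz$low_confidence)
  expect_equal(oz$orientation, 0)
})

test_that("detection is deterministic and translation-equivariant", {
  s <- fix_phantom()[, , 1]
  k1 <- detect_features(s)
  expect_gt(nrow(k1), 0)
  expect_identical(k1, detect_features(s))   # bit-identical repeat

  # orientation range and sorting invariants
  expect_true(all(k1$orientation >= 0 & k1$orientation < 360))
  expect_true(!is.unsorted(k1$y))

  # integer translation moves interior keypoints by the same amount
  dx <- 3L; dy <- 2L
  n <- nrow(s)
  sh <- matrix(0, n, n)
  sh[(1 + dx):n, (1 + dy):n] <- s[1:(n - dx), 1:(n - dy)]
  k2 <- detect_features(sh)
  interior <- which(k1$x > 10 & k1$x < 80 & k1$y > 10 & k1$y < 80)
  hits <- vapply(interior, function(r)
    min(sqrt((k2$x - (k1$x[r] + dx))^2 + (k2$y - (k1$y[r] + dy))^2)),
    numeric(1))
  expect_gt(mean(hits <= 0.5), 0.85)

  # sub-threshold noise yields nothing
  quiet <- matrix(0.5, 64, 64) +
    with_seed(5, matrix(rnorm(64 * 64, sd = 1e-4), 64, 64))
  expect_equal(nrow(detect_features(quiet)), 0)
})
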