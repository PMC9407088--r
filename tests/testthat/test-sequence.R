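test_that("transform chains compose in frame order", {
  ids <- replicate(4, identity_transform(), simplify = FALSE)
  cum <- compose_to_reference(ids)
  for (m in cum) expect_equal(m, identity_transform())

  # pure translations compose to the vector sum
  tr <- lapply(list(c(1, 2), c(-3, 1), c(0.5, -4)), function(v)
    motion_transform(v[1], v[2]))
  cum <- compose_to_reference(tr)
  expect_equal(cum[[4]][1:2, 3], c(1 - 3 + 0.5, 2 + 1 - 4))

  # random homography chain against a fold-left product oracle
  set.seed(53)
  chain <- lapply(1:5, function(i) {
    H <- diag(3) + matrix(rnorm(9, sd = 0.03), 3, 3); H / H[3, 3]
  })
  cum <- compose_to_reference(chain)
  for (i in 2:6)
    expect_equal(cum[[i]], oracle_chain(chain[seq_len(i - 1)]),
                 tolerance = 1e-10)
})

test_that("inverse warping is exact for identity and integer shifts", {
  s <- fix_phantom()[, , 1]
  w0 <- warp_slice(s, identity_transform())
  expect_equal(w0$warped, s)
  expect_true(all(w0$mask == 1))

  # integer translation equals a rolled copy with a vacated zero band
  Tt <- motion_transform(3, -2)
  wt <- warp_slice(s, Tt)
  n <- nrow(s)
  expect_equal(wt$warped[4:n, 1:(n - 2)], s[1:(n - 3), 3:n])
  expect_true(all(wt$mask[1:3, ] == 0))
  expect_true(all(wt$mask[, (n - 1):n] == 0))
  expect_true(all(wt$warped[1:3, ] == 0))

  # warp there and back: only interpolation loss remains (smooth image,
  # so the loss is dominated by true resampling error, not aliasing)
  s <- gaussian_blur(s, 1.5)
  Tr <- motion_transform(1.3, -0.7, 3, 1.01, c(47.5, 47.5))
  fwd <- warp_slice(s, Tr)
  back <- warp_slice(fwd$warped, solve(Tr))
  core <- back$mask > 0 & warp_slice(fwd$mask, solve(Tr))$warped > 0.99
  core[c(1:6, 91:96), ] <- FALSE; core[, c(1:6, 91:96)] <- FALSE
  rmse <- sqrt(mean((back$warped[core] - s[core])^2))
  expect_lt(rmse, 0.02 * diff(range(s)))
})

test_that("adjacent-pair registration recovers known shifts", {
  s <- fix_phantom()[, , 1]
  # five frames, each shifted by (2, -1) px from its predecessor
  shift <- motion_transform(2, -1)
  frames <- vector("list", 5)
  frames[[1]] <- s
  for (i in 2:5)
    frames[[i]] <- warp_slice(frames[[i - 1]], shift)$warped
  rap <- register_adjacent_pairs(frames, registration_params(seed = 2))
  expect_length(rap$pairwise, 4)
  expect_length(rap$excluded, 0)
  corners <- grid_corners(96, 96)
  for (i in 1:4) {
    # pairwise i maps frame i+1 into frame i: the inverse of the shift
    disp <- apply_transform(rap$pairwise[[i]], corners) - corners
    expect_lt(max(abs(disp[, 1] - (-2))), 0.3)
    expect_lt(max(abs(disp[, 2] - 1)), 0.3)
  }

  # identical frames give near-identity transforms
  same <- replicate(3, s, simplify = FALSE)
  rap0 <- register_adjacent_pairs(same, registration_params(seed = 2))
  for (m in rap0$pairwise) {
    disp <- apply_transform(m, corners) - corners
    expect_lt(max(abs(disp)), 0.5)
  }

  # a blank frame interrupts the chain: identity recorded, frame flagged
  broken <- frames
  broken[[3]] <- matrix(0, 96, 96)
  rapb <- register_adjacent_pairs(broken, registration_params(seed = 2))
  expect_true(3 %in% rapb$excluded)
  expect_equal(rapb$pairwise[[2]], identity_transform())
})

test_that("sequence registration aligns a drifting phantom to frame one", {
  clean <- fix_phantom()
  an <- animate_phantom(clean, phantom_spec(t = 6, noise_sigma = 0.01,
                                            seed = 13))
  sl <- extract_slice_sequences(an$sequence)[[1]]
  reg <- register_sequence(sl, registration_params(seed = 5))
  expect_s3_class(reg, "registered_sequence")
  ref <- reg$warped[[1]]
  for (i in 2:6) {
    m <- reg$masks[[i]] > 0
    expect_gt(ncc(ref, reg$warped[[i]], m), 0.98)
  }

  # identical frames pass through up to interpolation noise
  same <- replicate(3, clean[, , 1], simplify = FALSE)
  regs <- register_sequence(same, registration_params(seed = 2))
  for (i in 2:3)
    expect_lt(max(abs(regs$warped[[i]] - clean[, , 1]) *
                    (regs$masks[[i]] > 0)), 0.05)
})

test_that("chained transforms drift sub-pixel over twenty frames", {
  clean <- fix_phantom()
  an <- animate_phantom(clean, phantom_spec(t = 20, max_translation = 3,
                                            max_rotation = 1.5,
                                            max_scale = 0.01,
                                            noise_sigma = 0.01, seed = 17))
  sl <- extract_slice_sequences(an$sequence)[[1]]
  reg <- register_sequence(sl, registration_params(seed = 3))
  expect_length(reg$excluded, 0)
  corners <- grid_corners(96, 96)
  gt <- an$truth$per_frame_transforms
  errs <- vapply(2:20, function(i) {
    want <- solve(gt[[i]])      # frame i -> clean = frame 1 space
    max(sqrt(rowSums((apply_transform(reg$cumulative[[i]], corners) -
                        apply_transform(want, corners))^2)))
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("adjacent frames match better than distant ones on a drift", {
  # temporally accumulating content change (BOLD-like drift) is what makes
  # neighbours easier to match than the first frame
  clean <- fix_phantom()
  an <- animate_phantom(clean, phantom_spec(t = 8, max_translation = 4,
                                            max_rotation = 2,
                                            max_scale = 0.02,
                                            noise_sigma = 0.02,
                                            content_drift = 0.05, seed = 23))
  sl <- extract_slice_sequences(an$sequence)[[1]]
  feats <- lapply(sl$frames, compute_slice_features)
  sim <- function(a, b) {
    ms <- match_features(feats[[a]]$descriptors, feats[[b]]$descriptors, 0.9)
    matching_similarity(ms$n_ref, ms$n_mov, nrow(ms$pairs))
  }
  adjacent <- vapply(1:7, function(i) sim(i, i + 1), numeric(1))
  to_first <- vapply(2:8, function(i) sim(1, i), numeric(1))
  expect_gte(mean(adjacent), mean(to_first))
})
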