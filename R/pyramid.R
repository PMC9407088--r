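# Gaussian and difference-of-Gaussians scale space for 2D slices.
#
# Pixel convention used throughout the package: a slice is a numeric matrix
# indexed [x, y] (x = first axis), and public keypoint/transform coordinates
# are 0-based, so pixel (0, 0) is matrix element [1, 1].

#' 1D Gaussian convolution kernel
#'
#' Normalised kernel truncated at radius `ceiling(4 * sigma)`.
#' @keywords internal
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense 1D blur operator (n x n) with reflecting boundary, so a separable
# 2D blur is opR %*% img %*% t(opC). Sizes here are <= a few hundred, where
# the dense matrix product is fast and exact.
blur_operator <- function(n, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  op <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in (-r):r) {
    j <- reflect_index(idx + o, n)
    w <- k[o + r + 1L]
    op[cbind(idx, j)] <- op[cbind(idx, j)] + w
  }
  op
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with reflecting boundary handling, which
#' avoids the dark halo a zero-padded blur produces at the brain edge.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the input.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (sigma <= 0) return(image)
  opr <- blur_operator(nrow(image), sigma)
  opc <- blur_operator(ncol(image), sigma)
  opr %*% image %*% t(opc)
}

#' Build a multi-octave Gaussian pyramid
#'
#' Octave `o`, level `j` holds the image blurred to absolute scale
#' `base_sigma * 2^o * k^j` with `k = 2^(1/intervals_s)`; each octave has
#' `intervals_s + 3` levels and octave `o + 1` is a 2x downsampling of the
#' level of octave `o` whose relative blur is `2 * base_sigma`. Blur is
#' applied incrementally so the composed blur equals the absolute scale
#' (the input is treated as unblurred).
#'
#' @param image Numeric matrix, at least 16 x 16.
#' @param intervals_s Scales per octave doubling (>= 1).
#' @param base_sigma Blur of the first level, in pixels.
#' @param num_octaves Number of octaves, or `NULL` for the automatic rule
#'   `floor(log2(min(dim))) - 2` (keeps the smallest octave >= 16 px).
#' @return A `gaussian_pyramid` object: `octaves` (list of w x h x levels
#'   arrays), `sigmas` (per-octave absolute scales), `k_factor`,
#'   `base_sigma`, `intervals`.
#' @export
build_gaussian_pyramid <- function(image, intervals_s = 3L, base_sigma = 1.6,
                                   num_octaves = NULL) {
  if (!is.matrix(image) || min(dim(image)) < 16)
    stop("image must be a matrix of at least 16 x 16 pixels")
  if (intervals_s < 1) stop("intervals_s must be >= 1")
  if (base_sigma <= 0) stop("base_sigma must be > 0")
  s <- as.integer(intervals_s)
  k <- 2^(1 / s)
  max_oct <- max(1L, as.integer(floor(log2(min(dim(image)))) - 2))
  if (is.null(num_octaves)) num_octaves <- max_oct
  num_octaves <- as.integer(num_octaves)
  if (num_octaves < 1) stop("num_octaves must be >= 1")
  if (num_octaves > max_oct)
    stop(sprintf("image of %d x %d is too small for %d octaves (max %d)",
                 nrow(image), ncol(image), num_octaves, max_oct))

  n_levels <- s + 3L
  rel_sigma <- base_sigma * k^(0:(n_levels - 1L))  # same in every octave
  octaves <- vector("list", num_octaves)
  sigmas <- vector("list", num_octaves)
  base <- image
  for (o in seq_len(num_octaves)) {
    stack <- array(0, dim = c(nrow(base), ncol(base), n_levels))
    lvl <- if (o == 1L) gaussian_blur(base, base_sigma) else base
    stack[, , 1L] <- lvl
    for (j in 2:n_levels) {
      inc <- sqrt(rel_sigma[j]^2 - rel_sigma[j - 1L]^2)
      lvl <- gaussian_blur(lvl, inc)
      stack[, , j] <- lvl
    }
    octaves[[o]] <- stack
    sigmas[[o]] <- rel_sigma * 2^(o - 1L)
    if (o < num_octaves) {
      # next octave seeds from the level with relative blur 2 * base_sigma
      seed_lvl <- stack[, , s + 1L]
      base <- seed_lvl[seq(1L, nrow(seed_lvl), by = 2L),
                       seq(1L, ncol(seed_lvl), by = 2L), drop = FALSE]
    }
  }
  structure(list(octaves = octaves, sigmas = sigmas, k_factor = k,
                 base_sigma = base_sigma, intervals = s),
            class = "gaussian_pyramid")
}

#' Build the difference-of-Gaussians pyramid
#'
#' Level `j` of each octave is Gaussian level `j + 1` minus level `j`
#' (exact subtraction), giving `intervals + 2` levels per octave.
#'
#' @param gp A `gaussian_pyramid`.
#' @return A `dog_pyramid` object mirroring the Gaussian octave shapes.
#' @export
build_dog_pyramid <- function(gp) {
  stopifnot(inherits(gp, "gaussian_pyramid"))
  octaves <- lapply(gp$octaves, function(stack) {
    L <- dim(stack)[3]
    stack[, , 2:L, drop = FALSE] - stack[, , 1:(L - 1L), drop = FALSE]
  })
  structure(list(octaves = octaves,
                 sigmas = lapply(gp$sigmas, function(s) s[-length(s)]),
                 k_factor = gp$k_factor, base_sigma = gp$base_sigma,
                 intervals = gp$intervals),
            class = "dog_pyramid")
}
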