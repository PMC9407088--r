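# Single-modality registration-quality metrics: MSE, NCC (Pearson),
# mutual information and normalised mutual information on a shared
# min-max intensity binning.

check_pair <- function(a, b, mask) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || !all(da == db)) stop("image shapes differ")
  if (is.null(mask)) mask <- array(TRUE, da)
  dm <- dim(mask) %||% length(mask)
  if (!all(dm == da)) stop("mask shape differs from images")
  mask <- mask > 0
  if (!any(mask)) stop("empty evaluation mask")
  mask
}

#' Mean squared error over a mask
#' @param a,b Images (equal shape).
#' @param mask Optional evaluation mask (non-zero = evaluate).
#' @return Mean of squared intensity differences.
#' @export
mse <- function(a, b, mask = NULL) {
  mask <- check_pair(a, b, mask)
  mean((a[mask] - b[mask])^2)
}

#' Normalised cross-correlation over a mask
#'
#' Zero-mean normalised cross-correlation, i.e. the Pearson correlation
#' of the masked intensities.
#'
#' @inheritParams mse
#' @return Correlation in [-1, 1].
#' @export
ncc <- function(a, b, mask = NULL) {
  mask <- check_pair(a, b, mask)
  x <- a[mask]; y <- b[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("NCC undefined: an image is constant over the mask")
  stats::cor(x, y)
}

# Min-max equal-width binning into 1..bins over the masked values.
bin_intensities <- function(v, bins) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(rep(1L, length(v)))
  pmin(bins, as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * bins)) + 1L)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information of two images
#'
#' MI of the joint intensity histogram: each image is min-max binned over
#' the mask into `bins` equal-width bins, and MI is computed from the
#' `bins x bins` joint histogram with natural logarithms, so
#' `mutual_information(a, a)` equals the entropy of `a`'s histogram.
#'
#' @inheritParams mse
#' @param bins Histogram bins per image.
#' @return MI in nats (>= 0).
#' @export
mutual_information <- function(a, b, mask = NULL, bins = 32L) {
  mask <- check_pair(a, b, mask)
  ia <- bin_intensities(a[mask], bins)
  ib <- bin_intensities(b[mask], bins)
  n <- length(ia)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins) / n
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  shannon_entropy(pa) + shannon_entropy(pb) - shannon_entropy(joint)
}

#' Normalised mutual information
#'
#' `NMI = (H(a) + H(b)) / H(a, b)` with the same binning as
#' [mutual_information()]; ranges over [1, 2], with 2 for identical
#' images and 1 for independent ones.
#'
#' @inheritParams mutual_information
#' @return NMI value.
#' @export
nmi <- function(a, b, mask = NULL, bins = 32L) {
  mask <- check_pair(a, b, mask)
  ia <- bin_intensities(a[mask], bins)
  ib <- bin_intensities(b[mask], bins)
  n <- length(ia)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins) / n
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  hj <- shannon_entropy(joint)
  if (hj == 0) return(2)   # both images constant: identical histograms
  (shannon_entropy(pa) + shannon_entropy(pb)) / hj
}

#' Full metric report for an image pair
#'
#' @inheritParams mutual_information
#' @return List with `mse`, `ncc` (NA when undefined), `mi`, `nmi`,
#'   `n_pixels`, `histogram_bins`.
#' @export
metric_report <- function(a, b, mask = NULL, bins = 32L) {
  mk <- check_pair(a, b, mask)
  list(mse = mse(a, b, mk),
       ncc = tryCatch(ncc(a, b, mk), error = function(e) NA_real_),
       mi = mutual_information(a, b, mk, bins),
       nmi = nmi(a, b, mk, bins),
       n_pixels = sum(mk), histogram_bins = as.integer(bins))
}
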