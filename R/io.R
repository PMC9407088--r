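# NIfTI I/O: load a 4D fMRI series, split it into per-layer slice
# sequences, and write the fused 3D template back with its affine.
#
# Axis convention: NIfTI order (x, y, z, t); a "slice" is data[, , k, i]
# treated as a matrix indexed (x, y); pixel coordinates are 0-based with
# x along the first axis.

#' Construct an fMRI sequence object
#'
#' @param data 4D numeric array (x, y, z, t) with finite entries.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param frame_ids 0-based original time indices of the retained frames.
#' @return A list of class `fmri_sequence` with `data`, `affine`,
#'   `voxel_sizes` (mm triplet from the affine), `frame_ids`,
#'   `frame_count`, `layer_count`.
#' @export
fmri_sequence <- function(data, affine = diag(4),
                          frame_ids = seq_len(dim(data)[4]) - 1L) {
  if (length(dim(data)) != 4) stop("expected 4D data (x, y, z, t)")
  d <- dim(data)
  if (d[4] < 2) stop("need at least 2 time frames")
  if (d[3] < 1) stop("need at least 1 layer")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4 x 4")
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != d[4] || is.unsorted(frame_ids, strictly = TRUE))
    stop("frame_ids must be strictly increasing with one entry per frame")
  structure(list(data = data, affine = affine,
                 voxel_sizes = sqrt(colSums(affine[1:3, 1:3]^2)),
                 frame_ids = frame_ids, frame_count = d[4],
                 layer_count = d[3]),
            class = "fmri_sequence")
}

#' Load a 4D fMRI NIfTI file
#'
#' Reads a NIfTI-1/NIfTI-2 file, casts intensities to double, and
#' preserves the voxel-to-world affine.
#'
#' @param path Path to a `.nii` / `.nii.gz` file with 4 dimensions.
#' @param nan How to treat NaN/Inf voxels: `"error"` (default) or
#'   `"zero"` (replace with 0 and message), since silent NaNs poison the
#'   gradients feature detection relies on.
#' @return An `fmri_sequence`.
#' @export
load_4d <- function(path, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  if (!file.exists(path)) stop(sprintf("file does not exist: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("unreadable NIfTI file %s: %s", path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 4)
    stop(sprintf("expected 4D image, got %dD (%s)", length(d),
                 paste(d, collapse = " x ")))
  data <- array(as.numeric(img), dim = d)
  if (any(!is.finite(data))) {
    if (nan == "error")
      stop("image contains NaN/Inf voxels (use nan = \"zero\" to zero-fill)")
    message(sprintf("zero-filled %d non-finite voxels", sum(!is.finite(data))))
    data[!is.finite(data)] <- 0
  }
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  fmri_sequence(data, aff)
}

#' Split a 4D sequence into per-layer slice sequences
#'
#' Element `k` holds, in temporal order, the layer-`k` slice of every
#' retained frame; restacking all outputs reproduces the input array
#' exactly.
#'
#' @param seq An `fmri_sequence`.
#' @return List of `layer_count` `slice_sequence` objects, each with
#'   `layer_index` (0-based), `frames` (list of matrices) and
#'   `frame_ids`.
#' @export
extract_slice_sequences <- function(seq) {
  stopifnot(inherits(seq, "fmri_sequence"))
  lapply(seq_len(seq$layer_count), function(k) {
    structure(list(
      layer_index = k - 1L,
      frames = lapply(seq_len(seq$frame_count),
                      function(i) seq$data[, , k, i]),
      frame_ids = seq$frame_ids),
      class = "slice_sequence")
  })
}

#' Construct a template volume object
#'
#' @param data 3D numeric array (x, y, z).
#' @param affine 4 x 4 matrix copied from the source sequence.
#' @param provenance List of parameters and frame ids used in the build.
#' @return A list of class `template_volume`.
#' @export
template_volume <- function(data, affine = diag(4), provenance = list()) {
  if (length(dim(data)) != 3) stop("template data must be 3D")
  structure(list(data = data, affine = affine, provenance = provenance),
            class = "template_volume")
}

#' Write a template volume as NIfTI
#'
#' Stores the fused template as float32 with the source affine (sform and
#' qform), so a reload reproduces the data to float32 precision and the
#' affine exactly.
#'
#' @param tpl A `template_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_template <- function(tpl, path) {
  stopifnot(inherits(tpl, "template_volume"))
  img <- RNifti::asNifti(tpl$data, datatype = "float")
  # qform is left unset: RNifti recomputes pixdim from the qform and then
  # renormalises the srow entries, which corrupts anisotropic affines
  img <- RNifti::`sform<-`(img, structure(tpl$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Export template layers as 8-bit grayscale PNGs
#'
#' Intensities are min-max scaled over the whole volume; a
#' zero-dynamic-range volume exports all-zero images.
#'
#' @param tpl A `template_volume`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, one per layer.
#' @export
export_slices_png <- function(tpl, dir) {
  stopifnot(inherits(tpl, "template_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scaled <- normalize01(tpl$data)
  nz <- dim(tpl$data)[3]
  paths <- character(nz)
  for (k in seq_len(nz)) {
    paths[k] <- file.path(dir, sprintf("slice_%03d.png", k - 1L))
    # PNG rows run along y so the slice is transposed on write
    png::writePNG(t(scaled[, , k]), paths[k])
  }
  paths
}

#' Read a motion-parameter table
#'
#' Whitespace-delimited text, one row per frame, 6 columns: 3
#' translations (mm) then 3 rotations (degrees).
#'
#' @param path Text file path.
#' @return Numeric matrix with 6 columns.
#' @export
read_motion_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file does not exist: %s", path))
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6)
    stop(sprintf("motion table must have 6 columns, got %d", ncol(m)))
  storage.mode(m) <- "double"
  m
}
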