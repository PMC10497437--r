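#' Read and write NIfTI volumes and cord masks
#'
#' Volumes are stored as 32-bit float NIfTI-1 with voxel spacing in the
#' header; masks as unsigned 8-bit. Reading a mask or a landmark table
#' validates it against the paired volume (grid congruence, binarity,
#' level completeness). The internal axis convention is: third array axis =
#' slices, ordered superior to inferior. Files written by this package
#' round-trip exactly; for externally produced files whose slice axis
#' differs, pass `sliceAxis` to permute on read.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume The paired [VolumeImage-class] used for validation.
#' @param sliceAxis Which input-array axis holds the slices (default 3);
#'   an explicit override for files not following the convention.
#' @return `readVolume`: a [VolumeImage-class]; `readMask`: a
#'   [CordMask-class]; `readLandmarks`: a [LandmarkSet-class].
#' @name imaging-io
NULL

#' @rdname imaging-io
#' @export
readVolume <- function(path, sliceAxis = 3L) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  if (length(dim(v)) != 3L)
    .cordError("ioError", "expected a 3D NIfTI volume, got %dD", length(dim(v)))
  sp <- RNifti::pixdim(img)[1:3]
  if (sliceAxis != 3L) {
    perm <- c(setdiff(1:3, sliceAxis), sliceAxis)
    v <- aperm(v, perm)
    sp <- sp[perm]
  }
  if (any(!is.finite(v)))
    .cordError("ioError", "volume contains non-finite values")
  VolumeImage(v, sp)
}

#' @rdname imaging-io
#' @export
readMask <- function(path, volume, sliceAxis = 3L) {
  raw <- readVolume(path, sliceAxis)
  .checkCongruent(raw, volume)
  mask <- CordMask(raw@values, raw@spacing)   # binarity check inside
  mask
}

#' @param x Object to write ([VolumeImage-class] or [CordMask-class]).
#' @rdname imaging-io
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "VolumeImage"))
  img <- RNifti::asNifti(x@values)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname imaging-io
#' @export
writeMask <- function(x, path) {
  stopifnot(is(x, "CordMask"))
  img <- RNifti::asNifti(x@values)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname imaging-io
#' @export
readLandmarks <- function(path, volume = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("level", "slice") %in% names(tab)))
    .cordError("landmarkError", "landmark CSV needs columns 'level,slice'")
  slices <- tab$slice
  names(slices) <- tab$level
  lm <- LandmarkSet(slices)   # completeness + monotonicity checked inside
  if (!is.null(volume) && any(lm@slices >= nSlices(volume)))
    .cordError("landmarkError",
               "landmark slice beyond volume extent (%d slices)",
               nSlices(volume))
  lm
}

#' @param landmarks A [LandmarkSet-class] to write.
#' @rdname imaging-io
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  utils::write.csv(
    data.frame(level = names(landmarks@slices), slice = landmarks@slices),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-rater binary rating table
#'
#' Expects a CSV with columns `segment_id`, `level`, and one `rater<k>`
#' column per observer (0/1 cells, no missing values).
#'
#' @param path CSV path.
#' @return A [RatingTable-class] with segment ids as row names; the level
#'   of each segment is kept in attribute `"level"`.
#' @export
readRatings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rc <- grep("^rater", names(tab), value = TRUE)
  if (length(rc) < 3L)
    .cordError("ioError", "ratings CSV needs >= 3 rater columns, found %d",
               length(rc))
  m <- as.matrix(tab[, rc])
  if (!is.null(tab$segment_id)) rownames(m) <- tab$segment_id
  rt <- RatingTable(m)
  attr(rt@ratings, "level") <- tab$level
  rt
}

.checkCongruent <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a@values), dim(b@values)))
    .cordError("congruenceError",
               "grid shapes differ: %s vs %s",
               paste(dim(a@values), collapse = "x"),
               paste(dim(b@values), collapse = "x"))
  if (any(abs(a@spacing - b@spacing) > tol))
    .cordError("congruenceError",
               "voxel spacings differ: (%s) vs (%s) mm",
               paste(format(a@spacing), collapse = ", "),
               paste(format(b@spacing), collapse = ", "))
  invisible(TRUE)
}

#' Dice overlap coefficient between two cord masks
#'
#' Computes 2|A∩B| / (|A| + |B|). Two empty masks are in vacuous agreement
#' and score 1 (the class validity forbids constructing an empty
#' [CordMask-class], but raw arrays are accepted too).
#'
#' @param a,b Congruent [CordMask-class] objects or binary arrays of equal
#'   shape.
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' m <- array(0, c(4, 4, 2)); m[2:3, 2:3, ] <- 1
#' diceCoefficient(m, m)  # 1
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "CordMask")) a@values else a
  bv <- if (is(b, "CordMask")) b@values else b
  if (is(a, "CordMask") && is(b, "CordMask")) .checkCongruent(a, b)
  else if (!identical(dim(av), dim(bv)))
    .cordError("congruenceError", "mask shapes differ")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1.0)
  2 * sum(av * bv) / (sa + sb)
}
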