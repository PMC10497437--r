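#' Accessors for voxel grids and derived objects
#'
#' `gridValues` returns the raw 3D array, `voxelSpacing` the voxel edge
#' lengths in mm, `gridDim` the grid dimensions, and `nSlices` the number of
#' axial slices (third axis).
#'
#' @param x A [VolumeImage-class], [CordMask-class] or other grid object.
#' @return The corresponding slot value.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname grid-accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname grid-accessors
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname grid-accessors
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname grid-accessors
#' @export
setMethod("gridDim", "VoxelGrid", function(x) dim(x@values))

#' @rdname grid-accessors
#' @export
setMethod("nSlices", "VoxelGrid", function(x) dim(x@values)[3L])

#' Landmark slice indices
#'
#' @param x A [LandmarkSet-class].
#' @return Named integer vector of 0-based body-center slice indices C2..C7.
#' @export
setGeneric("landmarkSlices", function(x) standardGeneric("landmarkSlices"))

#' @rdname landmarkSlices
#' @export
setMethod("landmarkSlices", "LandmarkSet", function(x) x@slices)

#' Rating-table accessors
#'
#' @param x A [RatingTable-class].
#' @return `ratings`: the integer 0/1 matrix; `nRaters`/`nSegments`: counts.
#' @name rating-accessors
NULL

#' @rdname rating-accessors
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @rdname rating-accessors
#' @export
setMethod("ratings", "RatingTable", function(x) x@ratings)

#' @rdname rating-accessors
#' @export
setGeneric("nRaters", function(x) standardGeneric("nRaters"))

#' @rdname rating-accessors
#' @export
setMethod("nRaters", "RatingTable", function(x) ncol(x@ratings))

#' @rdname rating-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname rating-accessors
#' @export
setMethod("nSegments", "RatingTable", function(x) nrow(x@ratings))

#' Area under the ROC curve
#'
#' @param x A [RocResult-class].
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname auc
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeImage %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g] a.u.\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "CordMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("CordMask %d x %d x %d voxels, spacing %s mm, %d cord voxels\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = " x "),
              as.integer(sum(object@values))))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet (0-based body-center slices):\n")
  print(object@slices)
})

setMethod("show", "SICurve", function(object) {
  def <- sum(!is.na(object@meanSI))
  cat(sprintf("SICurve '%s': %d slices (%d with cord), CSA %.2f-%.2f mm^2\n",
              object@subject, length(object@slice), def,
              min(object@csa[object@csa > 0]), max(object@csa)))
})

setMethod("show", "RatingTable", function(object) {
  cat(sprintf("RatingTable: %d segments x %d raters, %d unanimous rows\n",
              nrow(object@ratings), ncol(object@ratings),
              sum(apply(object@ratings, 1L, function(r) all(r == r[1L])))))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: %d thresholds (direction '%s'), AUC %.4f (%s)\n",
              length(object@thresholds), object@direction, object@auc,
              aucCategory(object@auc)))
})

#' Coerce an SICurve to a data frame
#'
#' @param x An [SICurve-class].
#' @param ... Ignored.
#' @return A data frame with columns `slice`, `csa_mm2`, `mean_si_au`.
#' @export
as.data.frame.SICurve <- function(x, ...) {
  data.frame(slice = x@slice, csa_mm2 = x@csa, mean_si_au = x@meanSI)
}

#' Qualitative AUC band
#'
#' Labels an AUC with the conventional qualitative band: 0.8-0.9 is
#' "excellent" and above 0.9 "outstanding" discrimination.
#'
#' @param x AUC value in \[0, 1\].
#' @return Character scalar.
#' @export
aucCategory <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
  if (x > 0.9) "outstanding"
  else if (x >= 0.8) "excellent"
  else if (x >= 0.7) "acceptable"
  else "poor"
}
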