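#' @import methods
NULL

## Classed conditions so callers can distinguish failure modes
.cordError <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "cordT2Error")))
}

.cordWarning <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "cordT2Warning")))
}

#' Virtual parent for voxel grids
#'
#' Holds a 3D value array with physical voxel spacing in mm. The third array
#' axis is the slice axis, ordered superior to inferior (C2 at low index).
#'
#' @slot values 3D numeric array.
#' @slot spacing Numeric triple, voxel edge lengths in mm (x, y, z).
#' @keywords internal
setClass("VoxelGrid", representation("VIRTUAL",
  values = "array",
  spacing = "numeric"
))

setValidity("VoxelGrid", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive finite values (mm)")
  TRUE
})

#' 3D intensity volume in arbitrary units
#'
#' The raw T2-weighted MRI stand-in: a scalar intensity field in arbitrary
#' units (a.u.) on an anisotropic voxel grid. Slice axis is the third array
#' axis, superior to inferior.
#'
#' @slot values 3D numeric array of intensities (a.u.), all finite.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("VolumeImage", contains = "VoxelGrid")

setValidity("VolumeImage", function(object) {
  if (any(!is.finite(object@values)))
    return("volume values must all be finite")
  TRUE
})

#' Binary spinal-cord mask
#'
#' A binary grid congruent to a [VolumeImage] marking spinal-cord voxels.
#'
#' @slot values 3D array with values in \{0, 1\}.
#' @slot spacing Voxel spacing in mm.
#' @export
setClass("CordMask", contains = "VoxelGrid")

setValidity("CordMask", function(object) {
  v <- object@values
  if (any(!(v %in% c(0, 1))))
    return("mask values must be 0 or 1")
  if (sum(v) < 1)
    return("mask must contain at least one voxel")
  TRUE
})

#' Construct a VolumeImage
#'
#' @param values 3D numeric array of intensities (a.u.).
#' @param spacing Numeric triple of voxel edge lengths in mm; default the
#'   reference acquisition grid 0.6 x 0.6 x 1.0 mm.
#' @return A [VolumeImage-class] object.
#' @export
VolumeImage <- function(values, spacing = c(0.6, 0.6, 1.0)) {
  new("VolumeImage", values = values, spacing = as.numeric(spacing))
}

#' Construct a CordMask
#'
#' @param values 3D array coercible to binary; values must round to 0/1
#'   within 1e-6.
#' @param spacing Numeric triple of voxel edge lengths in mm.
#' @return A [CordMask-class] object.
#' @export
CordMask <- function(values, spacing = c(0.6, 0.6, 1.0)) {
  r <- round(values)
  if (any(abs(values - r) > 1e-6) || any(!(r %in% c(0, 1))))
    .cordError("maskError", "mask values are not binary within tolerance 1e-6")
  storage.mode(r) <- "double"
  new("CordMask", values = r, spacing = as.numeric(spacing))
}

.CERVICAL_BODIES <- c("C2", "C3", "C4", "C5", "C6", "C7")
.CERVICAL_LEVELS <- c("C2/3", "C3/4", "C4/5", "C5/6", "C6/7")

#' Vertebral-body landmark set
#'
#' One slice index per vertebral body center, C2 through C7, on the slice
#' axis of the paired volume. Indices are 0-based and strictly increasing
#' (superior to inferior).
#'
#' @slot slices Named integer vector with names C2..C7.
#' @export
setClass("LandmarkSet", representation(slices = "integer"))

setValidity("LandmarkSet", function(object) {
  s <- object@slices
  if (!identical(names(s), .CERVICAL_BODIES))
    return(sprintf("landmarks must be exactly %s in order",
                   paste(.CERVICAL_BODIES, collapse = ", ")))
  if (any(s < 0L)) return("slice indices must be >= 0 (0-based)")
  if (any(diff(s) <= 0L)) return("slice indices must be strictly increasing")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param slices Named numeric/integer vector of 0-based body-center slice
#'   indices; must contain exactly C2..C7. Fractional values are rounded
#'   half-down so adjacent half-open level intervals stay disjoint.
#' @return A [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(slices) {
  miss <- setdiff(.CERVICAL_BODIES, names(slices))
  if (length(miss))
    .cordError("landmarkError", "missing vertebral landmark(s): %s",
               paste(miss, collapse = ", "))
  s <- slices[.CERVICAL_BODIES]
  s <- as.integer(ceiling(s - 0.5))  # round half-down
  names(s) <- .CERVICAL_BODIES
  new("LandmarkSet", slices = s)
}

#' Slice-wise signal-intensity curve
#'
#' Per-slice cross-sectional area (CSA, mm^2) and mean T2 signal intensity
#' (a.u.) along the superior-inferior axis. Slices where the mask is empty
#' have CSA 0 and an undefined (NA) mean.
#'
#' @slot slice Integer vector of 0-based slice indices.
#' @slot csa Numeric vector, CSA in mm^2 (voxel count times in-plane area).
#' @slot meanSI Numeric vector, slice-mean T2-SI in a.u.; NA where CSA = 0.
#' @slot subject Character scalar, provenance identifier.
#' @export
setClass("SICurve", representation(
  slice = "integer", csa = "numeric", meanSI = "numeric", subject = "character"
))

setValidity("SICurve", function(object) {
  n <- length(object@slice)
  if (length(object@csa) != n || length(object@meanSI) != n)
    return("slice, csa and meanSI must have equal length")
  if (any(object@csa < 0)) return("csa must be non-negative")
  bad <- xor(object@csa > 0, !is.na(object@meanSI))
  if (any(bad)) return("meanSI must be defined exactly where csa > 0")
  TRUE
})

#' ROC analysis result
#'
#' Thresholds with sensitivity/specificity pairs and the area under the
#' curve. A positive call is score >= threshold ("greater" orientation) or
#' score <= threshold ("less"). Thresholds include a sentinel that calls
#' nothing positive, so the ROC curve always reaches (0, 0).
#'
#' @slot thresholds Sorted unique score values plus the sentinel.
#' @slot sensitivity Sensitivity at each threshold.
#' @slot specificity Specificity at each threshold.
#' @slot auc Area under the ROC curve (trapezoid; equals the midrank
#'   Mann-Whitney U divided by n1*n0).
#' @slot direction "greater" or "less".
#' @export
setClass("RocResult", representation(
  thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
  auc = "numeric", direction = "character"
))

#' Multi-rater binary rating table
#'
#' Rows are rated segments (subject x cervical level), columns are raters.
#' Cells are 0 (T2-negative) or 1 (T2-positive). An odd rater count (>= 3)
#' guarantees a strict majority consensus.
#'
#' @slot ratings Integer matrix in \{0, 1\}, no missing cells.
#' @export
setClass("RatingTable", representation(ratings = "matrix"))

setValidity("RatingTable", function(object) {
  r <- object@ratings
  if (nrow(r) < 1L) return("rating table must have at least one segment row")
  if (ncol(r) < 3L) return("at least 3 raters are required")
  if (ncol(r) %% 2L == 0L)
    return("rater count must be odd to guarantee strict majority")
  if (any(is.na(r))) return("rating table must have no missing cells")
  if (any(!(r %in% c(0L, 1L)))) return("ratings must be 0 or 1")
  TRUE
})

#' Construct a RatingTable
#'
#' @param ratings Matrix or data frame of 0/1 ratings, one column per rater,
#'   one row per segment. Row names, if present, are kept as segment ids.
#' @return A [RatingTable-class] object.
#' @export
RatingTable <- function(ratings) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "integer"
  new("RatingTable", ratings = m)
}

#' Focal hyperintense lesion specification
#'
#' An intramedullary lesion modeled as a separable field added to the cord:
#' a Gaussian profile along the cord axis times a radial in-plane profile
#' whose demarcation is controlled by `sharpness` (1 = sharply delineated,
#' "snake-eye"-like; small values = blurry).
#'
#' @slot centerSlice Integer, 0-based slice of the lesion center.
#' @slot axialSigma Positive real, Gaussian sigma along the axis (slices).
#' @slot amplitude Real >= 0, peak added intensity as a fraction of the cord
#'   baseline.
#' @slot sharpness Real in (0, 1]; shapes the in-plane edge.
#' @slot offset Length-2 numeric, in-plane offset from the cord axis (mm).
#' @slot radius Positive real, in-plane lesion radius (mm).
#' @export
setClass("LesionSpec", representation(
  centerSlice = "integer", axialSigma = "numeric", amplitude = "numeric",
  sharpness = "numeric", offset = "numeric", radius = "numeric"
))

setValidity("LesionSpec", function(object) {
  if (object@axialSigma <= 0) return("axialSigma must be > 0")
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@sharpness <= 0 || object@sharpness > 1)
    return("sharpness must be in (0, 1]")
  if (length(object@offset) != 2L) return("offset must have length 2")
  if (object@radius <= 0) return("radius must be > 0")
  TRUE
})

#' @param centerSlice,axialSigma,amplitude,sharpness,offset,radius See slots.
#' @rdname LesionSpec-class
#' @export
LesionSpec <- function(centerSlice, axialSigma = 4, amplitude = 0.5,
                       sharpness = 1, offset = c(0, 0), radius = 2) {
  new("LesionSpec", centerSlice = as.integer(centerSlice),
      axialSigma = axialSigma, amplitude = amplitude, sharpness = sharpness,
      offset = as.numeric(offset), radius = radius)
}

#' Synthetic cervical-spine phantom specification
#'
#' Defines a tubular spinal cord of constant baseline intensity surrounded
#' by a bright CSF sheath and darker background tissue, with vertebral
#' landmarks, optional focal lesions, Rician noise, and a per-subject global
#' intensity scale standing in for scanner arbitrariness.
#'
#' @slot dim Integer triple: in-plane x in-plane x slices.
#' @slot spacing Voxel spacing in mm.
#' @slot cordRadius Cord tube radius in mm.
#' @slot baseline Cord baseline intensity (a.u.).
#' @slot background Surrounding-tissue intensity (a.u.).
#' @slot csf CSF sheath intensity (a.u.), T2-bright.
#' @slot csfThickness CSF sheath thickness (mm).
#' @slot landmarks Named integer vector C2..C7 of body-center slice indices.
#' @slot lesions List of [LesionSpec-class].
#' @slot noiseSigma Rician noise scale (a.u.), >= 0.
#' @slot noiseModel "rician" (magnitude-MRI convention) or "gaussian".
#' @slot globalScale Positive per-subject intensity scale factor.
#' @slot centralCanal Logical; add a thin bright central-canal tube.
#' @slot canalRadius Central canal radius (mm), used when centralCanal.
#' @slot seed Integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  dim = "integer", spacing = "numeric", cordRadius = "numeric",
  baseline = "numeric", background = "numeric", csf = "numeric",
  csfThickness = "numeric", landmarks = "integer", lesions = "list",
  noiseSigma = "numeric", noiseModel = "character", globalScale = "numeric",
  centralCanal = "logical", canalRadius = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be three integers >= 4")
  if (any(object@spacing <= 0)) return("spacing entries must be > 0")
  if (object@cordRadius <= 0) return("cordRadius must be > 0")
  half <- min((object@dim[1:2] / 2 - 1) * object@spacing[1:2])
  if (object@cordRadius + object@csfThickness >= half)
    return("cord tube (incl. CSF sheath) must fit fully in-plane")
  if (object@baseline <= 0) return("baseline must be > 0")
  if (object@background < 0) return("background must be >= 0")
  if (object@csf <= 0) return("csf must be > 0")
  lm <- object@landmarks
  if (!identical(names(lm), .CERVICAL_BODIES))
    return("landmarks must be exactly C2..C7")
  if (any(diff(lm) <= 0L)) return("landmark slices must be strictly increasing")
  if (any(lm < 0L) || any(lm >= object@dim[3L]))
    return("landmark slices must lie inside the grid")
  for (l in object@lesions) {
    if (!is(l, "LesionSpec")) return("lesions must be LesionSpec objects")
    v <- validObject(l, test = TRUE)
    if (is.character(v)) return(v)
    if (l@centerSlice < 0L || l@centerSlice >= object@dim[3L])
      return("lesion centerSlice must lie inside the grid")
  }
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("rician", "gaussian"))
    return("noiseModel must be 'rician' or 'gaussian'")
  if (object@globalScale <= 0) return("globalScale must be > 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the reference acquisition: 0.6 x 0.6 x 1.0 mm voxels, a
#' 4 mm radius cord at ~250 a.u. baseline, vertebral body centers every 18
#' slices so every disc level spans 18 slices.
#'
#' @param dim,spacing,cordRadius,baseline,background,csf,csfThickness,landmarks,lesions,noiseSigma,noiseModel,globalScale,centralCanal,canalRadius,seed
#'   See the class slots.
#' @return A validated [PhantomSpec-class].
#' @export
PhantomSpec <- function(dim = c(64L, 64L, 120L), spacing = c(0.6, 0.6, 1.0),
                        cordRadius = 4.0, baseline = 250, background = 60,
                        csf = 420, csfThickness = 1.2,
                        landmarks = c(C2 = 10L, C3 = 28L, C4 = 46L,
                                      C5 = 64L, C6 = 82L, C7 = 100L),
                        lesions = list(), noiseSigma = 0,
                        noiseModel = "rician", globalScale = 1,
                        centralCanal = FALSE, canalRadius = 0.6,
                        seed = 1L) {
  lm <- as.integer(landmarks)
  names(lm) <- names(landmarks)
  tryCatch(
    new("PhantomSpec", dim = as.integer(dim),
        spacing = as.numeric(spacing), cordRadius = cordRadius,
        baseline = baseline, background = background, csf = csf,
        csfThickness = csfThickness, landmarks = lm, lesions = lesions,
        noiseSigma = noiseSigma, noiseModel = noiseModel,
        globalScale = globalScale, centralCanal = centralCanal,
        canalRadius = canalRadius, seed = as.integer(seed)),
    error = function(e)
      .cordError("specError", "invalid PhantomSpec: %s", conditionMessage(e)))
}
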