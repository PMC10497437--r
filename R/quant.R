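#' Extract the slice-wise T2 signal-intensity curve
#'
#' For every axial slice, computes the cord cross-sectional area (CSA,
#' voxel count times in-plane voxel area, mm^2) and the arithmetic mean of
#' the volume intensities over the cord-mask voxels of that slice (the
#' slice-mean T2-SI, in arbitrary units). Slices where the mask is empty
#' are flagged undefined (NA), not zero.
#'
#' @param volume A [VolumeImage-class].
#' @param mask A congruent [CordMask-class].
#' @param subject Provenance identifier carried by the curve.
#' @return An [SICurve-class].
#' @examples
#' ph <- generatePhantom(PhantomSpec())
#' curve <- extractSICurve(ph$volume, ph$mask)
#' head(as.data.frame(curve))
#' @export
extractSICurve <- function(volume, mask, subject = "subject") {
  stopifnot(is(volume, "VolumeImage"), is(mask, "CordMask"))
  .checkCongruent(volume, mask)
  d <- dim(volume@values)
  mv <- matrix(mask@values, ncol = d[3L])
  vv <- matrix(volume@values, ncol = d[3L])
  counts <- colSums(mv)
  if (sum(counts) == 0)
    .cordError("quantError", "cord mask is empty")
  sums <- colSums(vv * mv)
  csa <- counts * volume@spacing[1L] * volume@spacing[2L]
  meanSI <- ifelse(counts > 0, sums / counts, NA_real_)
  new("SICurve", slice = seq_len(d[3L]) - 1L, csa = csa, meanSI = meanSI,
      subject = subject)
}

#' Subdivide the cord span into cervical disc-level intervals
#'
#' Each disc level (C2/3 ... C6/7) spans from the center of its upper
#' vertebral body to the center of the lower one, as half-open slice
#' intervals \[center(Ck), center(Ck+1)). The five intervals tile
#' \[center(C2), center(C7)) with no gaps or overlaps, so no slice is
#' counted in two levels.
#'
#' @param curve An [SICurve-class] (used to verify every interval holds at
#'   least 2 slices with a defined mean).
#' @param landmarks A [LandmarkSet-class].
#' @return Data frame with columns `level`, `start`, `end` (0-based,
#'   half-open) and `n_defined`.
#' @export
subdivideSegments <- function(curve, landmarks) {
  stopifnot(is(curve, "SICurve"), is(landmarks, "LandmarkSet"))
  s <- landmarks@slices
  if (max(s) > max(curve@slice) + 1L)
    .cordError("landmarkError", "landmarks extend beyond the curve")
  out <- data.frame(level = .CERVICAL_LEVELS,
                    start = s[-length(s)], end = s[-1L],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$n_defined <- vapply(seq_len(nrow(out)), function(i) {
    idx <- curve@slice >= out$start[i] & curve@slice < out$end[i]
    sum(!is.na(curve@meanSI[idx]))
  }, 1L)
  thin <- out$n_defined < 2L
  if (any(thin))
    .cordError("segmentTooThinError",
               "level %s has fewer than 2 slices with defined mean",
               paste(out$level[thin], collapse = ", "))
  out
}

#' Per-segment signal statistics and the T2 myelopathy index
#'
#' Over the slice means of one disc-level interval, computes the mean, SD
#' and range (max - min) of the T2-SI, and the T2 myelopathy index
#'
#'   T2-MI = T2-SI range x 100 / T2-SI mean  (percent),
#'
#' a scale-invariant variability measure: multiplying the whole volume by
#' any positive factor leaves T2-MI unchanged, which makes it comparable
#' across scans whose absolute arbitrary units are not.
#'
#' @param curve An [SICurve-class].
#' @param start,end Half-open 0-based slice interval \[start, end).
#' @param level Level label attached to the result.
#' @param sdDenominator `"n-1"` (sample SD, default) or `"n"`.
#' @return One-row data frame: `level`, `start`, `end`, `n_slices`,
#'   `mean_au`, `sd_au`, `range_au`, `t2_mi_percent`.
#' @examples
#' # slice means 240/250/260 -> mean 250, SD 10, range 20, T2-MI 8%
#' cv <- new("SICurve", slice = 0:2, csa = rep(0.36, 3),
#'           meanSI = c(240, 250, 260), subject = "ex")
#' segmentStatistics(cv, 0, 3, "C2/3")
#' @export
segmentStatistics <- function(curve, start, end, level = NA_character_,
                              sdDenominator = c("n-1", "n")) {
  stopifnot(is(curve, "SICurve"), end > start)
  sdDenominator <- match.arg(sdDenominator)
  idx <- curve@slice >= start & curve@slice < end
  m <- curve@meanSI[idx]
  nEmpty <- sum(is.na(m))
  if (nEmpty / max(length(m), 1L) > 0.2)
    .cordWarning("emptySliceWarning",
                 "level %s: %d of %d slices have an empty mask (excluded)",
                 level, nEmpty, length(m))
  m <- m[!is.na(m)]
  if (length(m) < 2L)
    .cordError("segmentTooThinError",
               "level %s has fewer than 2 slices with defined mean", level)
  mu <- mean(m)
  if (mu <= 0)
    .cordError("t2miUndefinedError",
               "level %s: non-positive mean T2-SI, T2-MI undefined", level)
  s <- stats::sd(m)
  if (sdDenominator == "n") s <- s * sqrt((length(m) - 1) / length(m))
  rg <- max(m) - min(m)
  data.frame(level = level, start = start, end = end, n_slices = length(m),
             mean_au = mu, sd_au = s, range_au = rg,
             t2_mi_percent = rg * 100 / mu,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify one subject: five disc-level statistics from C2/3 to C6/7
#'
#' Runs the full per-subject quantification: slice-wise SI curve, level
#' subdivision by vertebral body centers, and per-level statistics
#' including T2-MI.
#'
#' @param volume A [VolumeImage-class].
#' @param mask A congruent [CordMask-class].
#' @param landmarks A [LandmarkSet-class].
#' @param subject Subject identifier attached to the rows.
#' @param sdDenominator Passed to [segmentStatistics()].
#' @return Data frame with five rows (C2/3 ... C6/7) and the columns of
#'   [segmentStatistics()] plus `subject`.
#' @examples
#' ph <- generatePhantom(PhantomSpec(lesions = list(LesionSpec(73))))
#' quantifySubject(ph$volume, ph$mask, ph$landmarks, "case01")
#' @export
quantifySubject <- function(volume, mask, landmarks, subject = "subject",
                            sdDenominator = c("n-1", "n")) {
  sdDenominator <- match.arg(sdDenominator)
  curve <- extractSICurve(volume, mask, subject)
  segs <- subdivideSegments(curve, landmarks)
  out <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    tryCatch(
      segmentStatistics(curve, segs$start[i], segs$end[i], segs$level[i],
                        sdDenominator),
      cordT2Error = function(e) {
        stop(errorCondition(
          sprintf("subject %s, level %s: %s", subject, segs$level[i],
                  conditionMessage(e)),
          class = class(e)))
      })
  }))
  out$subject <- subject
  out[, c("subject", setdiff(names(out), "subject"))]
}

#' Write an SI curve or segment-statistics table to CSV
#'
#' Curves get columns `slice,csa_mm2,mean_si_au`; statistics tables are
#' written as-is (`level,mean_au,sd_au,range_au,t2_mi_percent,...`).
#'
#' @param x An [SICurve-class] or a data frame.
#' @param path Output CSV path.
#' @export
writeCurve <- function(x, path) {
  df <- if (is(x, "SICurve")) as.data.frame(x) else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
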