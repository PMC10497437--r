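#' Majority consensus of multi-rater binary ratings
#'
#' With an odd rater count a strict majority always exists; the consensus
#' label of each segment is the category chosen by more than half of the
#' raters.
#'
#' @param table A [RatingTable-class] (odd rater count enforced by the
#'   class validity).
#' @return Integer vector of 0/1 consensus labels, one per segment.
#' @examples
#' rt <- RatingTable(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0)))
#' consensusRatings(rt)  # 1 0 0
#' @export
consensusRatings <- function(table) {
  stopifnot(is(table, "RatingTable"))
  as.integer(rowSums(table@ratings) > ncol(table@ratings) / 2)
}

#' Percent absolute agreement
#'
#' The percentage of segments on which all raters gave the identical
#' category, reported to one decimal (the conventional reporting
#' precision).
#'
#' @param table A [RatingTable-class].
#' @param digits Rounding digits for the reported percentage (default 1).
#' @return Numeric percentage in \[0, 100\].
#' @examples
#' rt <- RatingTable(rbind(c(1, 1, 1), c(1, 0, 1), c(0, 0, 0), c(0, 1, 1)))
#' percentAgreement(rt)  # 50.0
#' @export
percentAgreement <- function(table, digits = 1L) {
  stopifnot(is(table, "RatingTable"))
  r <- table@ratings
  unan <- rowSums(r == r[, 1L]) == ncol(r)
  round(100 * mean(unan), digits)
}

#' Fleiss' kappa for nominal multi-rater agreement
#'
#' Chance-corrected agreement for n raters assigning nominal categories:
#' kappa = (Pbar - Pe) / (1 - Pe), where Pbar is the mean pairwise
#' agreement per segment and Pe the chance agreement from the marginal
#' category proportions. Written for the binary T2-positive/negative scheme
#' but accepts any number of categories.
#'
#' @param table A [RatingTable-class], or an integer matrix of category
#'   codes (rows = subjects, columns = raters; equal rater count per row).
#' @param categories Optional vector of all category codes (so categories
#'   absent from the data still enter with proportion 0).
#' @return Kappa in \[-1, 1\], or `NA` when every cell is one category
#'   (chance agreement Pe = 1; kappa undefined).
#' @examples
#' rt <- RatingTable(rbind(c(1, 1, 1), c(0, 0, 0)))
#' fleissKappa(rt)  # 1: unanimous with both categories present
#' @export
fleissKappa <- function(table, categories = NULL) {
  m <- if (is(table, "RatingTable")) table@ratings else as.matrix(table)
  if (nrow(m) < 2L) .cordError("inputError", "need >= 2 rated segments")
  if (ncol(m) < 2L) .cordError("inputError", "need >= 2 raters")
  if (is.null(categories)) categories <- sort(unique(as.vector(m)))
  N <- nrow(m); n <- ncol(m)
  # n_ij: raters assigning category j to segment i
  nij <- vapply(categories, function(cat) rowSums(m == cat), numeric(N))
  nij <- matrix(nij, nrow = N)
  Pi <- (rowSums(nij^2) - n) / (n * (n - 1))
  pj <- colSums(nij) / (N * n)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < .Machine$double.eps * 8) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}
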