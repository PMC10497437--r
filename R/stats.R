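#' Age- and level-matched control assignment
#'
#' Builds a matched control set for positive case segments out of a healthy
#' volunteer pool: within each cervical level, cases are processed in
#' ascending age order and each receives the still-unused volunteer segment
#' at the same level minimizing the absolute age difference. Deterministic:
#' ties in age difference (and in case ordering) are broken by the lower
#' subject identifier. Each control segment is used at most once; a
#' volunteer may serve at several levels.
#'
#' @param cases Data frame with columns `subject`, `level`, `age`.
#' @param pool Data frame with the same columns (volunteer segments).
#' @return Data frame with one row per case: `case_subject`,
#'   `control_subject`, `level`, `case_age`, `control_age`, `age_diff`.
#' @examples
#' cases <- data.frame(subject = "p1", level = "C5/6", age = 60)
#' pool <- data.frame(subject = c("v1", "v2"), level = "C5/6",
#'                    age = c(58, 63))
#' matchControls(cases, pool)  # picks v1 (|58-60| = 2 < 3)
#' @export
matchControls <- function(cases, pool) {
  need <- c("subject", "level", "age")
  stopifnot(all(need %in% names(cases)), all(need %in% names(pool)))
  if (nrow(cases) == 0L)
    return(data.frame(case_subject = character(), control_subject = character(),
                      level = character(), case_age = numeric(),
                      control_age = numeric(), age_diff = numeric()))
  out <- vector("list", nrow(cases))
  k <- 0L
  for (lev in unique(cases$level)) {
    cs <- cases[cases$level == lev, , drop = FALSE]
    cs <- cs[order(cs$age, as.character(cs$subject)), , drop = FALSE]
    avail <- pool[pool$level == lev, , drop = FALSE]
    for (i in seq_len(nrow(cs))) {
      if (nrow(avail) == 0L)
        .cordError("matchingError",
                   "control pool exhausted at level %s", lev)
      d <- abs(avail$age - cs$age[i])
      j <- order(d, as.character(avail$subject))[1L]
      k <- k + 1L
      out[[k]] <- data.frame(
        case_subject = as.character(cs$subject[i]),
        control_subject = as.character(avail$subject[j]),
        level = lev, case_age = cs$age[i], control_age = avail$age[j],
        age_diff = d[j], stringsAsFactors = FALSE)
      avail <- avail[-j, , drop = FALSE]
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Mann-Whitney U test for two unpaired samples
#'
#' U is computed by midranks (ties contribute 1/2 per tied pair). The
#' two-sided p-value is exact (from the exact null distribution of U,
#' equivalent to enumerating all labelings) whenever `n_x * n_y <= 400`
#' and the pooled sample is tie-free; otherwise a normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `U` (for sample `x`), `p.value` (two-sided), and
#'   `exact` (logical, which route was taken).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y))
    .cordError("inputError", "both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- nx * ny <= 400 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(U), p.value = unname(wt$p.value), exact = exact)
}

#' Exact binomial test (two-sided)
#'
#' Two-sided p-value summing the probabilities of all outcomes no more
#' likely than the observed count under Binomial(n, p0) (the point-mass
#' method).
#'
#' @param k Observed successes, integer in \[0, n\].
#' @param n Number of trials, positive integer.
#' @param p0 Null success probability in (0, 1).
#' @return Two-sided p-value.
#' @examples
#' exactBinomialTest(0, 5, 0.5)  # 2/32 = 0.0625
#' @export
exactBinomialTest <- function(k, n, p0 = 0.5) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    .cordError("inputError", "need integers 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1)
    .cordError("inputError", "p0 must lie strictly between 0 and 1")
  stats::binom.test(k, n, p0)$p.value
}

#' Median and interquartile range
#'
#' Median and IQR (Q3 - Q1) with linear interpolation between order
#' statistics (quantile type 7), the rule used for all median (IQR)
#' reporting in this package.
#'
#' @param x Nonempty numeric sample.
#' @return List with `median`, `iqr`, `q1`, `q3`.
#' @export
summarizeMedianIQR <- function(x) {
  if (!length(x)) .cordError("inputError", "sample must be nonempty")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], iqr = q[3L] - q[1L], q1 = q[1L], q3 = q[3L])
}
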