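# Compact phantom used throughout the suite: 32x32x72 grid, body centers
# every 11 slices so each disc level spans 11 slices.
smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(
    dim = c(32L, 32L, 72L),
    landmarks = c(C2 = 6L, C3 = 17L, C4 = 28L, C5 = 39L, C6 = 50L, C7 = 61L)
  )
  do.call(PhantomSpec, utils::modifyList(defaults, args))
}

# Independent brute-force slice statistics: plain scalar loops over voxels,
# no reuse of the package's vectorized path.
bruteSliceMeans <- function(volArr, maskArr) {
  d <- dim(volArr)
  out <- rep(NA_real_, d[3])
  for (k in seq_len(d[3])) {
    s <- 0; n <- 0L
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (maskArr[i, j, k] == 1) { s <- s + volArr[i, j, k]; n <- n + 1L }
    }
    if (n > 0L) out[k] <- s / n
  }
  out
}

# Textbook Fleiss kappa, computed through pairwise rater agreement loops.
bruteFleissKappa <- function(m) {
  N <- nrow(m); n <- ncol(m)
  agree <- numeric(N)
  for (i in seq_len(N)) {
    cnt <- 0L
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b && m[i, a] == m[i, b]) cnt <- cnt + 1L
    }
    agree[i] <- cnt / (n * (n - 1))
  }
  cats <- sort(unique(as.vector(m)))
  pj <- vapply(cats, function(cc) sum(m == cc), 1) / (N * n)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-14) return(NA_real_)
  (mean(agree) - Pe) / (1 - Pe)
}

# Exact two-sided Mann-Whitney p by literal enumeration of all labelings.
bruteMWP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  combos <- utils::combn(n, nx)
  Us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
}

# Two-sided exact binomial p by summation over all n+1 outcomes.
bruteBinomP <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Type-7 quantile by hand: linear interpolation between order statistics.
bruteQuantile7 <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
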