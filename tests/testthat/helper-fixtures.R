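# Small in-code fixtures shared across test files.

# a trait table with a controllable cell layout: sites_n is a named list
# species -> named integer vector site -> n individuals
make_obs <- function(sites_n, trait = "wood_density", seed = 42) {
  set.seed(seed)
  rows <- lapply(names(sites_n), function(sp) {
    ns <- sites_n[[sp]]
    do.call(rbind, lapply(names(ns), function(si) {
      data.frame(site = si, species = sp, trait = trait,
                 value = exp(rnorm(ns[[si]], 0, 0.3)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# independent two-pass implementation of the n-1-denominator variance of logs
oracle_itv_star <- function(values) {
  lv <- log(values)
  m <- 0
  for (v in lv) m <- m + v
  m <- m / length(lv)
  s <- 0
  for (v in lv) s <- s + (v - m)^2
  s / (length(lv) - 1)
}

# brute-force per-cell TRI: explicit double loop over the 8-neighborhood
oracle_tri <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    ds <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(z[ii, jj])) next
      ds <- c(ds, abs(z[i, j] - z[ii, jj]))
    }
    if (length(ds)) out[i, j] <- mean(ds)
  }
  out
}

# type-7 (linear interpolation) quantile written out by hand
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exact OLS-based AIC of a predictor subset, for selection oracles
oracle_aic_ols <- function(X, y, subset) {
  n <- length(y)
  Xa <- if (length(subset)) cbind(1, X[, subset, drop = FALSE]) else
    matrix(1, n, 1)
  rss <- sum(qr.resid(qr(Xa), y)^2)
  k <- ncol(Xa) + 1
  n * log(2 * pi * rss / n) + n + 2 * k
}
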