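# Independent brute-force oracle implementations (explicit loops, no
# shared code with the package internals), used by the unit and
# acceptance suites.


brute_freq <- function(g, j) {
  col <- g[, j]
  col <- col[!is.na(col)]
  if (length(col) == 0) return(NA_real_)
  sum(col) / (2 * length(col))
}

brute_diversity <- function(g) {
  he <- ho <- sh <- numeric(0)
  for (j in seq_len(ncol(g))) {
    p <- brute_freq(g, j)
    if (is.na(p)) next
    he <- c(he, 2 * p * (1 - p))
    col <- g[, j][!is.na(g[, j])]
    ho <- c(ho, sum(col == 1) / length(col))
    term <- 0
    if (p > 0) term <- term + p * log(p)
    if (p < 1) term <- term + (1 - p) * log(1 - p)
    sh <- c(sh, -term)
  }
  list(he = mean(he), ho = mean(ho), sh = mean(sh),
       fis = (mean(he) - mean(ho)) / mean(he))
}

brute_ir <- function(g) {
  n_ind <- nrow(g)
  out <- rep(NA_real_, n_ind)
  for (i in seq_len(n_ind)) {
    h <- 0; n <- 0; sf <- 0
    for (j in seq_len(ncol(g))) {
      if (is.na(g[i, j])) next
      p <- brute_freq(g, j)
      n <- n + 1
      if (g[i, j] != 1) h <- h + 1
      # frequencies of the two carried allele copies
      if (g[i, j] == 0) sf <- sf + 2 * (1 - p)
      if (g[i, j] == 1) sf <- sf + p + (1 - p)
      if (g[i, j] == 2) sf <- sf + 2 * p
    }
    if (n > 0) out[i] <- (2 * h - sf) / (2 * n - sf)
  }
  out
}



brute_r <- function(g, xy, breaks) {
  n <- nrow(g)
  l <- ncol(g)
  d2 <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    s <- 0; used <- 0
    for (j in seq_len(l)) {
      if (is.na(g[a, j]) || is.na(g[b, j])) next
      s <- s + (g[a, j] - g[b, j])^2
      used <- used + 1
    }
    d2[a, b] <- if (used > 0) s * l / used else NA
  }
  cmat <- matrix(0, n, n)
  rm_ <- rowMeans(d2); gm <- mean(d2)
  for (a in seq_len(n)) for (b in seq_len(n))
    cmat[a, b] <- -0.5 * (d2[a, b] - rm_[a] - rm_[b] + gm)
  geo <- as.matrix(dist(xy))
  k <- length(breaks) - 1
  r <- rep(NA_real_, k)
  for (h in seq_len(k)) {
    num <- den <- 0; any_pair <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      if (geo[a, b] >= breaks[h] && geo[a, b] < breaks[h + 1]) {
        num <- num + cmat[a, b]
        den <- den + cmat[a, a]
        any_pair <- TRUE
      }
    }
    if (any_pair && den > 0) r[h] <- num / den
  }
  r
}

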