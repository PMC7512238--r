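# Independent brute-force oracles used to cross-check the package's
# vectorized / dynamic-programming implementations. Deliberately written
# as plain per-pixel / per-tuple loops with none of the implementation's
# shortcuts.

# Direct per-pixel evaluation of the band rule: sigma over the whole
# image, tile means from the original image, keep iff strictly inside
# x_bar +/- z*sigma/sqrt(n), else replace with the tile statistic.
oracle_ci_filter <- function(img, ia, ja, z, replacement = "mean",
                             band_n = "nominal") {
  mu <- mean(img)
  sigma <- sqrt(mean((img - mu)^2))
  out <- img
  for (r0 in seq(1, nrow(img), by = ia)) {
    for (c0 in seq(1, ncol(img), by = ja)) {
      rows <- r0:min(r0 + ia - 1, nrow(img))
      cols <- c0:min(c0 + ja - 1, ncol(img))
      tile <- img[rows, cols, drop = FALSE]
      xb <- mean(tile)
      n <- if (band_n == "nominal") ia * ja else length(tile)
      half <- z * sigma / sqrt(n)
      rv <- switch(replacement, mean = xb, min = min(tile), max = max(tile))
      for (r in rows) {
        for (cc in cols) {
          v <- img[r, cc]
          out[r, cc] <- if (v < xb + half && v > xb - half) v else rv
        }
      }
    }
  }
  out
}

# Between-class variance computed straight from the definition, looping
# over classes of the partition.
oracle_bcv <- function(counts, thresholds, nbins = length(counts)) {
  p <- counts / sum(counts)
  vals <- (seq_along(counts) - 1) / nbins
  mu_t <- sum(p * vals)
  bounds <- c(-1, thresholds, nbins - 1)   # 0-based sentinels
  s <- 0
  for (k in seq_len(length(thresholds) + 1)) {
    bins <- which(seq_along(counts) - 1 > bounds[k] &
                  seq_along(counts) - 1 <= bounds[k + 1])
    w <- sum(p[bins])
    if (w > 0) {
      mu_k <- sum(p[bins] * vals[bins]) / w
      s <- s + w * (mu_k - mu_t)^2
    }
  }
  s
}

# Within-class variance, for the total-variance decomposition check.
oracle_wcv <- function(counts, thresholds, nbins = length(counts)) {
  p <- counts / sum(counts)
  vals <- (seq_along(counts) - 1) / nbins
  bounds <- c(-1, thresholds, nbins - 1)
  s <- 0
  for (k in seq_len(length(thresholds) + 1)) {
    bins <- which(seq_along(counts) - 1 > bounds[k] &
                  seq_along(counts) - 1 <= bounds[k + 1])
    w <- sum(p[bins])
    if (w > 0) {
      mu_k <- sum(p[bins] * vals[bins]) / w
      s <- s + sum(p[bins] * (vals[bins] - mu_k)^2)
    }
  }
  s
}

# Exhaustive enumeration of every strictly increasing m-tuple of
# thresholds; combn() yields tuples in lexicographic order, so the first
# maximizer is the lexicographically smallest one.
oracle_enum_otsu <- function(counts, m, nbins = length(counts)) {
  cand <- utils::combn(0:(nbins - 2), m)
  vals <- apply(cand, 2, function(ts) oracle_bcv(counts, ts, nbins))
  best <- max(vals)
  list(thresholds = cand[, which(vals >= best - 1e-12)[1]], value = best)
}

# A random histogram with a few populated bins, for property tests.
random_hist <- function(nbins) {
  counts <- integer(nbins)
  k <- sample(2:min(6, nbins), 1)
  bins <- sample.int(nbins, k)
  counts[bins] <- sample.int(50, k, replace = TRUE)
  structure(list(counts = counts, nbins = nbins), class = "gray_histogram")
}

random_image <- function(nr, nc) matrix(stats::runif(nr * nc), nr, nc)
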