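# Multi-level Otsu thresholding, implemented from scratch on the
# intensity histogram. Thresholds are 0-based bin indices; the criterion
# is the between-class variance sigma_B^2 = sum_k w_k (mu_k - mu_T)^2.
#
# The optimum over all strictly increasing m-tuples is found exactly by
# dynamic programming over contiguous bin ranges (equivalent to the
# exhaustive search, at O(m * nbins^2) instead of O(nbins^m)); ties are
# broken by the lexicographically smallest tuple.

#' Intensity histogram of a grayscale image
#'
#' Bin \code{k} (0-based) covers intensities
#' \code{[k/nbins, (k+1)/nbins)}; the last bin is closed above so that
#' intensity 1.0 lands in bin \code{nbins - 1}. The representative
#' intensity of bin \code{k} is its left edge \code{k/nbins}, matching
#' the quantized gray level.
#'
#' @param image Grayscale image matrix.
#' @param nbins Number of bins (>= 2). Default 256.
#' @return An object of class \code{"gray_histogram"}: a list with
#'   \code{counts} (length \code{nbins}) and \code{nbins}.
#' @examples
#' h <- gray_histogram(matrix(c(0.25, 0.75), 10, 10))
#' which(h$counts > 0) - 1    # bins 64 and 192
#' @export
gray_histogram <- function(image, nbins = 256L) {
  image <- check_image(image)
  nbins <- check_nbins(nbins)
  b <- pmin(floor(as.vector(image) * nbins), nbins - 1L)
  structure(list(counts = tabulate(b + 1L, nbins = nbins), nbins = nbins),
            class = "gray_histogram")
}

check_nbins <- function(nbins) {
  if (length(nbins) != 1L || !is.finite(nbins) || nbins < 2) {
    stop("`nbins` must be an integer >= 2", call. = FALSE)
  }
  as.integer(nbins)
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("Intensity histogram: %d bins, %d pixels, %d non-empty bins\n",
              x$nbins, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

as_histogram <- function(x, nbins) {
  if (inherits(x, "gray_histogram")) return(x)
  if (is.matrix(x)) return(gray_histogram(x, nbins))
  stop("expected a gray_histogram or an image matrix", call. = FALSE)
}

# Bin probabilities and representative intensities; errors on an empty
# histogram.
hist_moments <- function(hist) {
  counts <- hist$counts
  total <- sum(counts)
  if (total <= 0) stop("histogram is empty", call. = FALSE)
  if (any(counts < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  p <- counts / total
  vals <- (seq_along(counts) - 1) / hist$nbins
  list(p = p, vals = vals, mu = sum(p * vals))
}

check_thresholds <- function(ts, nbins) {
  if (length(ts) < 1L || any(!is.finite(ts))) {
    stop("`thresholds` must be a non-empty numeric vector", call. = FALSE)
  }
  ts <- as.integer(ts)
  if (any(diff(ts) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  if (ts[1L] < 0L || ts[length(ts)] > nbins - 2L) {
    stop("`thresholds` must be bin indices in [0, nbins - 2]", call. = FALSE)
  }
  ts
}

#' Between-class variance of a threshold set
#'
#' The Otsu criterion \code{sigma_B^2 = sum_k w_k (mu_k - mu_T)^2} over
#' the \code{m + 1} classes induced on the histogram by \code{m}
#' thresholds: class \code{k} holds bins \code{b} with
#' \code{t_k < b <= t_(k+1)} (sentinels \code{t_0 = -1},
#' \code{t_(m+1) = nbins - 1}). Empty classes contribute zero.
#'
#' @param hist A [gray_histogram()] (or an image matrix, binned with
#'   \code{nbins}).
#' @param thresholds Strictly increasing 0-based bin indices in
#'   \code{[0, nbins - 2]}.
#' @param nbins Bin count used only when \code{hist} is an image.
#' @return Scalar between 0 and the total histogram variance.
#' @export
between_class_variance <- function(hist, thresholds, nbins = 256L) {
  hist <- as_histogram(hist, nbins)
  m <- hist_moments(hist)
  ts <- check_thresholds(thresholds, hist$nbins)
  breaks <- c(0L, ts + 1L, hist$nbins)   # 1-based class start offsets
  s <- 0
  for (k in seq_len(length(ts) + 1L)) {
    idx <- (breaks[k] + 1L):breaks[k + 1L]
    w <- sum(m$p[idx])
    if (w > 0) {
      mu_k <- sum(m$p[idx] * m$vals[idx]) / w
      s <- s + w * (mu_k - m$mu)^2
    }
  }
  s
}

#' Optimal multi-level Otsu thresholds
#'
#' Returns the strictly increasing set of \code{m} thresholds maximizing
#' [between_class_variance()] over all candidates — the exact optimum,
#' computed by dynamic programming over contiguous bin ranges using
#' cumulative zeroth/first histogram moments. Ties are broken by the
#' lexicographically smallest tuple, so results are fully deterministic
#' (e.g. a single-spike histogram yields threshold 0).
#'
#' @inheritParams between_class_variance
#' @param m Number of thresholds, \code{1 <= m <= nbins - 1}; \code{m}
#'   thresholds induce \code{m + 1} classes. Default 3.
#' @return Integer vector of \code{m} 0-based bin indices.
#' @examples
#' h <- gray_histogram(matrix(c(0.25, 0.75), 10, 10))
#' otsu_thresholds(h, m = 1)   # 64: smallest of the tied maximizers
#' @export
otsu_thresholds <- function(hist, m = 3L, nbins = 256L) {
  hist <- as_histogram(hist, nbins)
  B <- hist$nbins
  if (length(m) != 1L || !is.finite(m) || m < 1 || m > B - 1) {
    stop("`m` must satisfy 1 <= m <= nbins - 1", call. = FALSE)
  }
  m <- as.integer(m)
  mom <- hist_moments(hist)
  cp <- c(0, cumsum(mom$p))
  cm <- c(0, cumsum(mom$p * mom$vals))
  mu_T <- mom$mu
  # H[i, j]: criterion contribution of a class spanning bins i..j (1-based)
  H <- matrix(0, B, B)
  for (i in seq_len(B)) {
    j <- i:B
    w <- cp[j + 1L] - cp[i]
    mu <- ifelse(w > 0, (cm[j + 1L] - cm[i]) / w, mu_T)
    H[i, j] <- w * (mu - mu_T)^2
  }
  # S[[r]][i]: best criterion for bins i..B split into r contiguous classes
  S <- vector("list", m + 1L)
  S[[1L]] <- H[, B]
  for (r in 2L:(m + 1L)) {
    prev <- S[[r - 1L]]
    cur <- rep(-Inf, B)
    for (i in seq_len(B - r + 1L)) {
      j <- i:(B - r + 1L)           # end bin of the class starting at i
      cur[i] <- max(H[i, j] + prev[j + 1L])
    }
    S[[r]] <- cur
  }
  # Forward greedy reconstruction: smallest class end at every stage gives
  # the lexicographically smallest optimal threshold tuple.
  ts <- integer(m)
  i <- 1L
  for (k in seq_len(m)) {
    r <- m + 1L - k + 1L            # classes still to place
    j <- i:(B - r + 1L)
    cand <- H[i, j] + S[[r - 1L]][j + 1L]
    jbest <- j[which.max(cand)]
    ts[k] <- jbest - 1L             # 0-based threshold = last bin of class
    i <- jbest + 1L
  }
  ts
}

#' Label pixels by a threshold set
#'
#' Assigns class \code{k} (0-based) to a pixel whose histogram bin
#' \code{b} satisfies \code{t_k < b <= t_(k+1)} with sentinels
#' \code{t_0 = -1} and \code{t_(m+1) = nbins - 1}; \code{m} thresholds
#' yield \code{m + 1} classes ordered by intensity.
#'
#' @param image Grayscale image matrix.
#' @param thresholds Strictly increasing 0-based bin indices.
#' @param nbins Bin count of the quantization. Default 256.
#' @return Integer matrix of class labels in \code{0..m}, same shape as
#'   \code{image}.
#' @export
apply_thresholds <- function(image, thresholds, nbins = 256L) {
  image <- check_image(image)
  nbins <- check_nbins(nbins)
  ts <- check_thresholds(thresholds, nbins)
  b <- pmin(floor(as.vector(image) * nbins), nbins - 1L)
  matrix(findInterval(b, ts + 1L), nrow(image), ncol(image))
}
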