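# Tile-wise confidence-interval pre-filter. A pixel is kept only when it
# lies strictly inside the normal-theory confidence band for its tile's
# mean, x_bar +/- z * sigma / sqrt(n), with sigma taken from the whole
# image population; otherwise it is replaced by a tile statistic.

#' Parameters of the confidence-interval filter
#'
#' Bundles the tunable settings of the tile-wise filter. The default
#' half-width multiplier is the literal \code{z = 1.96}; when a
#' \code{confidence} level is supplied explicitly and \code{z} is not,
#' \code{z} is derived from the two-sided standard-normal quantile
#' \code{qnorm((1 + confidence) / 2)}. Setting \code{use_t = TRUE}
#' switches to the Student-t quantile with \code{n - 1} degrees of
#' freedom, an extension intended for small tiles.
#'
#' @param tile Length-2 integer vector \code{c(ia, ja)}: tile height and
#'   width in pixels. Default \code{c(8, 8)} (n = 64, comfortably above
#'   the usual n >= 30 rule of thumb for the normal band); \code{c(4, 13)}
#'   is the closest rectangle to a literal n = 52.
#' @param confidence Two-sided confidence level in (0, 1). Default 0.95.
#' @param z Positive half-width multiplier. Default 1.96.
#' @param replacement Statistic substituted for out-of-band pixels: the
#'   tile \code{"mean"} (default), \code{"min"} or \code{"max"}.
#' @param band_n Sample size used in the band half-width:
#'   \code{"nominal"} (default) always uses \code{ia * ja}, the literal
#'   reading of the band formula; \code{"actual"} uses each tile's true
#'   pixel count, which differs only on ragged edge tiles.
#' @param sd_type Passed to [global_std()]: \code{"population"} (default)
#'   or \code{"sample"}.
#' @param use_t Logical; use the Student-t quantile instead of the normal
#'   one, at the same confidence level. Default \code{FALSE}.
#' @return An object of class \code{"filter_params"}.
#' @examples
#' filter_params()
#' filter_params(confidence = 0.99)       # z derived: qnorm(0.995)
#' filter_params(tile = c(4, 13))         # literal n = 52 tiling
#' @export
filter_params <- function(tile = c(8, 8), confidence = 0.95, z = 1.96,
                          replacement = c("mean", "min", "max"),
                          band_n = c("nominal", "actual"),
                          sd_type = c("population", "sample"),
                          use_t = FALSE) {
  tile <- check_tile(tile)
  replacement <- match.arg(replacement)
  band_n <- match.arg(band_n)
  sd_type <- match.arg(sd_type)
  if (length(confidence) != 1L || !is.finite(confidence) ||
      confidence <= 0 || confidence >= 1) {
    stop("`confidence` must lie in (0, 1)", call. = FALSE)
  }
  conf_given <- !missing(confidence)
  z_given <- !missing(z)
  if (isTRUE(use_t)) {
    if (z_given) stop("give either `z` or `use_t`, not both", call. = FALSE)
    n <- prod(tile)
    if (n < 2L) stop("`use_t` needs a tile of at least 2 pixels", call. = FALSE)
    z <- stats::qt((1 + confidence) / 2, df = n - 1L)
  } else if (conf_given && !z_given) {
    z <- stats::qnorm((1 + confidence) / 2)
  }
  if (length(z) != 1L || !is.finite(z) || z <= 0) {
    stop("`z` must be a positive number", call. = FALSE)
  }
  structure(
    list(tile = tile, confidence = confidence, z = z,
         replacement = replacement, band_n = band_n,
         sd_type = sd_type, use_t = isTRUE(use_t)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "CI filter parameters: tile %dx%d (n = %d), z = %.6g (%.0f%% band),\n",
    x$tile[1L], x$tile[2L], prod(x$tile), x$z, 100 * x$confidence))
  cat(sprintf("  replacement = %s, band_n = %s, sd = %s%s\n",
              x$replacement, x$band_n, x$sd_type,
              if (x$use_t) ", Student-t quantile" else ""))
  invisible(x)
}

#' Confidence band for a tile mean
#'
#' The two-sided band \code{x_bar +/- z * sigma / sqrt(n)} expected to
#' contain the tile's population mean at the stated confidence level.
#' \code{n} is the nominal tile size \code{ia * ja} under
#' \code{band_n = "nominal"} and the tile's actual pixel count under
#' \code{band_n = "actual"}.
#'
#' @param stats A list with \code{mean} and \code{n_actual}, as returned
#'   by [tile_mean()].
#' @param sigma Global population standard deviation (scalar >= 0), from
#'   [global_std()].
#' @param params A [filter_params()] object.
#' @return Numeric vector \code{c(lo, hi)}, symmetric about the mean.
#' @examples
#' ci_band(list(mean = 0.6, n_actual = 4), 0.173205,
#'         filter_params(tile = c(2, 2)))
#' @export
ci_band <- function(stats, sigma, params = filter_params()) {
  if (!is.list(stats) || is.null(stats$mean) || is.null(stats$n_actual)) {
    stop("`stats` must be a list with `mean` and `n_actual`", call. = FALSE)
  }
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a non-negative scalar", call. = FALSE)
  }
  n <- if (params$band_n == "nominal") prod(params$tile) else stats$n_actual
  if (n < 1L) stop("band sample size must be >= 1", call. = FALSE)
  half <- params$z * sigma / sqrt(n)
  c(lo = stats$mean - half, hi = stats$mean + half)
}

#' Apply the confidence-interval pre-filter
#'
#' Single-pass tile-wise filter: the global standard deviation
#' \code{sigma} and every tile mean \code{x_bar} are computed once from
#' the original image; each pixel is then kept if it lies strictly inside
#' \code{(x_bar - z * sigma / sqrt(n), x_bar + z * sigma / sqrt(n))} and
#' otherwise replaced by the tile's replacement statistic (mean by
#' default). Replacements never feed back into the statistics. A constant
#' image is returned unchanged (the band is degenerate, so every pixel is
#' replaced by the tile mean, which equals the constant).
#'
#' @param image Grayscale image matrix.
#' @param params A [filter_params()] object.
#' @param details Logical; if \code{TRUE} return diagnostics alongside
#'   the filtered image.
#' @return The filtered image matrix, or (with \code{details = TRUE}) a
#'   list with \code{image}, \code{kept} (logical matrix), \code{sigma},
#'   \code{np} (tile count), \code{retention} (fraction of pixels kept)
#'   and \code{tile_means}.
#' @examples
#' img <- matrix(c(0.5, 0.5, 0.5, 0.9), 2, 2)
#' apply_ci_filter(img, filter_params(tile = c(2, 2)))
#' @export
apply_ci_filter <- function(image, params = filter_params(),
                            details = FALSE) {
  image <- check_image(image)
  ia <- params$tile[1L]; ja <- params$tile[2L]
  nr <- nrow(image); nc <- ncol(image)
  sigma <- global_std(image, params$sd_type)
  tid <- tile_index_matrix(nr, nc, ia, ja)
  np <- max(tid)
  v <- as.vector(image)
  t <- as.vector(tid)
  cnt <- tabulate(t, nbins = np)
  means <- as.vector(rowsum(v, t, reorder = TRUE)) / cnt
  n_band <- if (params$band_n == "nominal") rep.int(ia * ja, np) else cnt
  half <- params$z * sigma / sqrt(n_band)
  keep <- (v > means[t] - half[t]) & (v < means[t] + half[t])
  repl <- switch(params$replacement,
    mean = means,
    min  = vapply(split(v, factor(t, levels = seq_len(np))), min, 0),
    max  = vapply(split(v, factor(t, levels = seq_len(np))), max, 0)
  )
  out <- v
  out[!keep] <- repl[t][!keep]
  out <- matrix(out, nr, nc)
  if (!details) return(out)
  list(image = out, kept = matrix(keep, nr, nc), sigma = sigma, np = np,
       retention = mean(keep), tile_means = means)
}
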