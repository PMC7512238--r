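# The full segmentation chain: CI pre-filter (optional) followed by
# multi-level Otsu thresholding of the filtered image.

#' Segment an image with the CI + Otsu pipeline
#'
#' Runs the complete chain: the tile-wise confidence-interval pre-filter
#' (unless \code{prefilter = FALSE}, which gives the plain Otsu reference
#' pipeline), then exact multi-level Otsu thresholding of the result.
#' With the default \code{levels = 3}, four intensity classes are
#' produced.
#'
#' @param image Grayscale image matrix (see [as_gray_image()]).
#' @param params A [filter_params()] object controlling the pre-filter.
#' @param levels Number of Otsu thresholds \code{m} (>= 1); yields
#'   \code{m + 1} classes. Default 3.
#' @param nbins Histogram bins for thresholding. Default 256.
#' @param prefilter Apply the CI pre-filter before Otsu. Default
#'   \code{TRUE}; \code{FALSE} reproduces the standard Otsu-only
#'   reference method.
#' @return An object of class \code{"ciseg"} with components
#'   \code{labels} (integer class map, 0-based), \code{thresholds}
#'   (0-based bin indices), \code{filtered} (the pre-processed image;
#'   equals the input when \code{prefilter = FALSE}), \code{sigma}
#'   (global population standard deviation of the input), \code{np}
#'   (tile count), \code{retention} (fraction of pixels kept by the
#'   filter; \code{NA} without pre-filtering), \code{params},
#'   \code{levels}, \code{nbins} and \code{prefilter}.
#' @examples
#' ph <- make_phantom(96, 96, n_classes = 4, seed = 1)
#' noisy <- add_speckle(ph$image, variance = 0.12, seed = 2)
#' fit <- ci_otsu_segment(noisy, levels = 3)
#' fit
#' label_accuracy(fit$labels, ph$labels)
#' @export
ci_otsu_segment <- function(image, params = filter_params(), levels = 3L,
                            nbins = 256L, prefilter = TRUE) {
  image <- check_image(image)
  sigma <- global_std(image, params$sd_type)
  if (prefilter) {
    f <- apply_ci_filter(image, params, details = TRUE)
    filtered <- f$image
    np <- f$np
    retention <- f$retention
  } else {
    filtered <- image
    np <- NA_integer_
    retention <- NA_real_
  }
  ts <- otsu_thresholds(gray_histogram(filtered, nbins), m = levels)
  labels <- apply_thresholds(filtered, ts, nbins)
  structure(
    list(labels = labels, thresholds = ts, filtered = filtered,
         sigma = sigma, np = np, retention = retention, params = params,
         levels = as.integer(levels), nbins = as.integer(nbins),
         prefilter = isTRUE(prefilter)),
    class = "ciseg"
  )
}

#' Segment via filter + Otsu and return only the label map
#'
#' Convenience wrapper around [ci_otsu_segment()] returning just the
#' integer label matrix.
#'
#' @inheritParams ci_otsu_segment
#' @param m Number of thresholds. Default 3.
#' @return Integer label matrix with values in \code{0..m}.
#' @export
pipeline_segment <- function(image, params = filter_params(), m = 3L,
                             nbins = 256L, prefilter = TRUE) {
  ci_otsu_segment(image, params = params, levels = m, nbins = nbins,
                  prefilter = prefilter)$labels
}

#' @export
print.ciseg <- function(x, ...) {
  cat(sprintf("CI + Otsu segmentation of a %d x %d image\n",
              nrow(x$labels), ncol(x$labels)))
  if (x$prefilter) {
    cat(sprintf("  pre-filter: tile %dx%d, z = %.4g, sigma = %.5f, np = %d, retention = %.4f\n",
                x$params$tile[1L], x$params$tile[2L], x$params$z,
                x$sigma, x$np, x$retention))
  } else {
    cat("  pre-filter: none (reference Otsu pipeline)\n")
  }
  cat(sprintf("  Otsu: %d thresholds over %d bins -> %s (intensities %s)\n",
              x$levels, x$nbins,
              paste(x$thresholds, collapse = ", "),
              paste(format(x$thresholds / x$nbins, digits = 3),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.ciseg <- function(object, ...) {
  print(object)
  tab <- table(factor(object$labels, levels = 0:object$levels))
  cat("  class pixel counts:\n")
  for (k in names(tab)) {
    cat(sprintf("    class %s: %d (%.1f%%)\n", k, tab[[k]],
                100 * tab[[k]] / length(object$labels)))
  }
  invisible(object)
}

# Raster display of a [0,1] matrix with image-style orientation
# (row 1 at the top).
plot_gray <- function(z, main = "", col = grDevices::gray.colors(256, 0, 1),
                      ...) {
  graphics::image(t(z)[, nrow(z):1, drop = FALSE], col = col, axes = FALSE,
                  asp = nrow(z) / ncol(z), main = main, ...)
  invisible(NULL)
}

#' @export
plot.ciseg <- function(x, which = c("labels", "filtered"), ...) {
  which <- match.arg(which)
  if (which == "labels") {
    k <- x$levels + 1L
    plot_gray(x$labels / max(1L, x$levels),
              col = grDevices::hcl.colors(k, "viridis"),
              main = "segmentation labels", ...)
  } else {
    plot_gray(x$filtered, main = "pre-filtered image", ...)
  }
  invisible(x)
}
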