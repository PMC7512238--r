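# Grayscale images are plain numeric matrices with values in [0, 1],
# indexed (row, col) with 1-based coordinates.

#' Coerce an array to a grayscale image
#'
#' Converts numeric input to the internal grayscale representation: a
#' numeric matrix with intensities in \code{[0, 1]}. Three-channel (RGB)
#' arrays are collapsed with the BT.601 luma weights
#' \code{0.2989 R + 0.5870 G + 0.1140 B}; integer-valued input with a
#' maximum above 1 is rescaled by \code{max_value} (inferred as 255 or
#' 65535 when not given).
#'
#' @param x A numeric matrix, or a 3-d array whose third dimension holds
#'   1 (gray), 2 (gray + alpha), 3 (RGB) or 4 (RGBA) channels.
#' @param max_value Positive scalar used to rescale integer intensities
#'   to \code{[0, 1]}; \code{NULL} (default) infers it from the data.
#' @return A numeric matrix with all values in \code{[0, 1]}.
#' @examples
#' as_gray_image(matrix(0:255, 16, 16) / 255)
#' as_gray_image(matrix(c(0L, 128L, 255L, 64L), 2, 2))
#' @export
as_gray_image <- function(x, max_value = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    x <- if (d[3L] >= 3L) {
      0.2989 * x[, , 1L] + 0.5870 * x[, , 2L] + 0.1140 * x[, , 3L]
    } else {
      x[, , 1L]
    }
    x <- matrix(x, d[1L], d[2L])
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a 3-d numeric array", call. = FALSE)
  }
  x <- x * 1.0
  if (any(!is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  mx <- max(x)
  if (is.null(max_value) && mx > 1) {
    max_value <- if (mx > 255) 65535 else 255
  }
  if (!is.null(max_value)) x <- x / max_value
  check_image(x)
}

# Validate the grayscale-image invariants; returns the matrix invisibly
# usable in pipelines. Internal gatekeeper for every exported operation.
check_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L || length(x) == 0L) {
    stop(sprintf("`%s` must have at least one pixel", arg), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (min(x) < 0 || max(x) > 1) {
    stop(sprintf("`%s` must have intensities in [0, 1]", arg), call. = FALSE)
  }
  x
}

#' Standard deviation of the whole pixel population
#'
#' Treats every pixel intensity as one datum and returns the standard
#' deviation across the entire image. The default is the population
#' (divide-by-N) form; the unbiased sample form (N - 1 denominator) is
#' available as an option.
#'
#' @param image Grayscale image matrix (values in \code{[0, 1]}).
#' @param type \code{"population"} (default) or \code{"sample"}.
#' @return A non-negative scalar; exactly 0 for a constant image.
#' @examples
#' global_std(matrix(c(0.5, 0.5, 0.5, 0.9), 2, 2))
#' @export
global_std <- function(image, type = c("population", "sample")) {
  image <- check_image(image)
  type <- match.arg(type)
  v <- as.vector(image)
  if (type == "population") {
    sqrt(mean((v - mean(v))^2))
  } else {
    if (length(v) < 2L) stop("sample standard deviation needs >= 2 pixels",
                             call. = FALSE)
    stats::sd(v)
  }
}

#' Clip intensities to the unit interval
#'
#' @param x Numeric matrix or vector.
#' @return \code{x} with values clamped to \code{[0, 1]}.
#' @export
clip01 <- function(x) pmin(pmax(x, 0), 1)
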