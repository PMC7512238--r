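# Synthetic phantoms and noise models. Speckle is the signal-dependent
# multiplicative model J = I + u*I; Gaussian is additive. Both clip to
# [0, 1] after corruption (moment checks use clip = FALSE).

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards; NULL seed uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_variance <- function(variance) {
  if (length(variance) != 1L || !is.finite(variance) || variance < 0) {
    stop("`variance` must be a non-negative scalar", call. = FALSE)
  }
  variance
}

#' Corrupt an image with multiplicative speckle noise
#'
#' Applies the signal-dependent model \code{J = I + u * I} with \code{u}
#' i.i.d. zero-mean noise of the given variance: uniform on
#' \code{[-sqrt(3 v), +sqrt(3 v)]} by default (the conventional speckle
#' simulation model), or zero-mean Gaussian as an option. Because the
#' perturbation is proportional to the signal, zeros are preserved and
#' the per-level noise standard deviation scales linearly with intensity
#' — the defining signature of speckle as seen in ultrasound and SAR
#' imagery.
#'
#' @param image Grayscale image matrix.
#' @param variance Variance of the multiplier \code{u} (>= 0). The
#'   default 0.12 puts the post-noise population standard deviation of
#'   the default 256 x 256 four-class phantom at about 0.22, a typical
#'   magnitude for visibly speckled natural test images.
#' @param seed Optional integer seed; identical seed and parameters give
#'   bit-identical output without disturbing the caller's RNG stream.
#' @param multiplier Distribution of \code{u}: \code{"uniform"} (default)
#'   or \code{"gaussian"}.
#' @param clip Clip the result to \code{[0, 1]} (default \code{TRUE}).
#' @return Corrupted image matrix.
#' @examples
#' ph <- make_phantom(64, 64, n_classes = 4, seed = 1)
#' noisy <- add_speckle(ph$image, variance = 0.12, seed = 2)
#' @export
add_speckle <- function(image, variance = 0.12, seed = NULL,
                        multiplier = c("uniform", "gaussian"),
                        clip = TRUE) {
  image <- check_image(image)
  check_variance(variance)
  multiplier <- match.arg(multiplier)
  u <- with_seed(seed, {
    if (multiplier == "uniform") {
      a <- sqrt(3 * variance)
      stats::runif(length(image), -a, a)
    } else {
      stats::rnorm(length(image), 0, sqrt(variance))
    }
  })
  out <- image + matrix(u, nrow(image), ncol(image)) * image
  if (clip) out <- clip01(out)
  out
}

#' Corrupt an image with additive Gaussian noise
#'
#' \code{J = I + g} with \code{g} i.i.d. Normal(\code{mean},
#' \code{variance}), clipped to \code{[0, 1]} by default.
#'
#' @inheritParams add_speckle
#' @param variance Variance of the additive term (>= 0).
#' @param mean Mean of the additive term. Default 0.
#' @return Corrupted image matrix.
#' @export
add_gaussian <- function(image, variance, mean = 0, seed = NULL,
                         clip = TRUE) {
  image <- check_image(image)
  check_variance(variance)
  g <- with_seed(seed, stats::rnorm(length(image), mean, sqrt(variance)))
  out <- image + matrix(g, nrow(image), ncol(image))
  if (clip) out <- clip01(out)
  out
}

#' Generate a piecewise-constant phantom with ground truth
#'
#' Builds a synthetic test image: a background at the lowest intensity
#' level plus \code{n_classes - 1} randomly placed non-overlapping
#' rectangles (or discs), one intensity level per class, levels evenly
#' spaced over \code{[0.1, 0.9]}. The returned label map is exactly
#' consistent with the image (\code{image == levels[labels + 1]}), so
#' segmentations can be scored against a known truth.
#'
#' @param height,width Phantom dimensions in pixels.
#' @param n_classes Number of intensity classes, 2..8. Default 4.
#' @param seed Optional integer seed for reproducible placement.
#' @param shape \code{"rect"} (default) or \code{"disc"} regions.
#' @param size_frac Length-2 range of region extent as a fraction of the
#'   shorter image side. Default \code{c(0.15, 0.35)}.
#' @param align Snap rectangle corners and extents to multiples of this
#'   pitch (default 1, i.e. free placement). Setting \code{align} to the
#'   tile shape of [filter_params()] makes every filter tile of the
#'   clean phantom constant, so the CI pre-filter is exactly the
#'   identity on it — the setting used to verify exact clean-image
#'   recovery through the full pipeline. Rectangles only.
#' @param max_tries Placement retries per region before giving up.
#' @return An object of class \code{"phantom"}: a list with \code{image}
#'   (grayscale matrix), \code{labels} (0-based integer label matrix) and
#'   \code{levels} (ascending intensities, one per class).
#' @examples
#' ph <- make_phantom(128, 128, n_classes = 4, seed = 1)
#' table(ph$labels)
#' @export
make_phantom <- function(height, width, n_classes = 4L, seed = NULL,
                         shape = c("rect", "disc"),
                         size_frac = c(0.15, 0.35), align = c(1L, 1L),
                         max_tries = 200L) {
  if (height < 8 || width < 8) {
    stop("phantom must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (n_classes < 2 || n_classes > 8) {
    stop("`n_classes` must be between 2 and 8", call. = FALSE)
  }
  shape <- match.arg(shape)
  if (length(align) == 1L) align <- c(align, align)
  align <- as.integer(align)
  if (any(align < 1L)) stop("`align` must be positive", call. = FALSE)
  if (any(align > 1L) && shape != "rect") {
    stop("`align` is only supported for rectangular regions", call. = FALSE)
  }
  n_classes <- as.integer(n_classes)
  levels <- seq(0.1, 0.9, length.out = n_classes)
  labels <- matrix(0L, height, width)
  side <- min(height, width)
  with_seed(seed, {
    for (k in seq_len(n_classes - 1L)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ext <- pmax(2L, round(stats::runif(2L, size_frac[1L], size_frac[2L]) * side))
        ext <- pmax(align, (ext %/% align) * align)
        h <- min(ext[1L], height); w <- min(ext[2L], width)
        r0 <- (sample.int((height - h) %/% align[1L] + 1L, 1L) - 1L) * align[1L] + 1L
        c0 <- (sample.int((width - w) %/% align[2L] + 1L, 1L) - 1L) * align[2L] + 1L
        rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
        if (shape == "rect") {
          mask <- matrix(TRUE, h, w)
        } else {
          rad <- min(h, w) / 2
          cy <- mean(range(rows)); cx <- mean(range(cols))
          mask <- outer(rows, cols, function(r, c) (r - cy)^2 + (c - cx)^2 <= rad^2)
        }
        if (all(labels[rows, cols][mask] == 0L)) {
          sub <- labels[rows, cols]
          sub[mask] <- k
          labels[rows, cols] <- sub
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place all phantom regions without overlap; ",
             "enlarge the image or reduce `n_classes`/`size_frac`",
             call. = FALSE)
      }
    }
  })
  structure(
    list(image = matrix(levels[labels + 1L], height, width),
         labels = labels, levels = levels),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %d x %d, %d classes at levels %s\n",
              nrow(x$image), ncol(x$image), length(x$levels),
              paste(format(x$levels, digits = 3), collapse = ", ")))
  invisible(x)
}

#' @export
plot.phantom <- function(x, which = c("image", "labels"), ...) {
  which <- match.arg(which)
  z <- if (which == "image") x$image else x$labels / max(1L, max(x$labels))
  plot_gray(z, main = sprintf("phantom %s", which), ...)
}
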