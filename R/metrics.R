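# Segmentation evaluation: fixed-level binarization, Jaccard (Tanimoto)
# and Dice overlap, and per-pixel label accuracy with intensity-based
# class correspondence.

#' Binarize an image at a fixed level
#'
#' A pixel maps to 1 iff its intensity is strictly greater than
#' \code{level}; a pixel exactly at the level maps to 0. The strict rule
#' is fixed so results are reproducible across platforms.
#'
#' @param image Grayscale image matrix.
#' @param level Threshold intensity in \code{[0, 1]}. Default 0.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(image, level = 0.5) {
  image <- check_image(image)
  if (length(level) != 1L || !is.finite(level) || level < 0 || level > 1) {
    stop("`level` must lie in [0, 1]", call. = FALSE)
  }
  matrix(as.integer(image > level), nrow(image), ncol(image))
}

check_mask <- function(x, arg = "mask") {
  if (!is.matrix(x) || !all(x %in% c(0L, 1L, FALSE, TRUE))) {
    stop(sprintf("`%s` must be a 0/1 matrix", arg), call. = FALSE)
  }
  matrix(as.integer(x), nrow(x), ncol(x))
}

#' Jaccard and Dice overlap of two binary masks
#'
#' The Jaccard (Tanimoto) coefficient \code{|A & B| / |A | B|} over the
#' foreground, with the convention J = 1 when both masks are empty (two
#' empty segmentations agree perfectly); 0 means no overlap, 1 perfect
#' agreement. Dice is filled in from the identity
#' \code{dice = 2 J / (1 + J)}.
#'
#' @param a,b Binary (0/1 or logical) matrices of the same shape.
#' @return An object of class \code{"seg_score"}: list with
#'   \code{jaccard} and \code{dice}, both in \code{[0, 1]}.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' b <- matrix(c(1, 0, 1, 0), 2, 2)
#' jaccard(a, b)
#' @export
jaccard <- function(a, b) {
  a <- check_mask(a, "a"); b <- check_mask(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop("`a` and `b` must have the same shape", call. = FALSE)
  }
  inter <- sum(a & b)
  union <- sum(a | b)
  j <- if (union == 0L) 1 else inter / union
  structure(list(jaccard = j, dice = 2 * j / (1 + j)), class = "seg_score")
}

#' @export
print.seg_score <- function(x, ...) {
  cat(sprintf("Jaccard = %.4f, Dice = %.4f\n", x$jaccard, x$dice))
  invisible(x)
}

# Relabel classes of a label map by ascending mean intensity of the
# reference image over each class; returns integer ranks 0-based.
rank_labels_by_intensity <- function(labels, image) {
  cls <- sort(unique(as.vector(labels)))
  mu <- vapply(cls, function(k) mean(image[labels == k]), 0)
  rank_of <- match(cls, cls[order(mu)]) - 1L
  matrix(rank_of[match(labels, cls)], nrow(labels), ncol(labels))
}

#' Per-pixel label accuracy against ground truth
#'
#' Fraction of pixels whose predicted class matches the truth. Class
#' identities of a segmentation are arbitrary, so when a reference
#' \code{image} is supplied, both label maps are first put into
#' correspondence by ranking each map's classes by their mean intensity
#' in that image (ascending); a truth-consistent relabelling of the
#' predicted classes then scores 1.0. Without a reference image, labels
#' are compared as given (both maps are assumed intensity-ordered, as
#' produced by [apply_thresholds()] and [make_phantom()]).
#'
#' @param pred,truth Integer label matrices of the same shape.
#' @param image Optional grayscale image used to establish class
#'   correspondence.
#' @return Scalar accuracy in \code{[0, 1]}.
#' @export
label_accuracy <- function(pred, truth, image = NULL) {
  if (!is.matrix(pred) || !is.matrix(truth) ||
      !identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must be matrices of the same shape",
         call. = FALSE)
  }
  if (!is.null(image)) {
    image <- check_image(image)
    if (!identical(dim(image), dim(pred))) {
      stop("`image` must have the same shape as the label maps",
           call. = FALSE)
    }
    pred <- rank_labels_by_intensity(pred, image)
    truth <- rank_labels_by_intensity(truth, image)
  }
  mean(pred == truth)
}

#' Render a label map to grayscale class-mean intensities
#'
#' Maps class \code{k} to the mean intensity of \code{image} over that
#' class, producing the grayscale rendition used when a colored
#' segmentation must be compared to a reference by binarization: colored
#' class maps reduce to gray without committing to a palette.
#'
#' @param labels Integer label matrix.
#' @param image Grayscale image of the same shape supplying the
#'   intensities.
#' @return Grayscale matrix with one constant intensity per class.
#' @export
labels_to_gray <- function(labels, image) {
  image <- check_image(image)
  if (!identical(dim(labels), dim(image))) {
    stop("`labels` and `image` must have the same shape", call. = FALSE)
  }
  cls <- sort(unique(as.vector(labels)))
  mu <- vapply(cls, function(k) mean(image[labels == k]), 0)
  matrix(mu[match(labels, cls)], nrow(labels), ncol(labels))
}
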