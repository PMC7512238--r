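# Tiling of an image into ia x ja sub-images. Tiles are listed row-major;
# interior tiles have the nominal shape, the last row/column keeps the
# ragged remainder. Coordinates are 1-based (row, col).

#' Partition an image domain into a grid of tiles
#'
#' Splits a \code{height} x \code{width} pixel domain into
#' \code{ceiling(height/ia) * ceiling(width/ja)} rectangular sub-images in
#' row-major order. Interior tiles are \code{ia x ja}; tiles in the last
#' row/column hold the remainder. A tile larger than the image yields a
#' single tile spanning the whole image.
#'
#' @param height,width Image dimensions in pixels (>= 1).
#' @param tile Length-2 integer vector \code{c(ia, ja)}: nominal tile
#'   height and width in pixels.
#' @return A data frame with one row per tile and columns \code{row},
#'   \code{col} (1-based top-left corner), \code{height}, \code{width};
#'   attributes \code{ia}, \code{ja} and \code{np} (tile count).
#' @examples
#' make_tile_grid(5, 4, c(2, 2))   # 6 tiles, bottom row tiles are 1 x 2
#' @export
make_tile_grid <- function(height, width, tile) {
  if (length(height) != 1L || length(width) != 1L ||
      !is.finite(height) || !is.finite(width) ||
      height < 1 || width < 1) {
    stop("`height` and `width` must be positive integers", call. = FALSE)
  }
  tile <- check_tile(tile)
  ia <- tile[1L]; ja <- tile[2L]
  height <- as.integer(height); width <- as.integer(width)
  r0 <- seq.int(1L, height, by = ia)
  c0 <- seq.int(1L, width, by = ja)
  rh <- pmin(ia, height - r0 + 1L)
  cw <- pmin(ja, width - c0 + 1L)
  grid <- data.frame(
    row    = rep(r0, each = length(c0)),
    col    = rep(c0, times = length(r0)),
    height = rep(rh, each = length(c0)),
    width  = rep(cw, times = length(r0))
  )
  attr(grid, "ia") <- ia
  attr(grid, "ja") <- ja
  attr(grid, "np") <- nrow(grid)
  grid
}

check_tile <- function(tile) {
  if (length(tile) == 1L) tile <- c(tile, tile)
  if (length(tile) != 2L || any(!is.finite(tile)) || any(tile < 1)) {
    stop("`tile` must be two positive integers c(ia, ja)", call. = FALSE)
  }
  as.integer(tile)
}

#' Sample mean of one tile
#'
#' Arithmetic mean of the pixel intensities inside one rectangle of the
#' image, together with the actual pixel count of that rectangle.
#'
#' @param image Grayscale image matrix.
#' @param rect Numeric vector \code{c(row, col, height, width)} with a
#'   1-based top-left corner; must lie inside the image.
#' @return A list with elements \code{mean} and \code{n_actual}.
#' @export
tile_mean <- function(image, rect) {
  image <- check_image(image)
  if (length(rect) != 4L || any(!is.finite(rect)) || any(rect[3:4] < 1)) {
    stop("`rect` must be c(row, col, height, width)", call. = FALSE)
  }
  rect <- as.integer(rect)
  r1 <- rect[1L]; c1 <- rect[2L]
  r2 <- r1 + rect[3L] - 1L; c2 <- c1 + rect[4L] - 1L
  if (r1 < 1L || c1 < 1L || r2 > nrow(image) || c2 > ncol(image)) {
    stop("`rect` lies outside the image", call. = FALSE)
  }
  vals <- image[r1:r2, c1:c2]
  list(mean = mean(vals), n_actual = length(vals))
}

# Tile id (1..np, row-major) of every pixel, as an nr x nc integer matrix.
# Matches the ordering of make_tile_grid().
tile_index_matrix <- function(nr, nc, ia, ja) {
  rowT <- (seq_len(nr) - 1L) %/% ia
  colT <- (seq_len(nc) - 1L) %/% ja + 1L
  ntc <- (nc - 1L) %/% ja + 1L
  matrix(rep(rowT * ntc, times = nc) + rep(colT, each = nr), nr, nc)
}
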