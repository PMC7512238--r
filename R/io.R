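# Image input/output. PNG via the png package, TIFF via the tiff
# package, PGM (P2 ASCII and P5 binary) parsed here since no installed
# package reads it. All readers return [0,1] matrices; writers quantize
# with round-half-up.

#' Read a grayscale image from PNG, TIFF or PGM
#'
#' RGB(A) input is collapsed to gray with the BT.601 luma weights
#' 0.2989/0.5870/0.1140; integer samples are scaled to \code{[0, 1]} by
#' their bit-depth maximum. The format is chosen by file extension.
#'
#' @param path Path to a \code{.png}, \code{.tif}/\code{.tiff},
#'   \code{.pgm} or \code{.pnm} file, 8- or 16-bit.
#' @return A grayscale image matrix with values in \code{[0, 1]}.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = ,
    pnm = read_pgm(path),
    stop(sprintf("unsupported image format '.%s' (PNG, TIFF or PGM expected): %s",
                 ext, path), call. = FALSE)
  )
  as_gray_image(clip01(arr))
}

#' Write a grayscale image to PNG, TIFF or PGM
#'
#' Intensities are quantized to \code{depth} bits with round-half-up
#' (\code{floor(v * (2^depth - 1) + 0.5)}), so a write/read round trip
#' preserves every pixel to within one quantization step. PNG output is
#' 8-bit; TIFF and PGM support 8 or 16 bits.
#'
#' @param image Grayscale image matrix.
#' @param path Output path; extension selects the format.
#' @param depth Bits per sample, 8 (default) or 16.
#' @return The path, invisibly.
#' @export
write_gray <- function(image, path, depth = 8L) {
  image <- check_image(image)
  if (!depth %in% c(8L, 16L)) stop("`depth` must be 8 or 16", call. = FALSE)
  mx <- 2^depth - 1
  q <- floor(image * mx + 0.5)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (depth != 8L) stop("PNG output is 8-bit; use TIFF or PGM for 16-bit",
                            call. = FALSE)
      png::writePNG(q / mx, path)
    },
    tif = ,
    tiff = tiff::writeTIFF(q / mx, path, bits.per.sample = depth),
    pgm = ,
    pnm = write_pgm(q, path, mx),
    stop(sprintf("unsupported output format '.%s': %s", ext, path),
         call. = FALSE)
  )
  invisible(path)
}

# --- PGM --------------------------------------------------------------

read_pgm <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # tokenize the header: magic, width, height, maxval; '#' starts a
  # comment running to end of line
  pos <- 1L
  next_token <- function() {
    tok <- character(0)
    while (pos <= length(raw)) {
      ch <- rawToChar(raw[pos])
      if (ch == "#") {
        while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <<- pos + 1L
      } else if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break
        pos <<- pos + 1L
      } else {
        tok <- c(tok, ch)
        pos <<- pos + 1L
      }
    }
    paste(tok, collapse = "")
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("not a PGM file (magic '%s'): %s", magic, path),
         call. = FALSE)
  }
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (any(is.na(c(width, height, maxval))) || maxval < 1) {
    stop(sprintf("malformed PGM header: %s", path), call. = FALSE)
  }
  n <- width * height
  if (magic == "P5") {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (maxval < 256L) {
      vals <- as.integer(raw[pos:(pos + n - 1L)])
    } else {
      b <- raw[pos:(pos + 2L * n - 1L)]
      vals <- as.integer(b[seq(1L, 2L * n, 2L)]) * 256L +
              as.integer(b[seq(2L, 2L * n, 2L)])
    }
  } else {
    txt <- rawToChar(raw[pos:length(raw)])
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])
    if (length(vals) < n) {
      stop(sprintf("truncated PGM pixel data: %s", path), call. = FALSE)
    }
    vals <- vals[seq_len(n)]
  }
  # PGM stores pixels row-major, top to bottom
  matrix(vals, height, width, byrow = TRUE) / maxval
}

write_pgm <- function(q, path, maxval) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(q), nrow(q), maxval), con,
            eos = NULL)
  vals <- as.integer(t(q))   # row-major
  if (maxval < 256) {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L))), con)
  }
  invisible(path)
}

# --- label maps -------------------------------------------------------

#' Write a label map as an 8-bit image
#'
#' Stores the raw class index of each pixel (0, 1, 2, ...) in an 8-bit
#' grayscale file, and optionally a colorized companion for viewing.
#'
#' @param labels Integer label matrix with values in 0..255.
#' @param path Output path (PNG, TIFF or PGM).
#' @param colormap Optional palette name passed to
#'   [grDevices::hcl.colors()]; when given, a colorized RGB PNG is
#'   written alongside with suffix \code{"_color.png"}.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path, colormap = NULL) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels > 255) ||
      any(labels != round(labels))) {
    stop("`labels` must be an integer matrix with values in 0..255",
         call. = FALSE)
  }
  write_gray(labels / 255, path, depth = 8L)
  if (!is.null(colormap)) {
    k <- max(labels) + 1L
    pal <- grDevices::hcl.colors(max(2L, k), colormap)
    rgb <- grDevices::col2rgb(pal[labels + 1L]) / 255
    arr <- array(0, c(nrow(labels), ncol(labels), 3L))
    for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nrow(labels), ncol(labels))
    cpath <- sub("\\.[A-Za-z]+$", "_color.png", path)
    png::writePNG(arr, cpath)
  }
  invisible(path)
}

#' Read a label map written by [write_labels()]
#'
#' @param path Path to an 8-bit label image.
#' @return Integer label matrix.
#' @export
read_labels <- function(path) {
  v <- read_gray(path)
  matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
}
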