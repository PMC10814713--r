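#' @importFrom stats sd cor.test t.test qt pt rnorm runif median complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Internal raster model
# ---------------------
# A grayscale image is a plain integer matrix with values in [0, 255],
# indexed [row, col] with the origin at the top-left (i = row, j = column).
# A binary mask is an integer matrix with values in {0, 1}.
# An overlay is an M x N x 3 integer array with values in [0, 255].

round_half_up <- function(x) floor(x + 0.5)

#' Validate a grayscale image
#'
#' Checks that `x` is a non-empty numeric matrix of integral values in
#' \[0, 255\] and returns it as an integer matrix.
#'
#' @param x A matrix of pixel intensities.
#' @return An integer matrix with values in \[0, 255\].
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a grayscale image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a grayscale image must have at least one row and one column",
         call. = FALSE)
  }
  if (anyNA(x) || any(x != round_half_up(x)) || any(x < 0) || any(x > 255)) {
    stop("grayscale intensities must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Validate a binary mask
#'
#' @param x A matrix whose values are all 0 or 1 (logical matrices are
#'   accepted and coerced).
#' @return An integer matrix with values in \{0, 1\}.
#' @export
as_binary_image <- function(x) {
  if (is.matrix(x) && is.logical(x)) {
    storage.mode(x) <- "integer"
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a binary mask must be a numeric or logical matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a binary mask must have at least one row and one column",
         call. = FALSE)
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("binary mask values must be exactly 0 or 1", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

assert_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("%s have mismatched dimensions: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a radiograph as a grayscale intensity matrix
#'
#' Reads an 8-bit PNG or JPEG raster.  Colour inputs are reduced to a
#' single channel with the ITU-R BT.601 luma transform
#' (0.299 R + 0.587 G + 0.114 B), rounded half-up to integers; an alpha
#' channel, if present, is ignored.  Single-channel inputs pass through
#' unchanged.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An integer matrix with values in \[0, 255\], indexed
#'   \[row, column\] with the origin at the top-left.
#' @examples
#' tmp <- tempfile(fileext = ".png")
#' png::writePNG(matrix(0.5, 4, 4), tmp)
#' img <- read_gray(tmp)
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      stop(sprintf("unsupported raster format '.%s' (expected PNG or JPEG)",
                   ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) {
    stop(sprintf("image '%s' is zero-sized", path), call. = FALSE)
  }
  nchan <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
  gray01 <- if (nchan >= 3L) {
    0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
  } else if (nchan == 2L) {
    raw[, , 1]  # gray + alpha: keep the gray channel
  } else if (length(dim(raw)) == 3L) {
    raw[, , 1]
  } else {
    raw
  }
  as_gray_image(round_half_up(gray01 * 255))
}

require_png_path <- function(path) {
  if (tolower(tools::file_ext(path)) != "png") {
    stop(sprintf("output must be a PNG (lossless); got '%s'", path),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written as 255 and background (0) as 0, so reading
#' the file back and thresholding at > 127 reproduces the mask exactly.
#'
#' @param mask Binary matrix (\{0, 1\}).
#' @param path Output path; must end in `.png`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_image(mask)
  require_png_path(path)
  ok <- tryCatch({
    png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write mask to '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' Write an RGB overlay as an 8-bit PNG
#'
#' @param overlay M x N x 3 integer array with values in \[0, 255\].
#' @param path Output path; must end in `.png`.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(overlay, path) {
  if (!is.array(overlay) || length(dim(overlay)) != 3L || dim(overlay)[3] != 3L) {
    stop("an overlay must be an M x N x 3 array", call. = FALSE)
  }
  if (anyNA(overlay) || any(overlay < 0) || any(overlay > 255) ||
      any(overlay != round_half_up(overlay))) {
    stop("overlay channel values must be integers in [0, 255]", call. = FALSE)
  }
  require_png_path(path)
  ok <- tryCatch({
    png::writePNG(overlay / 255, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write overlay to '%s': %s",
                 path, conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read a stored \{0, 255\} mask PNG back as a binary matrix
#'
#' @param path Path to an 8-bit PNG mask.
#' @return Integer matrix in \{0, 1\}: pixels > 127 map to 1.
#' @export
read_mask <- function(path) {
  as_binary_image(read_gray(path) > 127L)
}
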