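# Binary morphology on {0,1} matrices.
# EBImage does the heavy lifting; wrappers enforce the zero-padding
# border convention (lungs never touch the film border in AP chest
# radiographs, so out-of-frame pixels are background).

#' Create a structuring element footprint
#'
#' Builds the binary neighbourhood footprint used by the morphological
#' stages of the segmentation pipeline.
#'
#' @param shape One of `"disk"` (Euclidean ball, the default used for
#'   both dilation and closing), `"square"`, or `"cross"` (a plus-shaped
#'   footprint).
#' @param radius Positive integer; the footprint spans
#'   `(2 * radius + 1)^2` cells centred on the origin.
#' @return An integer \{0, 1\} matrix of odd dimensions containing its
#'   centre, with attributes `shape` and `radius`.
#' @examples
#' structuring_element("disk", 1)   # the 4-neighbourhood plus centre
#' @export
structuring_element <- function(shape = c("disk", "square", "cross"),
                                radius = 3L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) {
    stop("structuring element radius must be a positive integer",
         call. = FALSE)
  }
  d <- seq.int(-radius, radius)
  fp <- switch(shape,
    disk   = outer(d, d, function(x, y) as.integer(x^2 + y^2 <= radius^2)),
    square = matrix(1L, 2L * radius + 1L, 2L * radius + 1L),
    cross  = outer(d, d, function(x, y) as.integer(x == 0L | y == 0L))
  )
  attr(fp, "shape") <- shape
  attr(fp, "radius") <- radius
  fp
}

assert_footprint <- function(B) {
  if (!is.matrix(B) || !all(B %in% c(0L, 1L)) ||
      nrow(B) %% 2L == 0L || ncol(B) %% 2L == 0L) {
    stop("a structuring element must be a {0,1} matrix of odd dimensions",
         call. = FALSE)
  }
  if (B[(nrow(B) + 1L) %/% 2L, (ncol(B) + 1L) %/% 2L] != 1L) {
    stop("the structuring element must contain its origin", call. = FALSE)
  }
  invisible(TRUE)
}

#' Dilate a binary mask
#'
#' Sets a pixel to foreground whenever the structuring element centred
#' there overlaps any foreground pixel; pixels outside the frame count
#' as background (zero padding).  Dilation strengthens object contours
#' and bridges small interruptions before small-object removal.
#'
#' @param mask Binary \{0, 1\} matrix.
#' @param B Structuring element from [structuring_element()].
#' @return Binary matrix of the same dimensions.
#' @export
dilate_mask <- function(mask, B = structuring_element("disk", 3L)) {
  mask <- as_binary_image(mask)
  assert_footprint(B)
  if (sum(B) == 1L) return(mask)  # origin-only SE: the neutral element
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask),
                                            kern = unclass(B)))
  as_binary_image(matrix(as.integer(out > 0), nrow(mask), ncol(mask)))
}

#' Erode a binary mask
#'
#' A pixel stays foreground only if the whole structuring element
#' centred there fits inside the foreground; out-of-frame pixels count
#' as background, so foreground touching the border is eroded.
#'
#' @inheritParams dilate_mask
#' @return Binary matrix of the same dimensions.
#' @export
erode_mask <- function(mask, B = structuring_element("disk", 3L)) {
  mask <- as_binary_image(mask)
  assert_footprint(B)
  if (sum(B) == 1L) return(mask)  # origin-only SE: the neutral element
  # EBImage replicates the border for erosion; pad with background first
  # so the zero-padding convention holds.
  pr <- (nrow(B) - 1L) %/% 2L
  pc <- (ncol(B) - 1L) %/% 2L
  M <- nrow(mask); N <- ncol(mask)
  padded <- matrix(0L, M + 2L * pr, N + 2L * pc)
  padded[pr + seq_len(M), pc + seq_len(N)] <- mask
  out <- EBImage::imageData(EBImage::erode(EBImage::Image(padded),
                                           kern = unclass(B)))
  as_binary_image(matrix(as.integer(out[pr + seq_len(M), pc + seq_len(N)] > 0),
                         M, N))
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with the same structuring element; fills
#' gaps and reconnects interrupted contours of the segmented lung field
#' without growing the mask where it is already solid.  Closing is
#' idempotent and extensive.
#'
#' @inheritParams dilate_mask
#' @param B Structuring element; the pipeline default is a disk of
#'   radius 7.
#' @return Binary matrix of the same dimensions.
#' @export
close_mask <- function(mask, B = structuring_element("disk", 7L)) {
  erode_mask(dilate_mask(mask, B), B)
}

#' Label connected components
#'
#' Flood-fill labelling of foreground components.  Labels are assigned
#' in the order components are first met in a row-major scan (top-left
#' to bottom-right), which fixes the tie order used by area-based
#' selection.
#'
#' @param mask Binary \{0, 1\} matrix.
#' @param connectivity 8 (default, diagonal neighbours connect) or 4.
#' @return Integer matrix; 0 is background, components are numbered
#'   from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_binary_image(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(0L, M, N)
  fg <- which(mask == 1L)
  if (!length(fg)) return(lab)
  rw <- (fg - 1L) %% M + 1L
  cl <- (fg - 1L) %/% M + 1L
  fg <- fg[order(rw, cl)]
  last <- M * N
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fr <- (frontier - 1L) %% M + 1L
      up <- frontier[fr > 1L] - 1L
      dn <- frontier[fr < M] + 1L
      nb <- c(up, dn, frontier - M, frontier + M)
      if (connectivity == 8L) {
        nb <- c(nb, up - M, up + M, dn - M, dn + M)
      }
      nb <- nb[nb >= 1L & nb <= last]
      nb <- unique(nb[mask[nb] == 1L & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Remove small connected components
#'
#' Deletes every foreground component whose pixel area is less than or
#' equal to `U`, keeping the larger segments that carry the anatomy of
#' interest.  With `U = 0` the mask is returned unchanged.
#'
#' @param mask Binary \{0, 1\} matrix.
#' @param U Non-negative integer area threshold in pixels; components
#'   with area `<= U` are removed.
#' @param connectivity 8 (default) or 4.
#' @return Binary matrix of the same dimensions.
#' @export
remove_small <- function(mask, U, connectivity = 8L) {
  mask <- as_binary_image(mask)
  U <- as.integer(U)
  if (is.na(U) || U < 0L) {
    stop("area threshold U must be a non-negative integer", call. = FALSE)
  }
  if (U == 0L) return(mask)
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  drop <- which(areas <= U)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}
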