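# Rule-based lung-field segmentation: global threshold -> dilation ->
# small-object removal -> lung ROI masking -> closing -> overlay.

#' Global threshold binarization
#'
#' Classic bright-foreground thresholding: a pixel becomes foreground
#' when its intensity is strictly greater than `T`.  Aerated lung is
#' radiolucent (dark) on a radiograph, so the pipeline usually runs with
#' `invert = TRUE`, selecting pixels with intensity `<= T`.
#'
#' @param X Grayscale integer matrix (\[0, 255\]).
#' @param T Threshold intensity in \[0, 255\].
#' @param invert If `FALSE` (the literal convention), foreground is
#'   `X > T`; if `TRUE`, foreground is `X <= T`.
#' @return Binary \{0, 1\} matrix of the same dimensions.
#' @export
binarize <- function(X, T, invert = FALSE) {
  X <- as_gray_image(X)
  if (length(T) != 1L || is.na(T) || T < 0 || T > 255) {
    stop("threshold T must be a single intensity in [0, 255]", call. = FALSE)
  }
  if (invert) as_binary_image(X <= T) else as_binary_image(X > T)
}

#' Otsu threshold over the 256-bin intensity histogram
#'
#' Returns the 8-bit threshold maximizing the between-class variance of
#' the histogram split \{<= T\} vs \{> T\}.  Deterministic: ties are
#' broken by the smallest qualifying threshold.
#'
#' @param X Grayscale integer matrix with at least two distinct
#'   intensities.
#' @return Integer threshold in \[0, 254\], suitable for [binarize()].
#' @export
otsu_threshold <- function(X) {
  X <- as_gray_image(X)
  h <- tabulate(as.vector(X) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # mass of class {<= t}, t = 0..255
  mu <- cumsum(p * (0:255))
  mu_total <- mu[256L]
  valid <- omega > 0 & omega < 1
  if (!any(valid)) {
    stop("Otsu threshold is undefined for a constant image", call. = FALSE)
  }
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the first (smallest) tie
}

#' Build the lung region-of-interest mask
#'
#' Under the `auto_largest_k` policy the ROI is the union of the
#' `roi_k` largest connected components of the cleaned mask (default
#' 2, one per lung field); components of equal area are ordered by
#' first appearance in a row-major scan.  Under `external_file` the ROI
#' is loaded from `config$roi_path` (a \{0, 255\} mask PNG) and must
#' match the mask dimensions.
#'
#' @param W Cleaned binary mask (after small-object removal).
#' @param config A [seg_config()] list.
#' @return Binary ROI matrix `Q` of the same dimensions as `W`.
#' @export
make_roi_mask <- function(W, config = seg_config()) {
  W <- as_binary_image(W)
  policy <- match.arg(config$roi_policy, c("auto_largest_k", "external_file"))
  if (policy == "external_file") {
    if (is.null(config$roi_path)) {
      stop("roi_policy 'external_file' requires config$roi_path",
           call. = FALSE)
    }
    Q <- read_mask(config$roi_path)
    assert_same_dim(W, Q, "mask and external ROI")
    return(Q)
  }
  lab <- label_components(W, config$connectivity)
  n <- max(lab)
  if (n == 0L) {
    stop("cannot build an automatic ROI from an empty mask: no candidate region",
         call. = FALSE)
  }
  areas <- tabulate(lab[lab > 0L], nbins = n)
  k <- min(as.integer(config$roi_k), n)
  # decreasing area, ties by smaller (earlier row-major) label
  keep <- order(-areas, seq_len(n))[seq_len(k)]
  as_binary_image(matrix(as.integer(lab %in% keep), nrow(W), ncol(W)))
}

#' Apply a region-of-interest mask
#'
#' Element-wise product (logical AND) of a binary image with the ROI
#' mask, restricting the segmentation to the pulmonary region.
#'
#' @param W Binary image.
#' @param Q Binary ROI mask of identical dimensions.
#' @return Binary matrix `W * Q`.
#' @export
apply_mask <- function(W, Q) {
  W <- as_binary_image(W)
  Q <- as_binary_image(Q)
  assert_same_dim(W, Q, "image and mask")
  as_binary_image(W * Q)
}

#' Colored overlay of a segmentation on the source radiograph
#'
#' Renders the grayscale image on all three channels and alpha-blends
#' the given colour at weight 0.5 wherever the mask is foreground, so
#' segmented lung fields stand out against the surrounding film.
#'
#' @param X Grayscale integer matrix.
#' @param mask Binary mask of identical dimensions (typically the
#'   closed segmentation).
#' @param color Integer RGB triple in \[0, 255\]; default red.
#' @return An M x N x 3 integer array in \[0, 255\].
#' @export
overlay_image <- function(X, mask, color = c(255L, 0L, 0L)) {
  X <- as_gray_image(X)
  mask <- as_binary_image(mask)
  assert_same_dim(X, mask, "image and mask")
  if (length(color) != 3L || any(is.na(color)) ||
      any(color < 0) || any(color > 255)) {
    stop("overlay color must be an RGB triple in [0, 255]", call. = FALSE)
  }
  out <- array(0L, c(nrow(X), ncol(X), 3L))
  sel <- mask == 1L
  for (ch in 1:3) {
    plane <- X
    plane[sel] <- round_half_up(0.5 * X[sel] + 0.5 * color[ch])
    out[, , ch] <- plane
  }
  storage.mode(out) <- "integer"
  out
}

#' Segmentation pipeline configuration
#'
#' Collects every tunable of [segment()] with the pipeline defaults:
#' Otsu thresholding with inverted polarity (foreground = radiolucent
#' aerated lung), a disk of radius 3 for dilation and radius 7 for
#' closing, small-object removal at 0.1\% of the image area, and an
#' automatic ROI equal to the two largest components (one per lung).
#'
#' @param threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param threshold_value Intensity in \[0, 255\], used when
#'   `threshold_mode = "fixed"`.
#' @param invert_polarity If `TRUE` (default) foreground is `X <= T`
#'   (dark, aerated lung); `FALSE` follows the literal bright-foreground
#'   convention.
#' @param dilation_se,closing_se Structuring elements from
#'   [structuring_element()].
#' @param area_threshold Non-negative integer `U` in pixels, or `NULL`
#'   (default) for 0.1\% of the image area rounded to an integer.
#' @param roi_policy `"auto_largest_k"` (default) or `"external_file"`.
#' @param roi_k Number of components kept by the automatic ROI.
#' @param roi_path Path to an external ROI mask PNG.
#' @param overlay_color RGB triple for the overlay.
#' @param connectivity 8 (default) or 4, for component labelling.
#' @return A list of class `"seg_config"`.
#' @export
seg_config <- function(threshold_mode = c("otsu", "fixed"),
                       threshold_value = 128L,
                       invert_polarity = TRUE,
                       dilation_se = structuring_element("disk", 3L),
                       closing_se = structuring_element("disk", 7L),
                       area_threshold = NULL,
                       roi_policy = c("auto_largest_k", "external_file"),
                       roi_k = 2L,
                       roi_path = NULL,
                       overlay_color = c(255L, 0L, 0L),
                       connectivity = 8L) {
  threshold_mode <- match.arg(threshold_mode)
  roi_policy <- match.arg(roi_policy)
  assert_footprint(dilation_se)
  assert_footprint(closing_se)
  if (!is.null(area_threshold) && (is.na(area_threshold) || area_threshold < 0)) {
    stop("area_threshold must be NULL or a non-negative integer", call. = FALSE)
  }
  if (as.integer(roi_k) < 1L) stop("roi_k must be >= 1", call. = FALSE)
  if (roi_policy == "external_file" && is.null(roi_path)) {
    stop("roi_policy 'external_file' requires roi_path", call. = FALSE)
  }
  structure(list(
    threshold_mode = threshold_mode,
    threshold_value = as.integer(threshold_value),
    invert_polarity = isTRUE(invert_polarity),
    dilation_se = dilation_se,
    closing_se = closing_se,
    area_threshold = if (is.null(area_threshold)) NULL else as.integer(area_threshold),
    roi_policy = roi_policy,
    roi_k = as.integer(roi_k),
    roi_path = roi_path,
    overlay_color = as.integer(overlay_color),
    connectivity = as.integer(connectivity)
  ), class = "seg_config")
}

stage_log <- function(verbose, stage, mask) {
  if (verbose) {
    message(sprintf("[segment] stage=%s foreground=%d", stage, sum(mask)))
  }
}

#' Segment the lung fields of a chest radiograph
#'
#' Runs the full rule-based chain: binarize at a global threshold,
#' dilate, remove small objects, restrict to the lung ROI, close, and
#' build the coloured overlay.  After closing, the mask is intersected
#' with the ROI again so the final segmentation never leaks outside the
#' pulmonary region.  All intermediate stages are retained for
#' inspection.
#'
#' @param X Grayscale integer matrix (\[0, 255\]).
#' @param config A [seg_config()] list.
#' @param verbose Emit one structured log line per stage (stage name
#'   and foreground pixel count) via [message()].
#' @return A list of class `"seg_result"` with elements `binary`,
#'   `dilated`, `cleaned`, `roi`, `masked`, `closed`, `product` (the
#'   intensity image restricted to the closed mask), `overlay`,
#'   `threshold_used`, and `stage_counts`.
#' @examples
#' ph <- make_phantom(grade_default_spec(1, seed = 1))
#' res <- segment(ph$image)
#' evaluate_pair(ph$gt_mask, res$closed)$dice
#' @export
segment <- function(X, config = seg_config(), verbose = FALSE) {
  X <- as_gray_image(X)
  if (!inherits(config, "seg_config")) {
    stop("config must be created with seg_config()", call. = FALSE)
  }
  T_used <- if (config$threshold_mode == "otsu") {
    otsu_threshold(X)
  } else {
    config$threshold_value
  }
  U <- if (is.null(config$area_threshold)) {
    as.integer(round_half_up(0.001 * nrow(X) * ncol(X)))
  } else {
    config$area_threshold
  }

  Y <- binarize(X, T_used, invert = config$invert_polarity)
  stage_log(verbose, "binarize", Y)
  Z <- dilate_mask(Y, config$dilation_se)
  stage_log(verbose, "dilate", Z)
  W <- remove_small(Z, U, config$connectivity)
  stage_log(verbose, "remove_small", W)
  Q <- make_roi_mask(W, config)
  stage_log(verbose, "roi", Q)
  Xm <- apply_mask(W, Q)
  stage_log(verbose, "apply_mask", Xm)
  Xc <- apply_mask(close_mask(Xm, config$closing_se), Q)
  stage_log(verbose, "close", Xc)
  ov <- overlay_image(X, Xc, config$overlay_color)

  structure(list(
    binary = Y, dilated = Z, cleaned = W, roi = Q, masked = Xm, closed = Xc,
    product = as_gray_image(X * Xc),
    overlay = ov,
    threshold_used = T_used,
    stage_counts = c(binarize = sum(Y), dilate = sum(Z), remove_small = sum(W),
                     roi = sum(Q), apply_mask = sum(Xm), close = sum(Xc))
  ), class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("Lung segmentation result (%d x %d)\n",
              nrow(x$binary), ncol(x$binary)))
  cat(sprintf("  threshold used: %d\n", x$threshold_used))
  for (s in names(x$stage_counts)) {
    cat(sprintf("  %-12s %8d foreground px\n", s, x$stage_counts[[s]]))
  }
  invisible(x)
}
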