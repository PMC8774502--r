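#' Segmentation configuration
#'
#' Controls the superpixel-based colour-patch detector. An image is first
#' partitioned into SLIC superpixels; superpixels whose mean colour is far
#' from the estimated skin tone (Euclidean distance over concatenated RGB and
#' hue-circular HSV coordinates) are flagged as artefact, small flagged
#' regions are dropped, and the resulting mask is dilated with an elliptical
#' structuring element before inpainting so patch borders are fully covered.
#'
#' The dilation element defaults to a 9x9 ellipse at the 224x224 resolution
#' convention and is scaled proportionally (odd-rounded, minimum 3) for other
#' image sizes, so it covers the same image fraction at any working scale.
#'
#' @param n_superpixels target number of SLIC superpixels.
#' @param compactness SLIC shape regularity weight (colour on a 0-255 scale).
#' @param colour_distance_threshold threshold on the 7-dimensional
#'   RGB + (cos h, sin h, s, v) distance to the skin tone; superpixels above
#'   it are flagged.
#' @param dilation_size odd diameter in pixels of the elliptical structuring
#'   element, or `NULL` to scale the 9-px/224 convention with `image_size`.
#' @param min_region_area connected regions smaller than this (pixels) are
#'   discarded as noise.
#' @param image_size working resolution used to resolve `dilation_size = NULL`.
#' @param slic_iterations SLIC refinement iterations.
#' @return a `seg_config` object.
#' @export
seg_config <- function(n_superpixels = 200L,
                       compactness = 10,
                       colour_distance_threshold = 1.0,
                       dilation_size = NULL,
                       min_region_area = 25L,
                       image_size = 128L,
                       slic_iterations = 10L) {
  if (is.null(dilation_size)) {
    dilation_size <- max(3L, as.integer(2 * floor(9 * image_size / 224 / 2) + 1))
  }
  cfg <- list(
    n_superpixels = as.integer(n_superpixels),
    compactness = compactness,
    colour_distance_threshold = colour_distance_threshold,
    dilation_size = as.integer(dilation_size),
    min_region_area = as.integer(min_region_area),
    image_size = as.integer(image_size),
    slic_iterations = as.integer(slic_iterations)
  )
  stopifnot(
    cfg$n_superpixels >= 2L,
    cfg$colour_distance_threshold > 0,
    cfg$dilation_size >= 1L, cfg$dilation_size %% 2L == 1L,
    cfg$min_region_area >= 0L,
    cfg$slic_iterations >= 1L
  )
  structure(cfg, class = "seg_config")
}

#' Estimate the average skin tone of an image
#'
#' Returns a robust central colour — the per-channel median over all pixels
#' outside `exclude_mask` (typically the lesion). The median, rather than the
#' mean, keeps a large dark lesion from dragging the estimate.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param exclude_mask optional logical mask of pixels to ignore.
#' @return a list with `rgb` (length-3 median) and `hsv` (HSV of that colour).
#' @export
estimate_skin_tone <- function(image, exclude_mask = NULL) {
  assert_image(image)
  keep <- if (is.null(exclude_mask)) {
    rep(TRUE, prod(dim(image)[1:2]))
  } else {
    assert_mask(exclude_mask, image, "exclude_mask")
    !as.vector(exclude_mask)
  }
  if (!any(keep)) stop("exclude_mask covers all pixels", call. = FALSE)
  rgb <- vapply(1:3, function(ch) median(as.vector(image[, , ch])[keep]), 0)
  hsv <- as.vector(grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 1))
  list(rgb = rgb, hsv = hsv)
}

#' SLIC superpixel labels
#'
#' Deterministic simple linear iterative clustering: cluster centres start on
#' a regular grid and are refined with windowed Lloyd iterations in a joint
#' colour-space metric.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param n_superpixels target superpixel count.
#' @param compactness spatial regularity weight.
#' @param iterations refinement iterations.
#' @return an H x W integer matrix of 1-based labels.
#' @export
slic_superpixels <- function(image, n_superpixels = 200L, compactness = 10,
                             iterations = 10L) {
  assert_image(image)
  d <- dim(image)
  slic_cpp(as.numeric(image), d[1], d[2],
           as.integer(n_superpixels), compactness, as.integer(iterations))
}

# Distance of each superpixel's mean colour to the skin tone, in the
# 7-dimensional RGB + (cos h, sin h, s, v) space.
superpixel_colour_distance <- function(image, labels, skin) {
  means <- vapply(1:3, function(ch) {
    as.vector(tapply(as.vector(image[, , ch]), as.vector(labels), mean))
  }, numeric(length(unique(as.vector(labels)))))
  hsv <- grDevices::rgb2hsv(t(means), maxColorValue = 1)
  ref <- colour_coords(skin$rgb, skin$hsv)
  coords <- cbind(means,
                  cos(2 * pi * hsv[1, ]), sin(2 * pi * hsv[1, ]),
                  hsv[2, ], hsv[3, ])
  sqrt(colSums((t(coords) - ref)^2))
}

#' Detect coloured-patch artefacts
#'
#' Segments the image into SLIC superpixels, estimates the skin tone, and
#' returns the union of superpixels whose mean colour distance to the skin
#' tone exceeds the configured threshold, with connected regions smaller
#' than `min_region_area` removed. Returns an all-`FALSE` mask when nothing
#' exceeds the threshold. The result is *not* dilated; apply [dilate_mask()]
#' before inpainting.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param config a [seg_config()].
#' @return a logical H x W mask.
#' @export
segment_patches <- function(image, config = seg_config()) {
  assert_image(image)
  skin <- estimate_skin_tone(image)
  # cheap pre-filter: if even per-pixel distances barely exceed the
  # threshold, there is no patch and SLIC can be skipped
  if (pixel_distance_count(image, skin, config$colour_distance_threshold) <
      config$min_region_area) {
    return(empty_mask(dim(image)[1], dim(image)[2]))
  }
  labels <- slic_superpixels(image, config$n_superpixels, config$compactness,
                             config$slic_iterations)
  d <- superpixel_colour_distance(image, labels, skin)
  lvl <- sort(unique(as.vector(labels)))
  flagged <- lvl[d > config$colour_distance_threshold]
  mask <- matrix(as.vector(labels) %in% flagged, nrow(labels), ncol(labels))
  drop_small_regions(mask, config$min_region_area)
}

pixel_distance_count <- function(image, skin, threshold) {
  hsv <- image_hsv(image)
  ref <- colour_coords(skin$rgb, skin$hsv)
  d2 <- (image[, , 1] - ref[1])^2 + (image[, , 2] - ref[2])^2 +
    (image[, , 3] - ref[3])^2 +
    (cos(2 * pi * hsv[, , 1]) - ref[4])^2 +
    (sin(2 * pi * hsv[, , 1]) - ref[5])^2 +
    (hsv[, , 2] - ref[6])^2 + (hsv[, , 3] - ref[7])^2
  sum(d2 > threshold^2)
}

drop_small_regions <- function(mask, min_area) {
  if (!any(mask) || min_area <= 1L) return(mask)
  labels <- from_ebimage_gray(EBImage::bwlabel(as_ebimage_gray(mask)))
  sizes <- table(labels[labels > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Elliptical structuring element
#'
#' @param size odd diameter in pixels.
#' @return a 0/1 matrix of dimension `size x size`.
#' @export
elliptical_kernel <- function(size = 9L) {
  stopifnot(size >= 1L, size %% 2L == 1L)
  if (size == 1L) return(matrix(1, 1, 1))
  EBImage::makeBrush(as.integer(size), shape = "disc")
}

#' Morphological mask dilation
#'
#' Single-application binary dilation; the output always contains the input.
#'
#' @param mask logical matrix.
#' @param kernel structuring element matrix (see [elliptical_kernel()]), or an
#'   odd integer diameter.
#' @return dilated logical mask.
#' @export
dilate_mask <- function(mask, kernel = elliptical_kernel(9L)) {
  assert_mask(mask)
  if (length(kernel) == 1L && is.numeric(kernel)) {
    kernel <- elliptical_kernel(as.integer(kernel))
  }
  if (!any(mask)) return(mask)
  out <- from_ebimage_gray(EBImage::dilate(as_ebimage_gray(mask), kernel))
  out > 0.5
}

#' Read a binary mask from a single-channel PNG
#'
#' Pixels above half intensity are mask members (0 = background,
#' 255 = artefact).
#'
#' @param path PNG file path.
#' @return a logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical masks of identical dimension.
#' @return IoU in [0, 1]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
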