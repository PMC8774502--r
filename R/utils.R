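#' @useDynLib shortcutaudit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile sd cor rbinom rnorm runif predict setNames
#' @importFrom utils head write.csv read.csv
NULL

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed (< 2^31) from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

clamp01 <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_image <- function(x, name = "image") {
  if (!is_rgb_image(x)) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", name), call. = FALSE)
  }
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) {
    stop(sprintf("`%s` must have intensities in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_mask <- function(mask, image = NULL, name = "mask") {
  if (!is.matrix(mask) || !(is.logical(mask) || all(mask %in% c(0, 1)))) {
    stop(sprintf("`%s` must be a logical matrix", name), call. = FALSE)
  }
  if (!is.null(image) && !all(dim(mask) == dim(image)[1:2])) {
    stop(sprintf("`%s` must match the image height x width", name), call. = FALSE)
  }
  invisible(mask)
}

empty_mask <- function(h, w = h) matrix(FALSE, h, w)

# Per-pixel HSV coordinates of an RGB image array; returns H x W x 3 with
# h, s, v all in [0, 1] (hue in turns).
image_hsv <- function(image) {
  d <- dim(image)
  m <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]),
    g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]),
    maxColorValue = 1
  )
  array(c(m[1, ], m[2, ], m[3, ]), dim = d)
}

hsv_to_rgb <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

# 7-dimensional colour coordinates used by the segmentation distance:
# (r, g, b, cos(2*pi*h), sin(2*pi*h), s, v). Hue is treated circularly so the
# red/magenta wrap-around does not inflate distances.
colour_coords <- function(rgb, hsv) {
  c(rgb, cos(2 * pi * hsv[1]), sin(2 * pi * hsv[1]), hsv[2], hsv[3])
}

# Apply an EBImage morphological/filter op defined on x-major images to a
# row-major (H x W) matrix.
as_ebimage_gray <- function(mask) t(mask * 1)
from_ebimage_gray <- function(img) t(img)
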