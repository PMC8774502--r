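.backends <- new.env(parent = emptyenv())

#' Register an inpainting backend
#'
#' A backend is a function `fn(image, mask)` returning an image of identical
#' shape in which pixels outside the mask are bit-exactly unchanged and
#' filled pixels lie in [0, 1]. The contract is verified on every call by
#' [inpaint()]. Registering under an existing name replaces the backend, so
#' a learned (e.g. neural) inpainter can be plugged in without code changes.
#'
#' @param name backend identifier.
#' @param fn the fill function.
#' @export
register_inpaint_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .backends)
  invisible(name)
}

#' List registered inpainting backends
#' @return character vector of backend names.
#' @export
inpaint_backends <- function() sort(ls(.backends))

get_backend <- function(name) {
  if (!exists(name, envir = .backends, inherits = FALSE)) {
    stop(sprintf("unknown inpainting backend '%s'; registered: %s",
                 name, paste(inpaint_backends(), collapse = ", ")),
         call. = FALSE)
  }
  get(name, envir = .backends)
}

# Harmonic (Laplace) fill: masked pixels solve the discrete Laplace equation
# with Dirichlet data from the unmasked 4-neighbourhood, i.e. the smoothest
# interpolation of the surrounding skin. Solved exactly per channel with one
# sparse SPD system shared across channels.
harmonic_fill <- function(image, mask) {
  if (!any(mask)) return(image)
  h <- nrow(mask); w <- ncol(mask)
  if (all(mask)) stop("cannot inpaint: mask covers the entire image", call. = FALSE)
  idx <- matrix(0L, h, w)
  unknown <- which(mask)
  idx[unknown] <- seq_along(unknown)
  ur <- (unknown - 1L) %% h + 1L
  uc <- (unknown - 1L) %/% h + 1L

  ii <- list(); jj <- list(); xx <- list()
  rhs <- matrix(0, length(unknown), 3)
  deg <- integer(length(unknown))
  flat <- function(r, c) (c - 1L) * h + r
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- ur + d[1]; nc <- uc + d[2]
    inb <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    deg <- deg + inb
    rr <- pmin(pmax(nr, 1L), h); cc <- pmin(pmax(nc, 1L), w)
    nf <- flat(rr, cc)
    is_unknown <- inb & mask[cbind(rr, cc)]
    is_known <- inb & !is_unknown
    if (any(is_unknown)) {
      ii[[length(ii) + 1L]] <- which(is_unknown)
      jj[[length(jj) + 1L]] <- idx[nf[is_unknown]]
      xx[[length(xx) + 1L]] <- rep(-1, sum(is_unknown))
    }
    if (any(is_known)) {
      for (ch in 1:3) {
        chan <- image[, , ch]
        rhs[which(is_known), ch] <- rhs[which(is_known), ch] + chan[nf[is_known]]
      }
    }
  }
  m <- length(unknown)
  A <- Matrix::sparseMatrix(
    i = c(seq_len(m), unlist(ii)),
    j = c(seq_len(m), unlist(jj)),
    x = c(as.numeric(deg), unlist(xx)),
    dims = c(m, m)
  )
  sol <- as.matrix(Matrix::solve(A, rhs))
  out <- image
  for (ch in 1:3) {
    chan <- out[, , ch]
    chan[unknown] <- pmin(1, pmax(0, sol[, ch]))
    out[, , ch] <- chan
  }
  out
}

identity_fill <- function(image, mask) image

register_inpaint_backend("harmonic", harmonic_fill)
register_inpaint_backend("identity", identity_fill)

#' Inpaint a masked region
#'
#' Fills `mask` with the selected backend and verifies the backend contract:
#' pixels outside the mask are unchanged and filled pixels are in [0, 1].
#' The reference backend `"harmonic"` is a classical smooth interpolation of
#' the surrounding pixels; `"identity"` returns the input unchanged and is
#' useful as a no-op control.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask logical matrix marking the fill region.
#' @param backend backend name (see [inpaint_backends()]) or a fill function.
#' @return the inpainted image.
#' @export
inpaint <- function(image, mask, backend = "harmonic") {
  assert_image(image)
  assert_mask(mask, image)
  fn <- if (is.function(backend)) backend else get_backend(backend)
  out <- fn(image, mask)
  if (!identical(dim(out), dim(image))) {
    stop("backend contract violation: output shape differs", call. = FALSE)
  }
  keep <- !mask
  for (ch in 1:3) {
    if (!identical(out[, , ch][keep], image[, , ch][keep])) {
      stop("backend contract violation: pixels outside the mask changed",
           call. = FALSE)
    }
  }
  if (any(mask) && (min(out[, , 1][mask], out[, , 2][mask], out[, , 3][mask]) < 0 ||
                    max(out[, , 1][mask], out[, , 2][mask], out[, , 3][mask]) > 1)) {
    stop("backend contract violation: filled pixels out of [0, 1]", call. = FALSE)
  }
  out
}

#' Random elliptical mask parameters
#'
#' Geometry of the random validity-check masks. Defaults mirror the synthetic
#' generator's patch geometry (semi-axes 10-25% of the image side, centres in
#' the outer quarter border ring) so that randomly inpainted regions are
#' in-distribution with respect to where real patches occur.
#'
#' @param axes_range min/max semi-axes as a fraction of the image side.
#' @param boundary_ring border band (fraction of image side) for the centre.
#' @return a `random_mask_params` object.
#' @export
random_mask_params <- function(axes_range = c(0.10, 0.25),
                               boundary_ring = 0.25) {
  stopifnot(
    axes_range[1] > 0, axes_range[1] <= axes_range[2], axes_range[2] < 0.5,
    boundary_ring > 0, boundary_ring <= 0.5
  )
  structure(list(axes_range = as.numeric(axes_range),
                 boundary_ring = boundary_ring),
            class = "random_mask_params")
}

# Draw a rotated ellipse with centre in the boundary ring, fully inside the
# image. Shared by the dataset generator and the random-mask sampler so both
# use the same placement prior. Consumes 5 RNG draws + 1 edge draw.
sample_ring_ellipse <- function(h, w, axes_range, boundary_ring) {
  side <- min(h, w)
  a <- runif(1, axes_range[1], axes_range[2]) * side
  b <- runif(1, axes_range[1], axes_range[2]) * side
  theta <- runif(1, 0, pi)
  rmax <- max(a, b)
  ring <- boundary_ring * side
  edge <- sample(1:4, 1)
  depth <- runif(1, rmax, max(ring, rmax))
  along_max <- c(h, h, w, w)[edge]
  along <- runif(1, min(rmax, along_max - rmax), max(rmax, along_max - rmax))
  cx <- switch(edge, depth, w - depth, along, along)
  cy <- switch(edge, along, along, depth, h - depth)
  list(mask = ellipse_mask(h, w, cx, cy, a, b, theta),
       cx = cx, cy = cy, a = a, b = b, theta = theta)
}

#' Draw a random elliptical mask near the image boundary
#'
#' @param image_shape integer vector `c(h, w)` (extra entries ignored).
#' @param params a [random_mask_params()].
#' @param seed optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return a logical H x W mask containing one filled rotated ellipse.
#' @export
random_elliptical_mask <- function(image_shape, params = random_mask_params(),
                                   seed = NULL) {
  h <- image_shape[1]; w <- image_shape[2]
  draw <- function() sample_ring_ellipse(h, w, params$axes_range,
                                         params$boundary_ring)$mask
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# 2-D Gaussian window, sd in pixels, normalised to sum 1.
gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM with the standard Gaussian-weighted 11x11 window (sigma = 1.5),
#' stability constants K1 = 0.01, K2 = 0.03 on a unit dynamic range, averaged
#' over colour channels. The half-window border is excluded from the mean so
#' no padding convention leaks into the score.
#'
#' @param image_a,image_b arrays (H x W x 3) or matrices of identical shape,
#'   intensities in [0, 1].
#' @return a scalar in (-1, 1]; 1 for identical images. Symmetric in its
#'   arguments.
#' @export
ssim <- function(image_a, image_b) {
  if (!identical(dim(image_a), dim(image_b))) {
    stop("images must have identical shape", call. = FALSE)
  }
  if (length(dim(image_a)) == 2L) {
    dim(image_a) <- c(dim(image_a), 1L)
    dim(image_b) <- c(dim(image_b), 1L)
  }
  mean(vapply(seq_len(dim(image_a)[3]), function(ch) {
    ssim_channel(image_a[, , ch], image_b[, , ch])
  }, 0))
}

ssim_channel <- function(x, y, size = 11L, sigma = 1.5) {
  w <- gaussian_window(size, sigma)
  half <- (size - 1L) / 2L
  conv <- function(m) EBImage::filter2(m, w)
  mux <- conv(x); muy <- conv(y)
  sxx <- conv(x * x) - mux^2
  syy <- conv(y * y) - muy^2
  sxy <- conv(x * y) - mux * muy
  c1 <- 0.01^2; c2 <- 0.03^2
  map <- ((2 * mux * muy + c1) * (2 * sxy + c2)) /
    ((mux^2 + muy^2 + c1) * (sxx + syy + c2))
  h <- nrow(x); wd <- ncol(x)
  if (h <= 2 * half || wd <= 2 * half) return(mean(map))
  mean(map[(half + 1):(h - half), (half + 1):(wd - half)])
}

#' In-distribution validity check for an inpainting backend
#'
#' Draws one random elliptical mask per patch-free image, inpaints it, and
#' summarises (i) the SSIM between each original and its randomly inpainted
#' version and (ii) the classifier's probability shift
#' `dp = P(malignant | inpainted) - P(malignant | original)`. If inpainting is
#' an uninformative replacement, the dp distribution should centre on zero;
#' images with `|dp|` above `outlier_threshold` are flagged for inspection
#' rather than dropped.
#'
#' @param classifier a fitted classifier (see [fit_reference()]).
#' @param images list of `labeled_image` objects with empty patch masks.
#' @param mask_params a [random_mask_params()].
#' @param backend inpainting backend name.
#' @param seed RNG seed for the mask draws.
#' @param outlier_threshold flag images with `|dp|` above this (default 0.2).
#' @return a `validity_report` list with SSIM and dp summaries, the per-image
#'   table, and the flagged outlier ids.
#' @export
validity_check <- function(classifier, images,
                           mask_params = random_mask_params(),
                           backend = "harmonic", seed = 1L,
                           outlier_threshold = 0.2) {
  if (length(images) == 0L) stop("empty image set", call. = FALSE)
  if (any(vapply(images, `[[`, NA, "has_patch"))) {
    stop("validity check requires images without patches", call. = FALSE)
  }
  altered <- with_seed(seed, lapply(images, function(im) {
    m <- random_elliptical_mask(dim(im$pixels), mask_params)
    list(image = inpaint(im$pixels, m, backend), mask = m)
  }))
  ssims <- vapply(seq_along(images), function(i) {
    ssim(images[[i]]$pixels, altered[[i]]$image)
  }, 0)
  p0 <- predict_proba(classifier, lapply(images, `[[`, "pixels"),
                      ids = dataset_ids(images))
  p1 <- predict_proba(classifier, lapply(altered, `[[`, "image"),
                      ids = dataset_ids(images))
  dp <- p1$p_malignant - p0$p_malignant
  outliers <- dataset_ids(images)[abs(dp) > outlier_threshold]
  structure(list(
    n = length(images),
    backend = backend,
    ssim = list(median = median(ssims), mean = mean(ssims), sd = sd(ssims)),
    dp = list(
      mean = mean(dp), sd = sd(dp),
      quantiles = quantile(dp, c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE),
      frac_outliers = mean(abs(dp) > outlier_threshold),
      outlier_threshold = outlier_threshold
    ),
    outlier_ids = outliers,
    per_image = data.frame(id = dataset_ids(images), ssim = ssims, dp = dp)
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> n = %d, backend = %s\n", x$n, x$backend))
  cat(sprintf("  SSIM   median %.3f, mean %.3f (sd %.3f)\n",
              x$ssim$median, x$ssim$mean, x$ssim$sd))
  cat(sprintf("  dP     mean %+.4f (sd %.4f), |dP| > %.2f for %.1f%% (%d flagged)\n",
              x$dp$mean, x$dp$sd, x$dp$outlier_threshold,
              100 * x$dp$frac_outliers, length(x$outlier_ids)))
  invisible(x)
}
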