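#' Parameters for the synthetic dermoscopy generator
#'
#' The generator emulates the confound structure of the ISIC archive: two
#' classes of lesion images where elliptical, saturated colour-calibration
#' patches occur in roughly half of the benign images and in none of the
#' malignant ones, with patches placed near the image boundary and away from
#' the lesion. Defaults encode that situation: 46% of benign images carry a
#' patch, no malignant image does.
#'
#' @param image_size side length in pixels of the square images (>= 32).
#' @param n_benign,n_malignant number of images per class.
#' @param patch_fraction_benign,patch_fraction_malignant probability that an
#'   image of the class receives a coloured patch.
#' @param lesion_contrast_benign,lesion_contrast_malignant dimensionless mean
#'   lesion darkness per class (0 = invisible, 1 = black); border irregularity
#'   is tied to the same parameter so darker lesions also have more ragged
#'   borders, giving the classifier a legitimate, non-shortcut signal.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise, in
#'   intensity units on the [0, 1] scale.
#' @param patch_axes_range range of the patch ellipse semi-axes as a fraction
#'   of the image side.
#' @param boundary_ring width of the border band (fraction of the image side)
#'   in which patch centres are placed.
#' @param seed integer RNG seed; identical params + seed reproduce the dataset
#'   bit-exactly.
#' @return an object of class `dermo_params`.
#' @export
dermo_params <- function(image_size = 128L,
                         n_benign = 100L,
                         n_malignant = 100L,
                         patch_fraction_benign = 0.46,
                         patch_fraction_malignant = 0,
                         lesion_contrast_benign = 0.35,
                         lesion_contrast_malignant = 0.55,
                         noise_sd = 0.02,
                         patch_axes_range = c(0.10, 0.25),
                         boundary_ring = 0.25,
                         seed = 1L) {
  p <- list(
    image_size = as.integer(image_size),
    n_benign = as.integer(n_benign),
    n_malignant = as.integer(n_malignant),
    patch_fraction_benign = patch_fraction_benign,
    patch_fraction_malignant = patch_fraction_malignant,
    lesion_contrast_benign = lesion_contrast_benign,
    lesion_contrast_malignant = lesion_contrast_malignant,
    noise_sd = noise_sd,
    patch_axes_range = as.numeric(patch_axes_range),
    boundary_ring = boundary_ring,
    seed = as.integer(seed)
  )
  stopifnot(
    p$image_size >= 32L,
    p$n_benign >= 0L, p$n_malignant >= 0L,
    p$patch_fraction_benign >= 0, p$patch_fraction_benign <= 1,
    p$patch_fraction_malignant >= 0, p$patch_fraction_malignant <= 1,
    p$noise_sd >= 0,
    length(p$patch_axes_range) == 2L,
    p$patch_axes_range[1] > 0,
    p$patch_axes_range[1] <= p$patch_axes_range[2],
    p$patch_axes_range[2] < 0.5,
    p$boundary_ring > 0, p$boundary_ring <= 0.5
  )
  structure(p, class = "dermo_params")
}

# Saturated patch palette, in HSV hue turns: blue, green, cyan, magenta.
# Hues are deliberately far from skin tones (~0.05) so the colour-distance
# segmentation has the same kind of margin real calibration charts have.
PATCH_HUES <- c(blue = 0.60, green = 0.33, cyan = 0.50, magenta = 0.83)

# Base skin tone (light Fitzpatrick-type dermoscopy background).
SKIN_RGB <- c(0.80, 0.60, 0.52)

# Low-frequency multiplicative texture: coarse Gaussian field, bilinearly
# upsampled to full resolution.
skin_background <- function(size, noise_sd) {
  base <- clamp01(SKIN_RGB + rnorm(3, 0, 0.02))
  coarse <- matrix(rnorm(81, 0, 1), 9, 9)
  field <- bilinear_upsample(coarse, size)
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] * (1 + 0.06 * field)
  clamp01(img)
}

bilinear_upsample <- function(m, size) {
  n <- nrow(m)
  pos <- seq(1, n, length.out = size)
  i0 <- pmin(floor(pos), n - 1L)
  fr <- pos - i0
  rows <- m[i0, , drop = FALSE] * (1 - fr) + m[i0 + 1, , drop = FALSE] * fr
  t(t(rows[, i0, drop = FALSE]) * (1 - fr) + t(rows[, i0 + 1, drop = FALSE]) * fr)
}

# Rasterise a rotated ellipse on an H x W grid. cx, cy, axes in pixels.
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  dx <- xs - cx
  dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# Irregular star-shaped lesion region: radius modulated by low-order random
# harmonics; irregularity controls the modulation depth.
lesion_region <- function(size, r0, irregularity, cx, cy) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), size), size, size)
  dx <- xs - cx
  dy <- ys - cy
  theta <- atan2(dy, dx)
  f <- 0
  for (k in 2:6) {
    f <- f + rnorm(1) * cos(k * theta + runif(1, 0, 2 * pi)) / k
  }
  r <- r0 * pmax(0.2, 1 + irregularity * f)
  d <- sqrt(dx * dx + dy * dy)
  # soft 1.5-px alpha edge; the binary mask thresholds alpha at 0.5
  alpha <- clamp01((r - d) / 1.5 + 0.5)
  alpha
}

#' Generate a confounded synthetic dermoscopy dataset
#'
#' Each image is a textured skin background plus one lesion (an irregular
#' dark blob whose darkness and border raggedness differ by class), and, with
#' the per-class patch probability, one saturated elliptical colour patch
#' placed in the border ring and disjoint from the lesion. Ground-truth
#' lesion and patch masks are recorded on every image.
#'
#' If no lesion-disjoint patch placement is found within 50 attempts the
#' image is emitted without a patch and flagged (`patch_failed = TRUE`).
#'
#' @param params a [dermo_params()] object.
#' @return a list of `labeled_image` objects (class `dermo_dataset`), each
#'   with fields `id`, `pixels` (H x W x 3 in [0, 1]), `label`
#'   ("benign"/"malignant"), `lesion_mask`, `patch_mask`, `has_patch`.
#' @export
generate_dermo_dataset <- function(params = dermo_params()) {
  stopifnot(inherits(params, "dermo_params"))
  with_seed(params$seed, {
    images <- vector("list", params$n_benign + params$n_malignant)
    k <- 0L
    for (label in c("benign", "malignant")) {
      n <- if (label == "benign") params$n_benign else params$n_malignant
      frac <- if (label == "benign") params$patch_fraction_benign else params$patch_fraction_malignant
      contrast <- if (label == "benign") params$lesion_contrast_benign else params$lesion_contrast_malignant
      if (n == 0L) next
      wants_patch <- rbinom(n, 1L, frac) == 1L
      for (i in seq_len(n)) {
        k <- k + 1L
        images[[k]] <- generate_one_image(
          id = sprintf("%s_%04d", label, i),
          label = label, contrast = contrast,
          wants_patch = wants_patch[i], params = params
        )
      }
    }
    structure(images[seq_len(k)], class = "dermo_dataset", params = params)
  })
}

generate_one_image <- function(id, label, contrast, wants_patch, params) {
  size <- params$image_size
  img <- skin_background(size, params$noise_sd)

  darkness <- min(0.85, max(0.05, rnorm(1, contrast, 0.08)))
  irregularity <- min(0.60, max(0.02, 0.10 + 0.45 * contrast + rnorm(1, 0, 0.04)))
  r0 <- runif(1, 0.14, 0.22) * size
  cx <- runif(1, 0.38, 0.62) * size
  cy <- runif(1, 0.38, 0.62) * size
  alpha <- lesion_region(size, r0, irregularity, cx, cy)
  lesion_mask <- alpha > 0.5
  lesion_rgb_scale <- 1 - darkness * c(0.75, 1.00, 1.05)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - alpha) +
      img[, , ch] * max(0, lesion_rgb_scale[ch]) * alpha
  }

  patch_mask <- empty_mask(size)
  patch_failed <- FALSE
  if (wants_patch) {
    placed <- FALSE
    for (attempt in 1:50) {
      cand <- sample_ring_ellipse(size, size, params$patch_axes_range,
                                  params$boundary_ring)$mask
      if (any(cand) && !any(cand & lesion_mask)) {
        hue <- PATCH_HUES[[sample(length(PATCH_HUES), 1)]]
        col <- hsv_to_rgb(hue, runif(1, 0.75, 0.95), runif(1, 0.75, 0.95))
        for (ch in 1:3) {
          chan <- img[, , ch]
          chan[cand] <- col[ch]
          img[, , ch] <- chan
        }
        patch_mask <- cand
        placed <- TRUE
        break
      }
    }
    patch_failed <- !placed
  }

  img <- clamp01(img + array(rnorm(size * size * 3, 0, params$noise_sd),
                             dim = c(size, size, 3)))
  labeled_image(id, img, label, lesion_mask, patch_mask, patch_failed)
}

#' Construct a labelled image record
#'
#' @param id opaque image identifier.
#' @param pixels H x W x 3 array with intensities in [0, 1].
#' @param label "benign" or "malignant".
#' @param lesion_mask,patch_mask optional logical masks matching the image.
#' @param patch_failed flag set by the generator when no lesion-disjoint patch
#'   placement was found.
#' @return a `labeled_image` object.
#' @export
labeled_image <- function(id, pixels, label,
                          lesion_mask = NULL, patch_mask = NULL,
                          patch_failed = FALSE) {
  assert_image(pixels, "pixels")
  label <- match.arg(label, c("benign", "malignant"))
  if (is.null(lesion_mask)) lesion_mask <- empty_mask(dim(pixels)[1], dim(pixels)[2])
  if (is.null(patch_mask)) patch_mask <- empty_mask(dim(pixels)[1], dim(pixels)[2])
  assert_mask(lesion_mask, pixels, "lesion_mask")
  assert_mask(patch_mask, pixels, "patch_mask")
  if (any(lesion_mask & patch_mask)) {
    stop("patch_mask and lesion_mask must be disjoint", call. = FALSE)
  }
  structure(
    list(id = as.character(id), pixels = pixels, label = label,
         lesion_mask = lesion_mask, patch_mask = patch_mask,
         has_patch = any(patch_mask), patch_failed = isTRUE(patch_failed)),
    class = "labeled_image"
  )
}

#' @export
print.dermo_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  np <- sum(vapply(x, `[[`, NA, "has_patch"))
  cat(sprintf("<dermo_dataset> %d images (%d benign, %d malignant), %d with patches\n",
              length(x), sum(labs == "benign"), sum(labs == "malignant"), np))
  invisible(x)
}

dataset_labels <- function(dataset) vapply(dataset, `[[`, "", "label")
dataset_ids <- function(dataset) vapply(dataset, `[[`, "", "id")
dataset_has_patch <- function(dataset) vapply(dataset, `[[`, NA, "has_patch")

#' Stratified train/test split
#'
#' Splits a dataset into disjoint, exhaustive train and test parts, stratified
#' by class label, seeded and reproducible. The default follows the common
#' 80/20 convention.
#'
#' @param dataset a list of `labeled_image` objects.
#' @param train_fraction fraction of each class assigned to the training set.
#' @param seed RNG seed.
#' @return a list with elements `train` and `test`.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  labs <- dataset_labels(dataset)
  for (cl in unique(labs)) {
    if (sum(labs == cl) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 members", cl), call. = FALSE)
    }
  }
  with_seed(seed, {
    train_idx <- integer(0)
    for (cl in sort(unique(labs))) {
      idx <- which(labs == cl)
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    train_idx <- sort(train_idx)
    list(
      train = structure(dataset[train_idx], class = "dermo_dataset"),
      test = structure(dataset[-train_idx], class = "dermo_dataset")
    )
  })
}

#' Write a dataset to disk
#'
#' Images are written as 8-bit RGB PNG, masks as single-channel PNG (0/255),
#' labels as a CSV with columns `id,label,has_patch`, and a YAML manifest
#' recording the generator parameters and file layout.
#'
#' @param dataset a `dermo_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dermo_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (im in dataset) {
    png::writePNG(aperm(im$pixels, c(1, 2, 3)),
                  file.path(dir, "images", paste0(im$id, ".png")))
    png::writePNG(im$lesion_mask * 1,
                  file.path(dir, "masks", paste0(im$id, "_lesion.png")))
    png::writePNG(im$patch_mask * 1,
                  file.path(dir, "masks", paste0(im$id, "_patch.png")))
  }
  labels <- data.frame(
    id = dataset_ids(dataset),
    label = dataset_labels(dataset),
    has_patch = dataset_has_patch(dataset)
  )
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  params <- attr(dataset, "params")
  manifest <- list(
    n_images = length(dataset),
    labels = "labels.csv",
    images = "images",
    masks = "masks",
    params = if (is.null(params)) NULL else unclass(params)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dermo_dataset()]
#'
#' @param dir dataset directory containing `manifest.yaml`.
#' @return a `dermo_dataset`.
#' @export
read_dermo_dataset <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$id[i]
    px <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    lm_path <- file.path(dir, "masks", paste0(id, "_lesion.png"))
    pm_path <- file.path(dir, "masks", paste0(id, "_patch.png"))
    lm <- if (file.exists(lm_path)) read_mask_png(lm_path) else NULL
    pm <- if (file.exists(pm_path)) read_mask_png(pm_path) else NULL
    labeled_image(id, px, labels$label[i], lm, pm)
  })
  structure(images, class = "dermo_dataset")
}
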