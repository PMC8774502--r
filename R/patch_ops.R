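#' Extract a coloured-patch template from an image
#'
#' Crops the tight bounding box of `patch_mask` and keeps the in-crop mask,
#' so the template can later be composited into other images. Masked pixels
#' are copied bit-exactly.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param patch_mask non-empty logical mask of the patch.
#' @param source_id provenance string recorded on the template.
#' @return a `patch_template` with fields `pixels`, `mask`, `source_id`.
#' @export
extract_patch <- function(image, patch_mask, source_id = "unknown") {
  assert_image(image)
  assert_mask(patch_mask, image, "patch_mask")
  if (!any(patch_mask)) stop("patch_mask is empty", call. = FALSE)
  rows <- range(which(rowSums(patch_mask) > 0))
  cols <- range(which(colSums(patch_mask) > 0))
  structure(list(
    pixels = image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
    mask = patch_mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
    source_id = as.character(source_id)
  ), class = "patch_template")
}

#' Composite a patch template into an image
#'
#' Places the template at a random location whose centre lies in the border
#' ring, rejecting placements that overlap `lesion_mask` (the automated
#' counterpart of excluding images where an inserted patch covers the
#' lesion). Pixels outside the placed mask are unchanged bit-exactly.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param template a [extract_patch()] result.
#' @param lesion_mask optional logical mask the placement must not touch.
#' @param boundary_ring border band (fraction of the short image side) for
#'   the template centre.
#' @param max_attempts placement attempts before giving up.
#' @param seed optional seed for a reproducible placement.
#' @param image_id used in the error message when no placement is found, so
#'   the caller can log the exclusion.
#' @return list with `image` (the composite) and `inserted_mask` (full-size
#'   logical mask of the placed template).
#' @export
insert_patch <- function(image, template, lesion_mask = NULL,
                         boundary_ring = 0.25, max_attempts = 50L,
                         seed = NULL, image_id = "image") {
  assert_image(image)
  stopifnot(inherits(template, "patch_template"))
  h <- dim(image)[1]; w <- dim(image)[2]
  th <- nrow(template$mask); tw <- ncol(template$mask)
  if (th > h || tw > w) stop("template does not fit inside the image", call. = FALSE)
  if (is.null(lesion_mask)) lesion_mask <- empty_mask(h, w)
  assert_mask(lesion_mask, image, "lesion_mask")

  place <- function() {
    side <- min(h, w)
    ring <- boundary_ring * side
    for (attempt in seq_len(max_attempts)) {
      # top-left corner such that the template centre is within `ring` of an
      # edge and the crop is fully inside the image
      edge <- sample(1:4, 1)
      depth <- runif(1, 0, max(0, ring - 1))
      r0 <- switch(edge,
        round(depth) + 1L,                           # top
        h - th + 1L - round(depth),                  # bottom
        sample(max(1L, h - th + 1L), 1L),            # left
        sample(max(1L, h - th + 1L), 1L))            # right
      c0 <- switch(edge,
        sample(max(1L, w - tw + 1L), 1L),
        sample(max(1L, w - tw + 1L), 1L),
        round(depth) + 1L,
        w - tw + 1L - round(depth))
      r0 <- min(max(r0, 1L), h - th + 1L)
      c0 <- min(max(c0, 1L), w - tw + 1L)
      placed <- empty_mask(h, w)
      placed[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)] <- template$mask
      if (!any(placed & lesion_mask)) {
        out <- image
        for (ch in 1:3) {
          crop <- out[r0:(r0 + th - 1L), c0:(c0 + tw - 1L), ch]
          crop[template$mask] <- template$pixels[, , ch][template$mask]
          out[r0:(r0 + th - 1L), c0:(c0 + tw - 1L), ch] <- crop
        }
        return(list(image = out, inserted_mask = placed))
      }
    }
    stop(sprintf("no lesion-disjoint patch placement found for '%s' in %d attempts",
                 image_id, max_attempts), call. = FALSE)
  }
  if (is.null(seed)) place() else with_seed(seed, place())
}

#' Footprint-inpainting control
#'
#' Inpaints the region an inserted patch *would* cover, without compositing
#' the patch, to separate the effect of the patch itself from the effect of
#' occluding that area: if prediction shifts were caused by the covered
#' pixels, inpainting the same footprint should shift predictions similarly.
#'
#' @param image original (patch-free) H x W x 3 array.
#' @param inserted_mask the mask returned by [insert_patch()].
#' @param backend inpainting backend name.
#' @return the original image with the footprint region inpainted.
#' @export
inpaint_footprint_control <- function(image, inserted_mask, backend = "harmonic") {
  inpaint(image, inserted_mask, backend)
}

#' Build a patch template library
#'
#' Extracts one template per patch-bearing image, using the ground-truth
#' patch mask when present or running [segment_patches()] otherwise (the
#' same segmentation approach that locates patches for removal).
#'
#' @param images list of `labeled_image` objects.
#' @param config a [seg_config()] used when an image has no stored mask.
#' @param use_true_masks use stored ground-truth patch masks when available.
#' @return list of `patch_template` objects (may be empty).
#' @export
build_patch_library <- function(images, config = seg_config(),
                                use_true_masks = TRUE) {
  out <- list()
  for (im in images) {
    mask <- if (use_true_masks && any(im$patch_mask)) {
      im$patch_mask
    } else {
      segment_patches(im$pixels, config)
    }
    if (any(mask)) {
      out[[length(out) + 1L]] <- extract_patch(im$pixels, mask, im$id)
    }
  }
  out
}

#' Write a patch template library as paired PNG files with a CSV index
#'
#' @param library list of `patch_template` objects.
#' @param dir output directory.
#' @export
write_patch_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(file = character(0), source_id = character(0))
  for (i in seq_along(library)) {
    stem <- sprintf("template_%03d", i)
    png::writePNG(library[[i]]$pixels, file.path(dir, paste0(stem, ".png")))
    write_mask_png(library[[i]]$mask, file.path(dir, paste0(stem, "_mask.png")))
    idx <- rbind(idx, data.frame(file = stem, source_id = library[[i]]$source_id))
  }
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a patch template library written by [write_patch_library()]
#'
#' @param dir library directory.
#' @return list of `patch_template` objects.
#' @export
read_patch_library <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    px <- png::readPNG(file.path(dir, paste0(idx$file[i], ".png")))
    m <- read_mask_png(file.path(dir, paste0(idx$file[i], "_mask.png")))
    structure(list(pixels = px, mask = m, source_id = idx$source_id[i]),
              class = "patch_template")
  })
}
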