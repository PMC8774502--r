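test_that("extraction is tight, area-preserving and round-trips", {
  im <- Filter(function(im) im$has_patch, small_confounded())[[1]]
  tpl <- extract_patch(im$pixels, im$patch_mask, im$id)
  expect_identical(sum(tpl$mask), sum(im$patch_mask))
  # tight bounding box: every crop edge row/column holds a mask pixel
  expect_true(any(tpl$mask[1, ]))
  expect_true(any(tpl$mask[nrow(tpl$mask), ]))
  expect_true(any(tpl$mask[, 1]))
  expect_true(any(tpl$mask[, ncol(tpl$mask)]))
  # re-inserting at the original location reproduces the source image
  rows <- range(which(rowSums(im$patch_mask) > 0))
  cols <- range(which(colSums(im$patch_mask) > 0))
  rebuilt <- im$pixels
  for (ch in 1:3) {
    crop <- rebuilt[rows[1]:rows[2], cols[1]:cols[2], ch]
    crop[tpl$mask] <- tpl$pixels[, , ch][tpl$mask]
    rebuilt[rows[1]:rows[2], cols[1]:cols[2], ch] <- crop
  }
  expect_identical(rebuilt, im$pixels)
  expect_error(extract_patch(im$pixels, matrix(FALSE, 96, 96)), "empty")
})

test_that("insertion is conservative, seeded and lesion-disjoint", {
  ds <- small_confounded()
  tpl <- extract_patch(Filter(function(im) im$has_patch, ds)[[1]]$pixels,
                       Filter(function(im) im$has_patch, ds)[[1]]$patch_mask)
  target <- Filter(function(im) im$label == "malignant", ds)[[1]]
  a <- insert_patch(target$pixels, tpl, target$lesion_mask, seed = 3L)
  b <- insert_patch(target$pixels, tpl, target$lesion_mask, seed = 3L)
  expect_identical(a$inserted_mask, b$inserted_mask)
  expect_identical(a$image, b$image)
  # changed-pixel set equals the inserted mask exactly
  changed <- (a$image[, , 1] != target$pixels[, , 1]) |
    (a$image[, , 2] != target$pixels[, , 2]) |
    (a$image[, , 3] != target$pixels[, , 3])
  expect_true(all(changed == a$inserted_mask |
                    (a$inserted_mask & !changed)))  # equal template pixels allowed
  expect_false(any(changed & !a$inserted_mask))
  expect_false(any(a$inserted_mask & target$lesion_mask))
  expect_lt(ssim(target$pixels, a$image), 1)
  # seeded batch: disjointness holds for every successful insertion
  for (s in 1:10) {
    r <- insert_patch(target$pixels, tpl, target$lesion_mask, seed = s)
    expect_false(any(r$inserted_mask & target$lesion_mask))
  }
})

test_that("insertion fails cleanly when no legal placement exists", {
  ds <- small_confounded()
  im <- Filter(function(im) im$has_patch, ds)[[1]]
  tpl <- extract_patch(im$pixels, im$patch_mask)
  full <- matrix(TRUE, 96, 96)
  expect_error(
    insert_patch(im$pixels, tpl, full, seed = 1L, image_id = "blocked_img"),
    "blocked_img"
  )
})

test_that("the footprint control inpaints exactly the inserted region", {
  ds <- small_confounded()
  im <- Filter(function(im) im$has_patch, ds)[[1]]
  tpl <- extract_patch(im$pixels, im$patch_mask)
  target <- Filter(function(im) im$label == "malignant", ds)[[2]]
  ins <- insert_patch(target$pixels, tpl, target$lesion_mask, seed = 5L)
  ctrl <- inpaint_footprint_control(target$pixels, ins$inserted_mask)
  keep <- !ins$inserted_mask
  for (ch in 1:3) {
    expect_identical(ctrl[, , ch][keep], target$pixels[, , ch][keep])
  }
  expect_identical(inpaint_footprint_control(target$pixels, matrix(FALSE, 96, 96)),
                   target$pixels)
})

test_that("patch libraries build from ground truth and round-trip to disk", {
  ds <- small_confounded()
  lib <- build_patch_library(Filter(function(im) im$has_patch, ds)[1:4])
  expect_length(lib, 4L)
  dir <- withr::local_tempdir()
  write_patch_library(lib, dir)
  back <- read_patch_library(dir)
  expect_length(back, 4L)
  expect_identical(back[[1]]$mask, lib[[1]]$mask)
  expect_identical(vapply(back, `[[`, "", "source_id"),
                   vapply(lib, `[[`, "", "source_id"))
  expect_lt(max(abs(back[[2]]$pixels - lib[[2]]$pixels)), 1 / 255)
})
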