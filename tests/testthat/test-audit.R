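# audits on the small fixture use ground-truth masks to keep them quick;
# the acceptance suite exercises the full segmentation path
fast_config <- function(seed = 1L) {
  audit_config(seg = seg_config(image_size = 96L),
               use_true_masks = TRUE, seed = seed)
}

test_that("a pixel-blind classifier shows no shortcut signal", {
  ds <- small_confounded()
  res <- run_removal_audit(constant_classifier(0.3), ds, fast_config())
  expect_equal(res$report$mad, 0)
  expect_equal(res$report$frac_decreased, 0)
  expect_true(is.na(res$report$mnd))
  expect_equal(res$report$flip_fraction_all, 0)

  lib <- build_patch_library(Filter(function(im) im$has_patch, ds)[1:3])
  res2 <- run_insertion_audit(constant_classifier(0.7), ds, lib, fast_config())
  expect_equal(res2$report$mad, 0)
  expect_equal(res2$report$flip_fraction, 0)
})

test_that("a no-op inpainting backend yields zero deviations", {
  ds <- small_confounded()
  clf <- memo("tiny_clf", {
    fit_reference(ds, train_config(image_size = 96L, seed = 1L))
  })
  cfg <- fast_config()
  cfg$backend <- "identity"
  res <- run_removal_audit(clf, ds, cfg)
  expect_equal(res$report$mad, 0)
  expect_equal(res$ssim$median, 1)
})

test_that("audits conserve samples between report and exclusion log", {
  ds <- small_confounded()
  clf <- memo("tiny_clf", {
    fit_reference(ds, train_config(image_size = 96L, seed = 1L))
  })
  cfg <- fast_config()
  rem <- run_removal_audit(clf, ds, cfg)
  expect_identical(nrow(rem$pairs) + nrow(rem$exclusions), rem$n_input)
  lib <- build_patch_library(Filter(function(im) im$has_patch, ds)[1:3])
  ins <- run_insertion_audit(clf, ds, lib, cfg)
  expect_identical(nrow(ins$pairs) + nrow(ins$exclusions), ins$n_input)
  # every audited pair is one of the eligible inputs, exactly once
  expect_false(anyDuplicated(ins$pairs$id) > 0)
})

test_that("audit results are deterministic given config and seed", {
  ds <- small_confounded()
  clf <- memo("tiny_clf", {
    fit_reference(ds, train_config(image_size = 96L, seed = 1L))
  })
  cfg <- fast_config(seed = 5L)
  lib <- build_patch_library(Filter(function(im) im$has_patch, ds)[1:3])
  a <- run_insertion_audit(clf, ds, lib, cfg)
  b <- run_insertion_audit(clf, ds, lib, cfg)
  expect_identical(a$pairs, b$pairs)
  expect_identical(unclass(a$report), unclass(b$report))
})

test_that("audits validate their input subsets", {
  ds <- Filter(function(im) im$label == "malignant", small_confounded())
  clf <- constant_classifier()
  expect_error(run_removal_audit(clf, ds, fast_config()), "benign")
  benign_only <- Filter(function(im) im$label == "benign", small_confounded())
  lib <- build_patch_library(Filter(function(im) im$has_patch, benign_only)[1])
  expect_error(run_insertion_audit(clf, benign_only, lib, fast_config()),
               "malignant")
  expect_error(run_insertion_audit(clf, small_confounded(), list(), fast_config()),
               "template")
})

test_that("de-biasing passes patch-free datasets through unchanged", {
  clean <- generate_dermo_dataset(dermo_params(
    image_size = 64L, n_benign = 4L, n_malignant = 3L,
    patch_fraction_benign = 0, seed = 6L
  ))
  deb <- debias_dataset(clean, audit_config(seg = seg_config(image_size = 64L)))
  expect_length(deb$altered_ids, 0L)
  expect_identical(lapply(deb$dataset, `[[`, "pixels"),
                   lapply(clean, `[[`, "pixels"))
})

test_that("de-biasing alters exactly the images with detected patches", {
  ds <- small_confounded()
  deb <- debias_dataset(ds, fast_config())
  truth <- vapply(ds, `[[`, NA, "has_patch")
  expect_setequal(deb$altered_ids, vapply(ds[truth], `[[`, "", "id"))
  expect_identical(length(deb$altered_ids), length(deb$detected_masks))
  # altered images no longer trigger the detector
  cfg <- seg_config(image_size = 96L)
  redetect <- vapply(deb$dataset[truth], function(im) {
    mean(segment_patches(im$pixels, cfg))
  }, 0)
  expect_true(mean(redetect <= 0.01) >= 0.95)
})
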