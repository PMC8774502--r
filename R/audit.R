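#' Audit configuration
#'
#' Bundles everything the audit experiments need: the decision threshold,
#' the segmentation and random-mask configurations, the inpainting backend,
#' and a master seed from which each stage derives its own deterministic
#' seed stream, so every experiment is independently reproducible.
#'
#' @param threshold decision threshold on P(malignant | x).
#' @param seg a [seg_config()].
#' @param mask_params a [random_mask_params()] for validity checks.
#' @param backend inpainting backend name.
#' @param use_true_masks if `TRUE`, use ground-truth patch masks where the
#'   dataset carries them (external-mask path); otherwise always segment.
#' @param n_templates maximum number of patch templates for insertion audits.
#' @param max_attempts placement attempts per insertion before excluding the
#'   image.
#' @param seed master seed.
#' @return an `audit_config` object.
#' @export
audit_config <- function(threshold = 0.4,
                         seg = seg_config(),
                         mask_params = random_mask_params(),
                         backend = "harmonic",
                         use_true_masks = FALSE,
                         n_templates = 50L,
                         max_attempts = 50L,
                         seed = 1L) {
  stopifnot(threshold > 0, threshold < 1, inherits(seg, "seg_config"),
            inherits(mask_params, "random_mask_params"))
  structure(list(threshold = threshold, seg = seg, mask_params = mask_params,
                 backend = backend, use_true_masks = isTRUE(use_true_masks),
                 n_templates = as.integer(n_templates),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "audit_config")
}

# Detected (and dilated) artefact mask for one image, honouring the
# external-mask path.
detect_patch_mask <- function(im, config) {
  mask <- if (config$use_true_masks && any(im$patch_mask)) {
    im$patch_mask
  } else {
    segment_patches(im$pixels, config$seg)
  }
  if (any(mask)) mask <- dilate_mask(mask, config$seg$dilation_size)
  mask
}

ssim_summary <- function(ssims) {
  list(median = median(ssims), mean = mean(ssims), sd = sd(ssims))
}

#' Removal audit: how much does the classifier rely on present patches?
#'
#' Restricted to benign images with patches (set A), this audit segments (or
#' loads) each patch mask, dilates and inpaints it, and compares predictions
#' on original vs. patch-free counterfactuals: MAD, %P down, MND, %flip,
#' specificity before/after, and the SSIM distribution of the alterations.
#' Images where no artefact mask is detected are excluded and logged.
#'
#' @param classifier fitted classifier.
#' @param images test images; only benign images with patches are audited.
#' @param config an [audit_config()].
#' @return an `audit_result` list with the `shortcut_report`, performance
#'   rows, SSIM summary, paired predictions and the exclusion log.
#' @export
run_removal_audit <- function(classifier, images, config = audit_config()) {
  subset_a <- Filter(function(im) im$label == "benign" && im$has_patch, images)
  if (length(subset_a) == 0L) {
    stop("removal audit needs benign images with patches", call. = FALSE)
  }
  exclusions <- data.frame(id = character(0), reason = character(0))
  kept <- list(); altered <- list(); ssims <- numeric(0)
  for (im in subset_a) {
    mask <- detect_patch_mask(im, config)
    if (!any(mask)) {
      exclusions <- rbind(exclusions,
                          data.frame(id = im$id, reason = "no artefact mask detected"))
      next
    }
    alt <- inpaint(im$pixels, mask, config$backend)
    kept[[length(kept) + 1L]] <- im
    altered[[length(altered) + 1L]] <- alt
    ssims <- c(ssims, ssim(im$pixels, alt))
  }
  if (length(kept) == 0L) stop("all removal-audit images were excluded", call. = FALSE)
  p_orig <- predict_proba(classifier, lapply(kept, `[[`, "pixels"),
                          ids = dataset_ids(kept))
  p_alt <- predict_proba(classifier, altered, ids = dataset_ids(kept))
  pairs <- paired_predictions(p_orig, p_alt,
                              setNames(dataset_labels(kept), dataset_ids(kept)),
                              alteration = "patch_removed")
  labs <- setNames(dataset_labels(kept), dataset_ids(kept))
  perf <- rbind(
    cbind(subset = "benign_with_patches",
          as.data.frame(sens_spec(p_orig, labs, config$threshold))),
    cbind(subset = "benign_with_inpainted_patches",
          as.data.frame(sens_spec(p_alt, labs, config$threshold)))
  )
  structure(list(kind = "removal", report = shortcut_report(pairs, config$threshold),
                 performance = perf, ssim = ssim_summary(ssims),
                 pairs = pairs, exclusions = exclusions,
                 n_input = length(subset_a)),
            class = "audit_result")
}

#' Insertion audit: does an inserted patch flip malignant predictions?
#'
#' Restricted to malignant images without patches (set B). One patch
#' template is composited into each image at a seeded boundary-ring location
#' disjoint from the lesion; images with no legal placement are excluded and
#' logged. Predictions on original vs. patched counterfactuals give the
#' deviation statistics and the sensitivity drop; the footprint control
#' inpaints the same region *without* the patch to show the shift comes from
#' the patch, not from what it covers.
#'
#' @param classifier fitted classifier.
#' @param images test images; only malignant images without patches audited.
#' @param library non-empty list of `patch_template` objects.
#' @param config an [audit_config()].
#' @param footprint_control also compute the footprint-inpainting control.
#' @return an `audit_result` list; when `footprint_control` is `TRUE` it
#'   contains a second `paired_predictions` table for the control.
#' @export
run_insertion_audit <- function(classifier, images, library,
                                config = audit_config(),
                                footprint_control = TRUE) {
  subset_b <- Filter(function(im) im$label == "malignant" && !im$has_patch, images)
  if (length(subset_b) == 0L) {
    stop("insertion audit needs malignant images without patches", call. = FALSE)
  }
  if (length(library) == 0L) stop("empty patch template library", call. = FALSE)
  exclusions <- data.frame(id = character(0), reason = character(0))
  kept <- list(); altered <- list(); control <- list(); ssims <- numeric(0)
  with_seed(derive_seed(config$seed, "insertion"), {
    for (im in subset_b) {
      tpl <- library[[sample(length(library), 1L)]]
      ins <- tryCatch(
        insert_patch(im$pixels, tpl, im$lesion_mask,
                     max_attempts = config$max_attempts, image_id = im$id),
        error = function(e) NULL
      )
      if (is.null(ins)) {
        exclusions <- rbind(exclusions,
                            data.frame(id = im$id,
                                       reason = "no lesion-disjoint placement"))
        next
      }
      kept[[length(kept) + 1L]] <- im
      altered[[length(altered) + 1L]] <- ins$image
      if (footprint_control) {
        control[[length(control) + 1L]] <-
          inpaint_footprint_control(im$pixels, ins$inserted_mask, config$backend)
      }
      ssims <- c(ssims, ssim(im$pixels, ins$image))
    }
  })
  if (length(kept) == 0L) stop("all insertion placements failed", call. = FALSE)
  ids <- dataset_ids(kept)
  labs <- setNames(dataset_labels(kept), ids)
  p_orig <- predict_proba(classifier, lapply(kept, `[[`, "pixels"), ids = ids)
  p_alt <- predict_proba(classifier, altered, ids = ids)
  pairs <- paired_predictions(p_orig, p_alt, labs, alteration = "patch_inserted")
  perf <- rbind(
    cbind(subset = "malignant_without_patches",
          as.data.frame(sens_spec(p_orig, labs, config$threshold))),
    cbind(subset = "malignant_with_inserted_patches",
          as.data.frame(sens_spec(p_alt, labs, config$threshold)))
  )
  control_pairs <- NULL
  if (footprint_control) {
    p_ctrl <- predict_proba(classifier, control, ids = ids)
    control_pairs <- paired_predictions(p_orig, p_ctrl, labs,
                                        alteration = "footprint_inpaint")
  }
  structure(list(kind = "insertion",
                 report = shortcut_report(pairs, config$threshold),
                 performance = perf, ssim = ssim_summary(ssims),
                 pairs = pairs, control_pairs = control_pairs,
                 exclusions = exclusions, n_input = length(subset_b)),
            class = "audit_result")
}

#' @export
print.audit_result <- function(x, ...) {
  cat(sprintf("<audit_result> %s audit: %d/%d images audited (%d excluded)\n",
              x$kind, nrow(x$pairs), x$n_input, nrow(x$exclusions)))
  print(x$report)
  invisible(x)
}

#' De-bias a training set by inpainting detected artefacts
#'
#' Every image with a detected (dilated) patch mask is replaced by its
#' inpainted version; patch-free images pass through unchanged. The returned
#' manifest records which images were altered, and the detected masks are
#' kept so callers can, e.g., extract patch templates from the originals.
#'
#' @param dataset list of `labeled_image` objects (training set).
#' @param config an [audit_config()].
#' @return list with `dataset` (de-biased), `altered_ids`, and
#'   `detected_masks` (named list, altered ids only).
#' @export
debias_dataset <- function(dataset, config = audit_config()) {
  out <- dataset
  altered_ids <- character(0)
  detected <- list()
  for (i in seq_along(dataset)) {
    im <- dataset[[i]]
    mask <- detect_patch_mask(im, config)
    if (!any(mask)) next
    px <- inpaint(im$pixels, mask, config$backend)
    out[[i]] <- labeled_image(im$id, px, im$label,
                              im$lesion_mask, NULL, im$patch_failed)
    altered_ids <- c(altered_ids, im$id)
    detected[[im$id]] <- mask
  }
  list(dataset = structure(out, class = "dermo_dataset"),
       altered_ids = altered_ids, detected_masks = detected)
}

subgroup_of <- function(images) {
  setNames(vapply(images, function(im) {
    if (im$label == "malignant") "malignant"
    else if (im$has_patch) "benign_with_patch"
    else "benign_no_patch"
  }, ""), dataset_ids(images))
}

#' Full de-bias-and-retrain experiment
#'
#' Runs the complete audit protocol: train a vanilla classifier on the raw
#' training set; de-bias the training set by inpainting detected patches and
#' retrain; then, for both classifiers, run the validity check, the removal
#' audit and the insertion audit on the test set, assemble the performance
#' table over test subsets, and compute the per-subgroup Pearson fidelity
#' between the two classifiers' test predictions.
#'
#' @param train,test lists of `labeled_image` objects.
#' @param config an [audit_config()].
#' @param tconfig a [train_config()] for both classifiers.
#' @return an `audit_run` list with per-classifier audits, the de-bias
#'   manifest, the performance and fidelity tables, and all exclusion logs.
#' @export
run_debias_experiment <- function(train, test, config = audit_config(),
                                  tconfig = train_config()) {
  vanilla <- fit_reference(train, tconfig)
  deb <- debias_dataset(train, config)
  retrained <- fit_reference(deb$dataset, tconfig)

  # template library from the originals of the train images whose patches
  # the de-bias step detected (the same segmentation approach, reused)
  by_id <- setNames(seq_along(train), dataset_ids(train))
  tpl_ids <- utils::head(deb$altered_ids, config$n_templates)
  library <- lapply(tpl_ids, function(id) {
    im <- train[[by_id[[id]]]]
    extract_patch(im$pixels, deb$detected_masks[[id]], im$id)
  })

  patch_free_test <- Filter(function(im) !im$has_patch, test)
  run_for <- function(classifier) {
    list(
      validity = validity_check(classifier, patch_free_test,
                                config$mask_params, config$backend,
                                seed = derive_seed(config$seed, "validity")),
      removal = run_removal_audit(classifier, test, config),
      insertion = run_insertion_audit(classifier, test, library, config)
    )
  }
  v <- run_for(vanilla)
  r <- run_for(retrained)

  all_ids <- dataset_ids(test)
  labs <- setNames(dataset_labels(test), all_ids)
  pv <- predict_proba(vanilla, lapply(test, `[[`, "pixels"), ids = all_ids)
  pr <- predict_proba(retrained, lapply(test, `[[`, "pixels"), ids = all_ids)
  pf_ids <- dataset_ids(patch_free_test)
  perf <- rbind(
    data.frame(subset = "full_test", classifier = "vanilla",
               as.data.frame(sens_spec(pv, labs, config$threshold))),
    data.frame(subset = "full_test", classifier = "retrained",
               as.data.frame(sens_spec(pr, labs, config$threshold))),
    data.frame(subset = "test_excl_patches", classifier = "vanilla",
               as.data.frame(sens_spec(pv[pv$id %in% pf_ids, ], labs, config$threshold))),
    data.frame(subset = "test_excl_patches", classifier = "retrained",
               as.data.frame(sens_spec(pr[pr$id %in% pf_ids, ], labs, config$threshold)))
  )
  for (who in c("vanilla", "retrained")) {
    res <- if (who == "vanilla") v else r
    for (stage in c("removal", "insertion")) {
      p <- res[[stage]]$performance
      perf <- rbind(perf, data.frame(subset = p$subset, classifier = who,
                                     sensitivity = p$sensitivity,
                                     specificity = p$specificity))
    }
  }

  fidelity <- pearson_fidelity(pv, pr, subgroup_of(test))

  structure(list(
    config = config, tconfig = tconfig,
    vanilla = c(list(classifier = vanilla), v),
    retrained = c(list(classifier = retrained), r),
    debias = list(altered_ids = deb$altered_ids,
                  n_altered = length(deb$altered_ids),
                  n_train = length(train)),
    performance = perf,
    fidelity = fidelity
  ), class = "audit_run")
}

#' @export
print.audit_run <- function(x, ...) {
  cat("<audit_run>\n")
  cat(sprintf("  de-biased %d/%d training images\n",
              x$debias$n_altered, x$debias$n_train))
  for (who in c("vanilla", "retrained")) {
    cat(sprintf("  -- %s --\n", who))
    print(x[[who]]$removal$report)
    print(x[[who]]$insertion$report)
  }
  cat("  fidelity (vanilla vs retrained):\n")
  print(x$fidelity, row.names = FALSE)
  invisible(x)
}

#' Shortcut-quantification table of an experiment
#'
#' One row per data subset x classifier with MAD, %P down, MND and %flip,
#' percentages formatted x100.
#'
#' @param run an [run_debias_experiment()] result.
#' @return a data.frame.
#' @export
audit_table <- function(run) {
  rows <- list()
  for (who in c("vanilla", "retrained")) {
    rows[[length(rows) + 1L]] <- cbind(
      classifier = who,
      format_shortcut_report(run[[who]]$removal$report, "benign_patches_removed"))
    rows[[length(rows) + 1L]] <- cbind(
      classifier = who,
      format_shortcut_report(run[[who]]$insertion$report, "malignant_patches_inserted"))
  }
  do.call(rbind, rows)
}

#' Write the report files of an experiment
#'
#' Emits JSON shortcut reports, the performance and fidelity tables, the
#' quantification table and the exclusion logs under `dir`.
#'
#' @param run an [run_debias_experiment()] result.
#' @param dir output directory.
#' @export
write_audit_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (who in c("vanilla", "retrained")) {
    write_shortcut_report(run[[who]]$removal$report,
                          file.path(dir, paste0(who, "_removal.json")))
    write_shortcut_report(run[[who]]$insertion$report,
                          file.path(dir, paste0(who, "_insertion.json")))
    excl <- rbind(run[[who]]$removal$exclusions, run[[who]]$insertion$exclusions)
    write.csv(excl, file.path(dir, paste0(who, "_exclusions.csv")),
              row.names = FALSE)
  }
  write.csv(run$performance, file.path(dir, "performance.csv"), row.names = FALSE)
  write.csv(run$fidelity, file.path(dir, "fidelity.csv"), row.names = FALSE)
  write.csv(audit_table(run), file.path(dir, "quantification.csv"),
            row.names = FALSE)
  invisible(dir)
}
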