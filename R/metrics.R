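#' Prediction records for a batch of images
#'
#' @param ids character image ids.
#' @param p_malignant predicted probabilities of the malignant class.
#' @return a data.frame with columns `id`, `p_malignant`, `p_benign`
#'   (the two probabilities sum to 1).
#' @export
prediction_records <- function(ids, p_malignant) {
  stopifnot(length(ids) == length(p_malignant),
            all(p_malignant >= -1e-9 & p_malignant <= 1 + 1e-9))
  p <- pmin(1, pmax(0, p_malignant))
  data.frame(id = as.character(ids), p_malignant = p, p_benign = 1 - p,
             stringsAsFactors = FALSE)
}

#' Pair original and altered predictions
#'
#' Matches two prediction sets one-to-one by id and attaches the true class
#' label of each image, so the deviation statistics can be computed on the
#' probability of the *true* class: P(benign | .) for benign images,
#' P(malignant | .) for malignant ones.
#'
#' @param original,altered prediction data.frames (see
#'   [prediction_records()]), with identical id sets.
#' @param true_labels named character vector or single label giving the true
#'   class of each id.
#' @param alteration what produced the altered set: patch removal, patch
#'   insertion, a random inpaint, or the patch-footprint inpaint control.
#' @return a `paired_predictions` data.frame with per-id original and altered
#'   probabilities and the signed true-class deviation `d`.
#' @export
paired_predictions <- function(original, altered, true_labels,
                               alteration = c("patch_removed", "patch_inserted",
                                              "random_inpaint", "footprint_inpaint")) {
  alteration <- match.arg(alteration)
  if (!setequal(original$id, altered$id) ||
      anyDuplicated(original$id) || anyDuplicated(altered$id)) {
    stop("original and altered ids must match one-to-one", call. = FALSE)
  }
  altered <- altered[match(original$id, altered$id), ]
  if (length(true_labels) == 1L && is.null(names(true_labels))) {
    true_labels <- setNames(rep(true_labels, nrow(original)), original$id)
  }
  lab <- unname(true_labels[original$id])
  if (anyNA(lab) || !all(lab %in% c("benign", "malignant"))) {
    stop("every id needs a true label in {benign, malignant}", call. = FALSE)
  }
  p_true <- function(p_mal, label) ifelse(label == "malignant", p_mal, 1 - p_mal)
  out <- data.frame(
    id = original$id,
    true_label = lab,
    orig_p_malignant = original$p_malignant,
    alt_p_malignant = altered$p_malignant,
    orig_p_true = p_true(original$p_malignant, lab),
    alt_p_true = p_true(altered$p_malignant, lab),
    stringsAsFactors = FALSE
  )
  out$d <- out$alt_p_true - out$orig_p_true
  attr(out, "alteration") <- alteration
  class(out) <- c("paired_predictions", "data.frame")
  out
}

assert_pairs <- function(pairs) {
  if (!inherits(pairs, "paired_predictions") || nrow(pairs) == 0L) {
    stop("non-empty paired_predictions required", call. = FALSE)
  }
  invisible(pairs)
}

#' Mean absolute deviation of true-class probabilities
#'
#' The average over paired images of |P_trueclass(altered) -
#' P_trueclass(original)|: how much, on average, removing or inserting the
#' artefact moves the prediction.
#'
#' @param pairs a [paired_predictions()] table.
#' @return scalar in [0, 1].
#' @export
mad_deviation <- function(pairs) {
  assert_pairs(pairs)
  mean(abs(pairs$d))
}

#' Direction-aware deviation summary
#'
#' The signed deviation is `d = P_trueclass(altered) - P_trueclass(original)`.
#' Reports the fraction of pairs with `d < 0` (the probability of the true
#' class *decreased*) and the mean magnitude of `d` over that subset (the
#' mean negative deviation, MND). When no pair decreased, MND is undefined
#' and reported as `NA`, never as 0.
#'
#' @param pairs a [paired_predictions()] table.
#' @return list with `frac_decreased`, `mnd`, `n_decreased`.
#' @export
deviation_summary <- function(pairs) {
  assert_pairs(pairs)
  dec <- pairs$d < 0
  list(
    frac_decreased = mean(dec),
    mnd = if (any(dec)) mean(abs(pairs$d[dec])) else NA_real_,
    n_decreased = sum(dec)
  )
}

# Decision rule: malignant iff p_malignant >= threshold. The boundary tie is
# assigned to malignant, favouring sensitivity.
classify_malignant <- function(p_malignant, threshold) p_malignant >= threshold

#' Decision-boundary flip fraction
#'
#' Fraction of images whose classification crosses the decision boundary
#' after the alteration. By default the denominator is restricted to images
#' that were *initially correctly* classified, so the statistic reads as
#' "fraction of initially-correct images that the artefact flips to an
#' incorrect class"; set `restrict_to_correct = FALSE` for the variant over
#' all pairs (any boundary crossing, either direction).
#'
#' @param pairs a [paired_predictions()] table.
#' @param threshold decision threshold on P(malignant | x).
#' @param restrict_to_correct see above.
#' @return scalar fraction in [0, 1].
#' @export
flip_fraction <- function(pairs, threshold = 0.4, restrict_to_correct = TRUE) {
  assert_pairs(pairs)
  stopifnot(threshold > 0, threshold < 1)
  orig_mal <- classify_malignant(pairs$orig_p_malignant, threshold)
  alt_mal <- classify_malignant(pairs$alt_p_malignant, threshold)
  if (restrict_to_correct) {
    correct <- orig_mal == (pairs$true_label == "malignant")
    if (!any(correct)) {
      stop("no originally-correct pairs: restricted flip fraction undefined",
           call. = FALSE)
    }
    flipped <- correct & (alt_mal != orig_mal)
    sum(flipped) / sum(correct)
  } else {
    mean(alt_mal != orig_mal)
  }
}

#' Sensitivity and specificity at a probability threshold
#'
#' Sensitivity is the true positive rate with malignant as the positive
#' class, specificity the true negative rate; an image is called malignant
#' when `p_malignant >= threshold`. A metric whose class is absent from
#' `labels` is not applicable and returned as `NA`.
#'
#' @param predictions a prediction data.frame (see [prediction_records()]).
#' @param labels character vector of true labels, aligned with `predictions`
#'   (or named by id).
#' @param threshold decision threshold on P(malignant | x).
#' @return list with `sensitivity` and `specificity` (either may be `NA`).
#' @export
sens_spec <- function(predictions, labels, threshold = 0.4) {
  if (!is.null(names(labels))) labels <- unname(labels[predictions$id])
  stopifnot(length(labels) == nrow(predictions),
            all(labels %in% c("benign", "malignant")))
  called_mal <- classify_malignant(predictions$p_malignant, threshold)
  pos <- labels == "malignant"
  list(
    sensitivity = if (any(pos)) sum(called_mal & pos) / sum(pos) else NA_real_,
    specificity = if (any(!pos)) sum(!called_mal & !pos) / sum(!pos) else NA_real_
  )
}

#' Per-subgroup Pearson fidelity between two classifiers
#'
#' Pearson correlation of P(malignant | x) between two classifiers over the
#' same images, overall and within subgroups (typically: malignant, benign
#' without patch, benign with patch). A subgroup with fewer than 3 members
#' or zero variance in either prediction vector has undefined correlation,
#' reported as `NA` and flagged.
#'
#' @param preds_a,preds_b prediction data.frames over the same ids.
#' @param subgroups named character vector (by id) or vector aligned with
#'   `preds_a` giving each image's subgroup.
#' @return data.frame with columns `subgroup`, `n`, `r`, `defined`.
#' @export
pearson_fidelity <- function(preds_a, preds_b, subgroups = NULL) {
  if (!setequal(preds_a$id, preds_b$id)) {
    stop("prediction sets must cover the same ids", call. = FALSE)
  }
  preds_b <- preds_b[match(preds_a$id, preds_b$id), ]
  if (is.null(subgroups)) {
    subgroups <- rep("all", nrow(preds_a))
  } else if (!is.null(names(subgroups))) {
    subgroups <- unname(subgroups[preds_a$id])
  }
  groups <- c(list(overall = rep(TRUE, nrow(preds_a))),
              lapply(split(seq_len(nrow(preds_a)), subgroups), function(i) {
                seq_len(nrow(preds_a)) %in% i
              }))
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    x <- preds_a$p_malignant[sel]
    y <- preds_b$p_malignant[sel]
    ok <- sum(sel) >= 3L && sd(x) > 0 && sd(y) > 0
    data.frame(subgroup = g, n = sum(sel),
               r = if (ok) cor(x, y) else NA_real_,
               defined = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full shortcut quantification report for a paired prediction set
#'
#' Bundles the deviation statistics: MAD, fraction decreased (%P down), MND,
#' and both flip-fraction variants, at the given decision threshold.
#' Fractions are stored on the [0, 1] scale; use [format_shortcut_report()]
#' for the percent-formatted view.
#'
#' @param pairs a [paired_predictions()] table.
#' @param threshold decision threshold on P(malignant | x).
#' @return a `shortcut_report` list.
#' @export
shortcut_report <- function(pairs, threshold = 0.4) {
  assert_pairs(pairs)
  dev <- deviation_summary(pairs)
  orig_mal <- classify_malignant(pairs$orig_p_malignant, threshold)
  n_correct <- sum(orig_mal == (pairs$true_label == "malignant"))
  structure(list(
    alteration = attr(pairs, "alteration"),
    n = nrow(pairs),
    threshold = threshold,
    mad = mad_deviation(pairs),
    frac_decreased = dev$frac_decreased,
    mnd = dev$mnd,
    n_decreased = dev$n_decreased,
    n_initially_correct = n_correct,
    flip_fraction = if (n_correct > 0) flip_fraction(pairs, threshold) else NA_real_,
    flip_fraction_all = flip_fraction(pairs, threshold, restrict_to_correct = FALSE)
  ), class = "shortcut_report")
}

#' @export
print.shortcut_report <- function(x, ...) {
  cat(sprintf("<shortcut_report> %s, n = %d, threshold = %.2f\n",
              x$alteration, x$n, x$threshold))
  cat(sprintf("  MAD %.3f | %%P down %.1f%% | MND %s | %%flip %s (all pairs: %.1f%%)\n",
              x$mad, 100 * x$frac_decreased,
              if (is.na(x$mnd)) "n.a." else sprintf("%.3f", x$mnd),
              if (is.na(x$flip_fraction)) "n.a."
              else sprintf("%.1f%%", 100 * x$flip_fraction),
              100 * x$flip_fraction_all))
  invisible(x)
}

#' Percent-formatted one-row view of a shortcut report
#'
#' @param report a [shortcut_report()].
#' @param label row label (e.g. the data subset and classifier).
#' @return a one-row data.frame with MAD, %P down, MND and %flip columns.
#' @export
format_shortcut_report <- function(report, label = report$alteration) {
  data.frame(
    subset = label,
    mad = report$mad,
    pct_p_down = 100 * report$frac_decreased,
    mnd = report$mnd,
    pct_flip = 100 * report$flip_fraction,
    n = report$n,
    stringsAsFactors = FALSE
  )
}

#' Serialise a shortcut report to JSON
#'
#' @param report a [shortcut_report()].
#' @param path output file.
#' @export
write_shortcut_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a shortcut report written by [write_shortcut_report()]
#'
#' @param path JSON file.
#' @return a `shortcut_report`.
#' @export
read_shortcut_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mad", "frac_decreased", "mnd", "flip_fraction", "flip_fraction_all")) {
    if (is.null(x[[f]])) x[[f]] <- NA_real_
  }
  structure(x, class = "shortcut_report")
}
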