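mk_pairs <- function(p_orig, p_alt, labels) {
  ids <- sprintf("i%d", seq_along(p_orig))
  paired_predictions(prediction_records(ids, p_orig),
                     prediction_records(ids, p_alt),
                     setNames(labels, ids))
}

test_that("mad matches hand-computed deviations of true-class probabilities", {
  # benign pairs: true-class prob is p_benign = 1 - p_malignant
  pairs <- mk_pairs(1 - c(0.8, 0.2, 0.6), 1 - c(0.5, 0.4, 0.5),
                    rep("benign", 3))
  expect_equal(mad_deviation(pairs), (0.3 + 0.2 + 0.1) / 3)
  same <- mk_pairs(c(0.3, 0.7), c(0.3, 0.7), c("benign", "malignant"))
  expect_equal(mad_deviation(same), 0)
  one <- mk_pairs(1.0, 0.0, "malignant")
  expect_equal(mad_deviation(one), 1.0)
})

test_that("deviation summary separates direction from magnitude", {
  pairs <- mk_pairs(c(0.8, 0.2), c(0.5, 0.4), rep("malignant", 2))
  s <- deviation_summary(pairs)     # d = (-0.3, +0.2)
  expect_equal(s$frac_decreased, 0.5)
  expect_equal(s$mnd, 0.3)
  up <- mk_pairs(c(0.2, 0.3), c(0.4, 0.3), rep("malignant", 2))
  s2 <- deviation_summary(up)
  expect_equal(s2$frac_decreased, 0)
  expect_true(is.na(s2$mnd))        # undefined, not zero
  same <- mk_pairs(c(0.5, 0.5), c(0.5, 0.5), rep("benign", 2))
  expect_equal(deviation_summary(same)$frac_decreased, 0)
})

test_that("flip fraction counts initially-correct boundary crossings", {
  pairs <- mk_pairs(c(0.9, 0.5, 0.3), c(0.3, 0.45, 0.2), rep("malignant", 3))
  # threshold 0.4: originally correct = {0.9, 0.5}; only 0.9 -> 0.3 flips
  expect_equal(flip_fraction(pairs, 0.4), 0.5)
  expect_equal(flip_fraction(pairs, 0.4, restrict_to_correct = FALSE), 1 / 3)
  none <- mk_pairs(c(0.9, 0.8), c(0.85, 0.75), rep("malignant", 2))
  expect_equal(flip_fraction(none, 0.4), 0)
  allwrong <- mk_pairs(c(0.1, 0.2), c(0.5, 0.6), rep("malignant", 2))
  expect_error(flip_fraction(allwrong, 0.4), "originally-correct")
})

test_that("deviation statistics agree with brute-force loops on random sets", {
  for (seed in 1:40) {
    pairs <- random_pairs(n = sample(2:40, 1), seed = seed)
    expect_equal(mad_deviation(pairs), mad_oracle(pairs), tolerance = 1e-12)
    s <- deviation_summary(pairs)
    o <- deviation_oracle(pairs)
    expect_equal(s$frac_decreased, o$frac_decreased, tolerance = 1e-12)
    expect_equal(s$mnd, o$mnd, tolerance = 1e-12)
    thr <- runif(1, 0.2, 0.8)
    orig_ok <- (pairs$orig_p_malignant >= thr) == (pairs$true_label == "malignant")
    if (any(orig_ok)) {
      expect_equal(flip_fraction(pairs, thr), flip_oracle(pairs, thr),
                   tolerance = 1e-12)
    }
    expect_equal(flip_fraction(pairs, thr, restrict_to_correct = FALSE),
                 flip_oracle(pairs, thr, restrict = FALSE), tolerance = 1e-12)
  }
})

test_that("statistics are invariant under permutation of pair order", {
  pairs <- random_pairs(30, seed = 99)
  perm <- pairs[sample(nrow(pairs)), ]
  class(perm) <- class(pairs)
  attr(perm, "alteration") <- attr(pairs, "alteration")
  expect_equal(mad_deviation(perm), mad_deviation(pairs))
  expect_equal(deviation_summary(perm), deviation_summary(pairs))
  expect_equal(flip_fraction(perm, 0.4), flip_fraction(pairs, 0.4))
})

test_that("sens/spec follow the threshold rule and the n.a. convention", {
  p <- prediction_records(c("a", "b"), c(0.5, 0.3))
  r <- sens_spec(p, c("malignant", "malignant"), 0.4)
  expect_equal(r$sensitivity, 0.5)
  expect_true(is.na(r$specificity))            # no benign samples
  rb <- sens_spec(p, c("benign", "benign"), 0.4)
  expect_true(is.na(rb$sensitivity))
  p2 <- prediction_records(c("a", "b", "c", "d"), c(0.9, 0.8, 0.1, 0.2))
  r2 <- sens_spec(p2, c("malignant", "malignant", "benign", "benign"), 0.4)
  expect_equal(r2$sensitivity, 1.0)
  expect_equal(r2$specificity, 1.0)
  # the boundary tie is called malignant
  tie <- sens_spec(prediction_records("a", 0.4), "malignant", 0.4)
  expect_equal(tie$sensitivity, 1.0)
  # random sets against the brute-force loop
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:30, 1)
    pm <- runif(n); labs <- sample(c("benign", "malignant"), n, replace = TRUE)
    got <- sens_spec(prediction_records(sprintf("x%d", 1:n), pm), labs, 0.4)
    want <- sens_spec_oracle(pm, labs, 0.4)
    expect_equal(got, want)
  }
})

test_that("pearson fidelity handles subgroups and degenerate cases", {
  ids <- sprintf("i%d", 1:6)
  a <- prediction_records(ids, c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  same <- pearson_fidelity(a, a)
  expect_equal(same$r[same$subgroup == "overall"], 1.0)
  b <- prediction_records(ids, 0.7 - c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  expect_equal(pearson_fidelity(a, b)$r[1], -1.0)
  lin <- prediction_records(ids, c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6) * 1.5)
  expect_equal(pearson_fidelity(a, lin)$r[1], 1.0)
  flat <- prediction_records(ids, rep(0.5, 6))
  res <- pearson_fidelity(a, flat)
  expect_true(is.na(res$r[1]))
  expect_false(res$defined[1])
  groups <- setNames(rep(c("g1", "g2"), each = 3), ids)
  by_group <- pearson_fidelity(a, b, groups)
  expect_setequal(by_group$subgroup, c("overall", "g1", "g2"))
  expect_equal(by_group$n[by_group$subgroup == "g1"], 3)
  # oracle agreement on random vectors
  set.seed(4)
  x <- runif(20); y <- runif(20)
  got <- pearson_fidelity(prediction_records(sprintf("r%d", 1:20), x),
                          prediction_records(sprintf("r%d", 1:20), y))
  expect_equal(got$r[1], pearson_oracle(x, y), tolerance = 1e-12)
})

test_that("paired prediction construction validates its inputs", {
  a <- prediction_records(c("x", "y"), c(0.2, 0.8))
  b <- prediction_records(c("x", "z"), c(0.2, 0.8))
  expect_error(paired_predictions(a, b, c(x = "benign", y = "benign")),
               "one-to-one")
  expect_error(prediction_records("x", 1.2))
  expect_error(mad_deviation(data.frame()), "paired_predictions")
})

test_that("shortcut reports round-trip losslessly through JSON", {
  pairs <- random_pairs(25, seed = 7)
  rep1 <- shortcut_report(pairs, threshold = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_shortcut_report(rep1, path)
  rep2 <- read_shortcut_report(path)
  for (f in c("mad", "frac_decreased", "mnd", "flip_fraction",
              "flip_fraction_all", "n", "n_decreased", "threshold")) {
    expect_equal(rep2[[f]], rep1[[f]], tolerance = 1e-12, label = f)
  }
  # a report with undefined MND survives the round trip as NA
  up <- mk_pairs(c(0.2, 0.3), c(0.4, 0.5), rep("malignant", 2))
  r3 <- shortcut_report(up, 0.4)
  write_shortcut_report(r3, path)
  expect_true(is.na(read_shortcut_report(path)$mnd))
})
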