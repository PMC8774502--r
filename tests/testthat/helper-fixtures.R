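# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

flat_image <- function(col, h = 32, w = h) {
  array(rep(col, each = h * w), dim = c(h, w, 3))
}

noisy_image <- function(h = 32, w = h, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# small confounded dataset with ground-truth masks, shared across files
small_confounded <- function() {
  memo("small_confounded", {
    generate_dermo_dataset(dermo_params(
      image_size = 96L, n_benign = 16L, n_malignant = 12L,
      patch_fraction_benign = 0.6, seed = 11L
    ))
  })
}

# a classifier that ignores pixels entirely
constant_classifier <- function(p_malignant = 0.3) {
  structure(list(p = p_malignant), class = "constant_classifier")
}
predict_proba.constant_classifier <- function(classifier, images, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("img_%d", seq_along(images))
  prediction_records(ids, rep(classifier$p, length(images)))
}
registerS3method("predict_proba", "constant_classifier",
                 predict_proba.constant_classifier,
                 envir = asNamespace("shortcutaudit"))

# --- independent oracles -----------------------------------------------------

# brute-force binary dilation: OR of the kernel stamped on every true cell
dilate_oracle <- function(mask, kernel) {
  h <- nrow(mask); w <- ncol(mask)
  kh <- nrow(kernel); kw <- ncol(kernel)
  oy <- (kh - 1) / 2; ox <- (kw - 1) / 2
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      rr <- r + i - 1 - oy; cc <- c + j - 1 - ox
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) out[rr, cc] <- TRUE
    }
  }
  out
}

# windowed SSIM by explicit loops over window positions (interior only)
ssim_oracle_channel <- function(x, y, size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  c1 <- 0.01^2; c2 <- 0.03^2
  h <- nrow(x); wd <- ncol(x)
  vals <- c()
  for (r in (half + 1):(h - half)) {
    for (c in (half + 1):(wd - half)) {
      wx <- x[(r - half):(r + half), (c - half):(c + half)]
      wy <- y[(r - half):(r + half), (c - half):(c + half)]
      mux <- sum(w * wx); muy <- sum(w * wy)
      sxx <- sum(w * wx * wx) - mux^2
      syy <- sum(w * wy * wy) - muy^2
      sxy <- sum(w * wx * wy) - mux * muy
      vals <- c(vals, ((2 * mux * muy + c1) * (2 * sxy + c2)) /
                  ((mux^2 + muy^2 + c1) * (sxx + syy + c2)))
    }
  }
  mean(vals)
}

ssim_oracle <- function(a, b) {
  mean(vapply(seq_len(dim(a)[3]), function(ch) {
    ssim_oracle_channel(a[, , ch], b[, , ch])
  }, 0))
}

# brute-force per-pair metric loops
mad_oracle <- function(pairs) {
  tot <- 0
  for (i in seq_len(nrow(pairs))) {
    tot <- tot + abs(pairs$alt_p_true[i] - pairs$orig_p_true[i])
  }
  tot / nrow(pairs)
}

deviation_oracle <- function(pairs) {
  n_dec <- 0; acc <- 0
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$alt_p_true[i] - pairs$orig_p_true[i]
    if (d < 0) { n_dec <- n_dec + 1; acc <- acc + abs(d) }
  }
  list(frac_decreased = n_dec / nrow(pairs),
       mnd = if (n_dec > 0) acc / n_dec else NA_real_)
}

flip_oracle <- function(pairs, threshold, restrict = TRUE) {
  n_den <- 0; n_flip <- 0
  for (i in seq_len(nrow(pairs))) {
    om <- pairs$orig_p_malignant[i] >= threshold
    am <- pairs$alt_p_malignant[i] >= threshold
    if (restrict) {
      if (om == (pairs$true_label[i] == "malignant")) {
        n_den <- n_den + 1
        if (am != om) n_flip <- n_flip + 1
      }
    } else {
      n_den <- n_den + 1
      if (am != om) n_flip <- n_flip + 1
    }
  }
  n_flip / n_den
}

sens_spec_oracle <- function(p_malignant, labels, threshold) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(p_malignant)) {
    called <- p_malignant[i] >= threshold
    if (labels[i] == "malignant") {
      if (called) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (called) fp <- fp + 1 else tn <- tn + 1
    }
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

random_pairs <- function(n, seed) {
  set.seed(seed)
  paired_predictions(
    prediction_records(sprintf("p%d", 1:n), runif(n)),
    prediction_records(sprintf("p%d", 1:n), runif(n)),
    setNames(sample(c("benign", "malignant"), n, replace = TRUE),
             sprintf("p%d", 1:n)),
    alteration = "patch_removed"
  )
}
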