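# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain per-element loops only.

# Per-pixel 3x3 convolution with reflect/replicate padding.
brute_conv3 <- function(img, kernel, border_mode = "reflect") {
  nr <- nrow(img); nc <- ncol(img)
  idx <- function(i, n) {
    if (i < 1) if (border_mode == "reflect" && n > 1) 2 - i else 1
    else if (i > n) if (border_mode == "reflect" && n > 1) 2 * n - i else n
    else i
  }
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + kernel[dy + 2, dx + 2] * img[idx(y + dy, nr), idx(x + dx, nc)]
    out[y, x] <- acc
  }
  out
}

# Weighted kappa straight from the definition, scalar double loops.
brute_weighted_kappa <- function(counts, W) {
  n <- sum(counts); K <- nrow(counts)
  po <- 0; pe <- 0
  ri <- rowSums(counts) / n; cj <- colSums(counts) / n
  for (i in seq_len(K)) for (j in seq_len(K)) {
    po <- po + W[i, j] * counts[i, j] / n
    pe <- pe + W[i, j] * ri[i] * cj[j]
  }
  (po - pe) / (1 - pe)
}

brute_binary_metrics <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b > 0) a / b else NA_real_
  list(accuracy = div(tp + tn, tp + fp + fn + tn),
       sensitivity = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       precision = div(tp, tp + fp),
       ppv = div(tp, tp + fp),
       npv = div(tn, tn + fn),
       f1 = div(2 * tp, 2 * tp + fp + fn))
}

# Re-derive every patient's stage from a landmark table using only scalar
# arithmetic and the published thresholds (no package staging code).
brute_stage_cohort <- function(landmarks) {
  out <- list()
  for (pid in unique(landmarks$patient_id)) {
    rows <- landmarks[landmarks$patient_id == pid, ]
    pmax_pct <- -Inf
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      dc <- sqrt((r$cej_x - r$crest_x)^2 + (r$cej_y - r$crest_y)^2) * r$mm_per_px
      da <- sqrt((r$cej_x - r$apex_x)^2 + (r$cej_y - r$apex_y)^2) * r$mm_per_px
      if (da <= 2) next
      pct <- (dc - 2) / (da - 2) * 100
      pct <- min(max(pct, 0), 100)
      if (pct > pmax_pct) pmax_pct <- pct
    }
    stage <- if (pmax_pct < 15) "I" else if (pmax_pct <= 33) "II" else
      if (rows$teeth_remaining[1] >= 20) "III" else "IV"
    out[[pid]] <- stage
  }
  unlist(out)
}

ramp_image <- function(nr = 32, nc = 64) {
  matrix(rep(round(seq(0, 255, length.out = nc)), each = nr), nr, nc)
}

# Kolmogorov distance between an image's intensity CDF and the uniform CDF
# on [0, 255].
kolmogorov_to_uniform <- function(img) {
  v <- sort(as.vector(img))
  ecdf_v <- seq_along(v) / length(v)
  unif <- (v + 1) / 256
  max(abs(ecdf_v - unif))
}
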