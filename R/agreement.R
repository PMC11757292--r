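# Rater-agreement and diagnostic-performance statistics: binary confusion
# metrics, dichotomization of ordinal cross-tabulations, weighted Cohen's
# kappa with bootstrap / asymptotic intervals, and exact binomial confidence
# intervals. Metrics with a zero denominator return NA_real_ (an explicit
# "undefined" marker) rather than 0.

#' Binary confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives against the reference standard).
#' @return An object of class `binary_confusion`.
#' @export
binary_confusion <- function(tp, fp, fn, tn) {
  for (nm in c("tp", "fp", "fn", "tn")) {
    v <- get(nm)
    check_number(v, nm, min = 0)
    if (v != round(v)) stopf("'%s' must be an integer count", nm)
  }
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "binary_confusion")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Diagnostic metrics from a binary confusion
#'
#' Standard definitions: accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision = PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`,
#' F1 `2TP/(2TP+FP+FN)`. Any metric whose denominator is zero is reported as
#' `NA` (undefined), never silently as 0.
#'
#' @param confusion A [binary_confusion()] with positive total.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `ppv`, `npv`, `f1` (proportions in `[0, 1]` or `NA`).
#' @examples
#' binary_metrics(binary_confusion(tp = 983, fp = 589, fn = 11, tn = 18687))
#' @export
binary_metrics <- function(confusion) {
  if (!inherits(confusion, "binary_confusion"))
    stopf("'confusion' must be a binary_confusion object")
  n <- with(confusion, tp + fp + fn + tn)
  if (n == 0) stopf("all-zero confusion matrix: metrics undefined")
  with(confusion, list(
    accuracy    = (tp + tn) / n,
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp),
    precision   = safe_ratio(tp, tp + fp),
    ppv         = safe_ratio(tp, tp + fp),
    npv         = safe_ratio(tn, tn + fn),
    f1          = safe_ratio(2 * tp, 2 * tp + fp + fn)
  ))
}

#' Ordered-category rater cross-tabulation
#'
#' A K x K contingency table of two raters over the same ordered categories;
#' rows index the rater under evaluation, columns the reference (expert)
#' rater.
#'
#' @param counts K x K matrix of non-negative integer counts.
#' @param categories Ordered category labels (length K); defaults to existing
#'   dimnames or `0:(K-1)`.
#' @return An object of class `rater_table` (the counts matrix with labelled
#'   dimnames).
#' @export
rater_table <- function(counts, categories = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stopf("'counts' must be a square matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stopf("'counts' must be non-negative integers")
  if (sum(counts) <= 0) stopf("rater table must have positive total count")
  if (nrow(counts) < 2L) stopf("need at least 2 categories")
  if (is.null(categories))
    categories <- dimnames(counts)[[1]] %||% as.character(0:(nrow(counts) - 1L))
  if (length(categories) != nrow(counts))
    stopf("'categories' length must match table size")
  dimnames(counts) <- list(rater = categories, reference = categories)
  structure(counts, class = c("rater_table", "matrix"))
}

#' Collapse an ordinal rater table to a binary confusion
#'
#' Categories in `negative_labels` (typically the "no disease" category)
#' define the condition-negative class on the reference margin and the
#' test-negative class on the rater margin; all other categories are
#' positive. Counts are conserved: `tp + fp + fn + tn` equals the table
#' total.
#'
#' @param table A [rater_table()].
#' @param negative_labels Subset of the table's categories treated as
#'   negative.
#' @return A [binary_confusion()].
#' @examples
#' t9 <- load_fixture_tables()
#' binary_metrics(dichotomize(t9$rater_tables$periodontist, "0"))
#' @export
dichotomize <- function(table, negative_labels) {
  if (!inherits(table, "rater_table")) stopf("'table' must be a rater_table")
  cats <- dimnames(table)[[1]]
  unknown <- setdiff(negative_labels, cats)
  if (length(unknown))
    stopf("unknown label(s) in negative_labels: %s", paste(unknown, collapse = ", "))
  neg_r <- cats %in% negative_labels
  m <- unclass(table)
  binary_confusion(tp = sum(m[!neg_r, !neg_r]),
                   fp = sum(m[!neg_r,  neg_r]),
                   fn = sum(m[ neg_r, !neg_r]),
                   tn = sum(m[ neg_r,  neg_r]))
}

#' Agreement weights for ordered categories
#'
#' Builds the K x K weight matrix: linear `w_ij = 1 - |i - j| / (K - 1)`,
#' quadratic `w_ij = 1 - (i - j)^2 / (K - 1)^2`, or identity (1 on the
#' diagonal, 0 off it, giving unweighted kappa).
#'
#' @param K Number of categories.
#' @param kind `"linear"` (default), `"quadratic"`, or `"identity"`.
#' @return K x K numeric matrix with unit diagonal and entries in `[0, 1]`.
#' @export
kappa_weights <- function(K, kind = c("linear", "quadratic", "identity")) {
  kind <- match.arg(kind)
  check_number(K, "K", min = 2)
  d <- abs(outer(seq_len(K), seq_len(K), "-"))
  switch(kind,
         linear    = 1 - d / (K - 1),
         quadratic = 1 - (d / (K - 1))^2,
         identity  = (d == 0) + 0)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordered categories:
#' `kappa_w = (P_o - P_e) / (1 - P_e)` with observed weighted agreement
#' `P_o = sum w_ij p_ij` and expected agreement
#' `P_e = sum w_ij p_i. p_.j` from the marginals. Off-diagonal weights
#' down-weight near-miss disagreements by category distance. Kappa is exactly
#' 1 when all mass is diagonal; when the marginals are degenerate
#' (`P_e = 1`) kappa is 1 for perfect agreement and `NA` (undefined)
#' otherwise.
#'
#' @param table A [rater_table()].
#' @param weights Weight kind passed to [kappa_weights()], or a K x K
#'   numeric weight matrix.
#' @return List with `kappa`, `weighted_agreement_percent` (`100 * P_o`),
#'   `po`, `pe`, `n`.
#' @examples
#' t9 <- load_fixture_tables()
#' weighted_kappa(t9$rater_tables$periodontist)  # kappa 0.634
#' @export
weighted_kappa <- function(table, weights = "linear") {
  if (!inherits(table, "rater_table")) stopf("'table' must be a rater_table")
  K <- nrow(table)
  W <- if (is.character(weights)) kappa_weights(K, weights) else {
    if (!is.matrix(weights) || any(dim(weights) != K))
      stopf("'weights' matrix must be %d x %d", K, K)
    weights
  }
  p <- unclass(table) / sum(table)
  po <- sum(W * p)
  pe <- sum(W * outer(rowSums(p), colSums(p)))
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) 1 else NA_real_
  } else (po - pe) / (1 - pe)
  list(kappa = kappa, weighted_agreement_percent = 100 * po,
       po = po, pe = pe, n = sum(table))
}

# Large-sample (delta-method) variance of weighted kappa
# (Fleiss-Cohen-Everitt form).
weighted_kappa_var <- function(table, W) {
  p <- unclass(table) / sum(table)
  n <- sum(table)
  pr <- rowSums(p); pc <- colSums(p)
  po <- sum(W * p)
  pe <- sum(W * outer(pr, pc))
  wbar_r <- as.vector(W %*% pc)   # row-wise expected weight
  wbar_c <- as.vector(t(W) %*% pr)
  term <- outer(wbar_r, wbar_c, "+")
  s <- sum(p * (W * (1 - pe) - term * (1 - po))^2)
  (s - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
}

#' Confidence interval for weighted kappa
#'
#' Either a seeded percentile bootstrap over subject resamples of the
#' contingency table, or the large-sample (asymptotic, delta-method) normal
#' interval.
#'
#' @param table A [rater_table()] with total n >= 10.
#' @param weights As in [weighted_kappa()].
#' @param method `"bootstrap"` (default) or `"asymptotic"`.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `kappa`, `method`, `level`.
#' @export
kappa_ci <- function(table, weights = "linear",
                     method = c("bootstrap", "asymptotic"),
                     B = 2000L, seed = 1L, level = 0.95) {
  method <- match.arg(method)
  if (!inherits(table, "rater_table")) stopf("'table' must be a rater_table")
  n <- sum(table)
  if (n < 10) stopf("need at least 10 subjects for an interval")
  check_number(level, "level", min = 0, max = 1, strict_min = TRUE)
  est <- weighted_kappa(table, weights)$kappa
  cats <- dimnames(table)[[1]]
  K <- nrow(table)

  if (method == "asymptotic") {
    W <- if (is.character(weights)) kappa_weights(K, weights) else weights
    se <- sqrt(weighted_kappa_var(table, W))
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(list(lower = max(-1, est - z * se), upper = min(1, est + z * se),
                kappa = est, method = method, level = level))
  }

  if (B < 100) stopf("'B' must be at least 100 bootstrap resamples")
  # reconstruct subject-level (rater, reference) pairs and resample them
  idx <- which(unclass(table) > 0, arr.ind = TRUE)
  pairs <- idx[rep(seq_len(nrow(idx)), unclass(table)[idx]), , drop = FALSE]
  set.seed(seed)
  ks <- vapply(seq_len(B), function(b) {
    take <- pairs[sample.int(n, n, replace = TRUE), , drop = FALSE]
    m <- matrix(0L, K, K)
    for (r in seq_len(nrow(take))) m[take[r, 1L], take[r, 2L]] <- m[take[r, 1L], take[r, 2L]] + 1L
    weighted_kappa(rater_table(m, cats), weights)$kappa
  }, numeric(1))
  qs <- stats::quantile(ks, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], kappa = est, method = method, level = level)
}

#' Binomial proportion confidence interval
#'
#' Exact Clopper-Pearson (default; inverts the binomial test via beta
#' quantiles) or Wilson score interval.
#'
#' @param successes,n Non-negative counts, `successes <= n`, `n > 0`.
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `estimate`, `method`, `level`.
#' @examples
#' proportion_ci(82, 90)  # approx (0.832, 0.961)
#' @export
proportion_ci <- function(successes, n, method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  check_number(n, "n", min = 1)
  check_number(successes, "successes", min = 0, max = n)
  check_number(level, "level", min = 0, max = 1, strict_min = TRUE)
  x <- successes
  a <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    phat <- x / n
    den <- 1 + z^2 / n
    centre <- (phat + z^2 / (2 * n)) / den
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  list(lower = lower, upper = upper, estimate = x / n,
       method = method, level = level)
}
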