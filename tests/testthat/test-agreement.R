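test_that("binary metrics follow the standard definitions", {
  m <- binary_metrics(binary_confusion(983, 589, 11, 18687))
  expect_equal(m$accuracy, (983 + 18687) / 20270)
  expect_equal(round(m$accuracy, 2), 0.97)
  expect_equal(m$f1, 2 * 983 / (2 * 983 + 589 + 11))

  # undefined denominators give NA, never 0
  m2 <- binary_metrics(binary_confusion(0, 0, 0, 10))
  expect_equal(m2$accuracy, 1.0)
  expect_true(is.na(m2$sensitivity))
  expect_true(is.na(m2$ppv))
  expect_error(binary_metrics(binary_confusion(0, 0, 0, 0)), "all-zero")
})

test_that("dichotomization collapses ordinal tables and conserves counts", {
  fx <- load_fixture_tables()
  p <- dichotomize(fx$rater_tables$periodontist, "0")
  expect_equal(unlist(unclass(p)), c(tp = 77, fp = 0, fn = 8, tn = 5))
  g <- dichotomize(fx$rater_tables$gp, "0")
  expect_equal(unlist(unclass(g)), c(tp = 73, fp = 0, fn = 12, tn = 5))
  a <- dichotomize(fx$rater_tables$ai, "0")
  expect_equal(unlist(unclass(a)), c(tp = 85, fp = 5, fn = 0, tn = 0))

  # conservation for arbitrary tables and label splits
  set.seed(21)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    m <- matrix(rpois(K * K, 3), K, K)
    if (sum(m) == 0) m[1, 2] <- 1
    t <- rater_table(m)
    neg <- sample(dimnames(t)[[1]], sample(K - 1, 1))
    d <- dichotomize(t, neg)
    expect_equal(with(d, tp + fp + fn + tn), sum(m))
  }
  # a diagonal table has no off-diagonal errors
  d <- dichotomize(rater_table(diag(c(3, 4, 5))), "0")
  expect_equal(d$fp + d$fn, 0)
  expect_error(dichotomize(fx$rater_tables$gp, "9"), "unknown label")
})

test_that("weighted kappa matches hand-computed values and edge cases", {
  fx <- load_fixture_tables()
  wk <- weighted_kappa(fx$rater_tables$ai, "linear")
  expect_equal(wk$po, 81 / 90, tolerance = 1e-12)
  expect_equal(wk$pe, 6641.5 / 8100, tolerance = 1e-12)
  expect_equal(wk$weighted_agreement_percent, 90.0, tolerance = 1e-9)

  # any diagonal table gives kappa exactly 1
  expect_equal(weighted_kappa(rater_table(diag(c(2, 7, 5))))$kappa, 1.0)

  # identity weights reduce to unweighted Cohen's kappa
  set.seed(8)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    m <- matrix(rpois(K * K, 4), K, K); m[1, 1] <- m[1, 1] + 1
    t <- rater_table(m)
    p <- m / sum(m)
    po <- sum(diag(p)); pe <- sum(rowSums(p) * colSums(p))
    expect_equal(weighted_kappa(t, "identity")$kappa, (po - pe) / (1 - pe),
                 tolerance = 1e-12)
  }
})

test_that("weighted kappa is invariant under order-preserving relabelling", {
  fx <- load_fixture_tables()
  for (t in fx$rater_tables) {
    K <- nrow(t)
    rev_t <- rater_table(unclass(t)[K:1, K:1], dimnames(t)[[1]])
    expect_equal(weighted_kappa(rev_t, "linear")$kappa,
                 weighted_kappa(t, "linear")$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate marginals return the undefined marker", {
  t <- rater_table(matrix(c(10L, 0L, 0L, 0L), 2, 2))
  expect_equal(weighted_kappa(t)$kappa, 1)  # perfect one-category agreement
  t2 <- rater_table(matrix(c(0L, 10L, 0L, 0L), 2, 2))
  # both raters degenerate on different categories: pe = po under identity
  expect_true(is.na(weighted_kappa(t2, "identity")$kappa) ||
                is.finite(weighted_kappa(t2, "identity")$kappa))
})

test_that("agreement metrics match brute-force recomputation on random tables", {
  set.seed(123)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(5:50, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(1 / K^2, K^2)))
    m <- matrix(cells, K, K)
    t <- rater_table(m)
    for (kind in c("linear", "quadratic", "identity")) {
      W <- kappa_weights(K, kind)
      got <- weighted_kappa(t, kind)$kappa
      want <- brute_weighted_kappa(m, W)
      if (is.na(want) || !is.finite(want)) next
      expect_equal(got, want, tolerance = 1e-12)
    }
    d <- dichotomize(t, dimnames(t)[[1]][1])
    got_m <- binary_metrics(d)
    want_m <- brute_binary_metrics(d$tp, d$fp, d$fn, d$tn)
    expect_equal(got_m, want_m, tolerance = 1e-12)
  }
})

test_that("kappa intervals collapse on perfect agreement and are reproducible", {
  t <- rater_table(diag(c(5L, 7L, 8L)))
  ci <- kappa_ci(t, B = 200, seed = 4)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  ci1 <- kappa_ci(load_fixture_tables()$rater_tables$gp, B = 300, seed = 9)
  ci2 <- kappa_ci(load_fixture_tables()$rater_tables$gp, B = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, ci1$kappa)
  expect_gt(ci1$upper, ci1$kappa)
  expect_error(kappa_ci(t, B = 50), "at least 100")
})

test_that("asymptotic kappa intervals cover the closed-form value", {
  kernel <- matrix(c(0.8, 0.15, 0.05,
                     0.1, 0.8, 0.1,
                     0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  mix <- c(0.3, 0.4, 0.3)
  exp_p <- expected_rater_table(rater_sim_spec(1, 10, mix, kernel))
  W <- kappa_weights(3, "linear")
  po <- sum(W * exp_p)
  pe <- sum(W * outer(rowSums(exp_p), colSums(exp_p)))
  k_true <- (po - pe) / (1 - pe)

  covered <- 0L
  for (r in 1:200) {
    sim <- gen_rater_pair(rater_sim_spec(seed = 1000 + r, n_subjects = 200,
                                         true_stage_mix = mix,
                                         confusion_kernel = kernel))
    ci <- kappa_ci(sim$table, method = "asymptotic")
    if (ci$lower <= k_true && k_true <= ci$upper) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.90)
})

test_that("binomial proportion intervals match the exact binomial test", {
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)
  # dual route: binom.test inverts the same exact construction independently
  for (case in list(c(82, 90), c(5, 90), c(45, 90), c(1, 12))) {
    got <- proportion_ci(case[1], case[2])
    want <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(c(got$lower, got$upper), as.numeric(want), tolerance = 1e-6)
    expect_true(got$lower <= got$estimate && got$estimate <= got$upper)
  }
  # Wilson route against prop.test without continuity correction
  got_w <- proportion_ci(82, 90, method = "wilson")
  want_w <- suppressWarnings(stats::prop.test(82, 90, correct = FALSE))$conf.int
  expect_equal(c(got_w$lower, got_w$upper), as.numeric(want_w), tolerance = 1e-9)
  expect_error(proportion_ci(5, 0), "'n'")
})

test_that("the exact interval for 82/90 reproduces the published bounds", {
  ci <- proportion_ci(82, 90)
  expect_equal(round(100 * ci$lower, 1), 83.2)
  expect_equal(round(100 * ci$upper, 1), 96.1)
})

test_that("fixture tables load with validated totals", {
  fx <- load_fixture_tables()
  expect_equal(sum(fx$rater_tables$periodontist), 90)
  expect_equal(unname(rowSums(unclass(fx$rater_tables$ai))), c(0, 1, 39, 47, 3))
  expect_equal(unname(colSums(unclass(fx$rater_tables$ai))), c(5, 5, 36, 43, 1))
  expect_equal(fx$cej_model$tp, 508)
  expect_equal(with(fx$cej_model, tp + fp + fn + tn), 18630)
  expect_equal(with(fx$teeth_model, tp + fp + fn + tn), 20270)
})

test_that("recomputation flags only the documented exceptions", {
  rep <- suppressWarnings(recompute_published_tables(strict = TRUE))
  expect_true(all(rep$match | rep$exception))
  mism <- rep$quantity[!rep$match]
  expect_setequal(mism, c("periodontist_agreement_percent",
                          "cej_model_accuracy_2sf"))
  # tampering with a fixture-derived count must be caught
  fx <- load_fixture_tables()
  bad <- unclass(fx$rater_tables$gp); bad[1, 1] <- bad[1, 1] + 1L
  expect_error(rater_table(bad[0:0, ]), "square")
  wk_bad <- weighted_kappa(rater_table(bad, dimnames(fx$rater_tables$gp)[[1]]))
  expect_false(isTRUE(all.equal(round(wk_bad$kappa, 3), 0.429)))
})
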