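test_that("distances are Euclidean pixel distances scaled to mm", {
  lm <- tooth_landmarks(1, c(0, 0), c(0, 30), c(0, 120), 0.1)
  d <- measure_distances(lm)
  expect_equal(unname(d), c(3.0, 12.0))

  # 3-4-5 triangle
  lm2 <- tooth_landmarks(2, c(0, 0), c(30, 40), c(60, 80), 0.1)
  expect_equal(measure_distances(lm2)[["d_crest_mm"]], 5.0)

  # random triples against a plain hypot oracle
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(runif(6, -500, 500), 3, 2)
    s <- runif(1, 0.01, 0.5)
    lm3 <- tooth_landmarks(i, pts[1, ], pts[2, ], pts[3, ], s)
    d3 <- measure_distances(lm3)
    expect_equal(d3[["d_crest_mm"]],
                 sqrt(sum((pts[1, ] - pts[2, ])^2)) * s, tolerance = 1e-9)
    expect_equal(d3[["d_apex_mm"]],
                 sqrt(sum((pts[1, ] - pts[3, ])^2)) * s, tolerance = 1e-9)
  }
})

test_that("coincident landmarks make a tooth unmeasurable", {
  lm <- tooth_landmarks("x", c(5, 5), c(5, 5), c(0, 100), 0.1)
  expect_error(measure_distances(lm), "unmeasurable")
})

test_that("bone-loss percentage applies the 2 mm biologic-width correction", {
  expect_equal(bone_loss_percent(2.0, 12.0), 0.0)
  expect_equal(bone_loss_percent(7.0, 12.0), 50.0)
  expect_equal(bone_loss_percent(4.5, 14.8), 2.5 / 12.8 * 100)
  expect_equal(bone_loss_percent(1.0, 12.0), 0.0)    # crest within biologic width
  expect_equal(bone_loss_percent(15.0, 12.0), 100.0) # crest beyond apex clamps
  expect_error(bone_loss_percent(3.0, 2.0), "degenerate root")
  expect_error(bone_loss_percent(3.0, 1.5), "degenerate root")
})

test_that("bone-loss percentage is monotone in both distances", {
  pol <- staging_policy()
  dc <- seq(2.1, 10, length.out = 20)
  p1 <- vapply(dc, bone_loss_percent, numeric(1), d_apex_mm = 12, policy = pol)
  expect_true(all(diff(p1) >= 0))
  da <- seq(8, 18, length.out = 20)
  p2 <- vapply(da, function(a) bone_loss_percent(6, a, pol), numeric(1))
  expect_true(all(diff(p2) <= 0))
})

test_that("abnormality flag is strict at the 2 mm threshold", {
  expect_false(flag_abnormal(2.0))
  expect_true(flag_abnormal(2.01))
  expect_false(flag_abnormal(0.0))
})

test_that("patient staging follows the worst tooth and the bands", {
  mk <- function(percents) data.frame(bone_loss_percent = percents)
  expect_equal(stage_patient(mk(c(5, 14.9)), 28)$patient_stage, "I")
  expect_equal(stage_patient(mk(c(10, 40)), 24)$patient_stage, "III")
  expect_equal(stage_patient(mk(40), 18)$patient_stage, "IV")
  expect_equal(stage_patient(mk(c(3, 20)), 10)$patient_stage, "II")
  expect_error(stage_patient(mk(numeric(0)), 20), "no assessable teeth")
})

test_that("stage boundaries are pinned exactly", {
  st <- function(p, teeth = 28)
    stage_patient(data.frame(bone_loss_percent = p), teeth)$patient_stage
  expect_equal(st(14.999), "I")
  expect_equal(st(15.0), "II")
  expect_equal(st(33.0), "II")
  expect_equal(st(33.001, teeth = 20), "III")
  expect_equal(st(33.001, teeth = 19), "IV")
})

test_that("staging is monotone in severity and tooth loss", {
  st <- function(p, teeth)
    stage_patient(data.frame(bone_loss_percent = p), teeth)$patient_stage
  order_of <- c(I = 1, II = 2, III = 3, IV = 4)
  ps <- c(1, 10, 15, 25, 33, 40, 80, 100)
  for (teeth in c(16, 19, 20, 28)) {
    stages <- order_of[vapply(ps, st, character(1), teeth = teeth)]
    expect_true(all(diff(stages) >= 0))
  }
  for (p in ps)
    expect_gte(order_of[st(p, 16)], order_of[st(p, 28)])
})

test_that("assessments are invariant to coordinate/scale reparametrization", {
  set.seed(7)
  for (i in 1:10) {
    pts <- matrix(runif(6, 0, 2000), 3, 2)
    s <- 0.08
    a1 <- assess_tooth(tooth_landmarks(1, pts[1, ], pts[2, ], pts[3, ], s))
    f <- runif(1, 0.5, 4)
    a2 <- assess_tooth(tooth_landmarks(1, pts[1, ] * f, pts[2, ] * f,
                                       pts[3, ] * f, s / f))
    expect_equal(a1$bone_loss_percent, a2$bone_loss_percent, tolerance = 1e-9)
    expect_equal(a1$d_crest_mm, a2$d_crest_mm, tolerance = 1e-9)
  }
})

test_that("assess_cohort stages patients and reports exclusions", {
  spec <- phantom_cohort_spec(seed = 11, n_patients = 6)
  cohort <- gen_cohort(spec)
  # corrupt one patient completely: coincident landmarks on every tooth
  pid <- cohort$landmarks$patient_id[1]
  bad <- cohort$landmarks$patient_id == pid
  cohort$landmarks$crest_x[bad] <- cohort$landmarks$cej_x[bad]
  cohort$landmarks$crest_y[bad] <- cohort$landmarks$cej_y[bad]
  cohort$landmarks$apex_x[bad] <- cohort$landmarks$cej_x[bad]
  cohort$landmarks$apex_y[bad] <- cohort$landmarks$cej_y[bad]

  res <- assess_cohort(cohort$landmarks)
  expect_false(pid %in% res$summary$patient_id)
  expect_true(pid %in% res$exclusions$patient_id)
  expect_true(any(grepl("not staged", res$exclusions$reason)))
  # the other five patients still recover their generating stage
  merged <- merge(res$summary, cohort$truth, by = "patient_id")
  expect_equal(merged$patient_stage, merged$true_stage)
})

test_that("empty and malformed cohort tables are handled explicitly", {
  empty <- data.frame(patient_id = character(), tooth_id = character(),
                      cej_x = numeric(), cej_y = numeric(),
                      crest_x = numeric(), crest_y = numeric(),
                      apex_x = numeric(), apex_y = numeric(),
                      mm_per_px = numeric(), teeth_remaining = integer())
  expect_warning(res <- assess_cohort(empty), "empty cohort")
  expect_equal(nrow(res$summary), 0)
  expect_error(assess_cohort(data.frame(patient_id = 1)), "lacks columns")
})

test_that("a single patient with the worked per-tooth percents is Stage II", {
  teeth <- data.frame(bone_loss_percent = c(0, 50, 2.5 / 12.8 * 100))
  # worst tooth 50% would be III/IV; dropping it, the 19.53% tooth drives II
  expect_equal(stage_patient(teeth[-2, , drop = FALSE], 26)$patient_stage, "II")
})
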