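# Landmark-based bone-loss measurement and Stage I-IV assignment.
#
# The severity statistic is percentage radiographic bone loss,
#   100 * (d(CEJ, crest) - 2 mm) / (d(CEJ, apex) - 2 mm),
# where 2 mm is the physiological biologic width between the cemento-enamel
# junction (CEJ) and the alveolar crest in health. A patient's stage is driven
# by the worst (maximum) per-tooth percentage: <15% Stage I, 15-33% Stage II,
# >33% Stage III or IV depending on the number of remaining teeth.

#' Landmarks for a single tooth
#'
#' Bundles the three measurement landmarks of one tooth -- the cemento-enamel
#' junction (CEJ), the alveolar bone crest, and the root apex -- as pixel
#' coordinates, together with the image calibration in mm per pixel.
#'
#' @param tooth_id Identifier for the tooth (any scalar).
#' @param cej,crest,apex Numeric length-2 vectors `(x, y)` in pixels.
#' @param mm_per_px Positive scalar, millimetres per pixel.
#'
#' @return An object of class `tooth_landmarks`.
#' @examples
#' tooth_landmarks("16", cej = c(0, 0), crest = c(0, 30), apex = c(0, 120),
#'                 mm_per_px = 0.1)
#' @export
tooth_landmarks <- function(tooth_id, cej, crest, apex, mm_per_px) {
  as_pt <- function(p, name) {
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      stopf("'%s' must be a numeric (x, y) pair", name)
    as.numeric(p)
  }
  cej <- as_pt(cej, "cej"); crest <- as_pt(crest, "crest"); apex <- as_pt(apex, "apex")
  check_number(mm_per_px, "mm_per_px", min = 0, strict_min = TRUE)
  structure(
    list(tooth_id = tooth_id, cej = cej, crest = crest, apex = apex,
         mm_per_px = mm_per_px),
    class = "tooth_landmarks"
  )
}

#' Staging policy thresholds
#'
#' Thresholds used throughout staging: the biologic-width correction
#' subtracted from both distances, the crest-distance cut-off above which a
#' tooth is flagged abnormal, the Stage I/II and II/III bone-loss boundaries,
#' and the remaining-teeth count separating Stage III from Stage IV.
#'
#' @param biologic_width_mm Physiological CEJ-to-crest distance subtracted
#'   from numerator and denominator (default 2 mm).
#' @param abnormal_threshold_mm A tooth with CEJ-to-crest distance strictly
#'   greater than this is flagged abnormal (default 2 mm).
#' @param stage1_max_percent Upper bound (exclusive) of the Stage I bone-loss
#'   band (default 15).
#' @param stage2_max_percent Upper bound (inclusive) of the Stage II band
#'   (default 33).
#' @param min_teeth_for_stage3 Patients above the Stage II band are Stage III
#'   when at least this many teeth remain, otherwise Stage IV (default 20).
#'
#' @return An object of class `staging_policy`.
#' @export
staging_policy <- function(biologic_width_mm = 2.0,
                           abnormal_threshold_mm = 2.0,
                           stage1_max_percent = 15,
                           stage2_max_percent = 33,
                           min_teeth_for_stage3 = 20) {
  check_number(biologic_width_mm, "biologic_width_mm", min = 0)
  check_number(abnormal_threshold_mm, "abnormal_threshold_mm", min = 0)
  check_number(stage1_max_percent, "stage1_max_percent", min = 0, strict_min = TRUE)
  check_number(stage2_max_percent, "stage2_max_percent", max = 100)
  if (stage1_max_percent >= stage2_max_percent)
    stopf("stage1_max_percent must be < stage2_max_percent")
  check_number(min_teeth_for_stage3, "min_teeth_for_stage3", min = 0, max = 32)
  structure(
    list(biologic_width_mm = biologic_width_mm,
         abnormal_threshold_mm = abnormal_threshold_mm,
         stage1_max_percent = stage1_max_percent,
         stage2_max_percent = stage2_max_percent,
         min_teeth_for_stage3 = min_teeth_for_stage3),
    class = "staging_policy"
  )
}

#' Measure CEJ-to-crest and CEJ-to-apex distances
#'
#' Straight-line (Euclidean) pixel distances converted to millimetres.
#' Coincident landmark points make the tooth unmeasurable and raise an error,
#' mirroring the clinical exclusion of teeth whose bone loss cannot be
#' assessed.
#'
#' @param landmarks A [tooth_landmarks()] object.
#' @return Named numeric vector `c(d_crest_mm, d_apex_mm)`.
#' @examples
#' lm <- tooth_landmarks(1, c(0, 0), c(0, 30), c(0, 120), 0.1)
#' measure_distances(lm)  # 3 mm and 12 mm
#' @export
measure_distances <- function(landmarks) {
  if (!inherits(landmarks, "tooth_landmarks"))
    stopf("'landmarks' must be a tooth_landmarks object")
  pts <- list(landmarks$cej, landmarks$crest, landmarks$apex)
  for (i in 1:2) for (j in (i + 1):3)
    if (all(pts[[i]] == pts[[j]]))
      stopf("tooth %s is unmeasurable: coincident landmark points",
            format(landmarks$tooth_id))
  d <- function(a, b) sqrt(sum((a - b)^2)) * landmarks$mm_per_px
  c(d_crest_mm = d(landmarks$cej, landmarks$crest),
    d_apex_mm  = d(landmarks$cej, landmarks$apex))
}

#' Percentage radiographic bone loss
#'
#' Applies the biologic-width-corrected ratio
#' `100 * (d_crest - bw) / (d_apex - bw)` with `bw` the policy's biologic
#' width (2 mm by default). Raw values below 0 (crest within the biologic
#' width) clamp to 0; values above 100 (crest beyond the apex) clamp to 100,
#' so staging is a total function of measurable teeth.
#'
#' @param d_crest_mm CEJ-to-alveolar-crest distance in mm.
#' @param d_apex_mm CEJ-to-root-apex distance in mm; must exceed the biologic
#'   width, otherwise the root is degenerate and an error is raised.
#' @param policy A [staging_policy()].
#' @return Bone-loss percentage in `[0, 100]`.
#' @examples
#' bone_loss_percent(7, 12)    # 50
#' bone_loss_percent(4.5, 14.8)  # 19.53
#' @export
bone_loss_percent <- function(d_crest_mm, d_apex_mm, policy = staging_policy()) {
  check_number(d_crest_mm, "d_crest_mm", min = 0)
  bw <- policy$biologic_width_mm
  if (!is.finite(d_apex_mm) || d_apex_mm <= bw)
    stopf("degenerate root: d_apex_mm (%.3f) must exceed the biologic width (%.3f mm)",
          d_apex_mm, bw)
  clamp((d_crest_mm - bw) / (d_apex_mm - bw) * 100, 0, 100)
}

#' Flag a tooth as abnormal
#'
#' A tooth is abnormal when its CEJ-to-crest distance strictly exceeds the
#' policy threshold (default 2 mm); exactly 2 mm is still within the
#' physiological biologic width.
#'
#' @inheritParams bone_loss_percent
#' @return Logical scalar.
#' @export
flag_abnormal <- function(d_crest_mm, policy = staging_policy()) {
  check_number(d_crest_mm, "d_crest_mm", min = 0)
  d_crest_mm > policy$abnormal_threshold_mm
}

#' Assess one tooth from its landmarks
#'
#' @param landmarks A [tooth_landmarks()] object.
#' @param policy A [staging_policy()].
#' @return A one-row data frame with `tooth_id`, `d_crest_mm`, `d_apex_mm`,
#'   `bone_loss_percent`, `abnormal`, `tooth_stage` (the band `"I"`, `"II"` or
#'   `"III_IV"`; the III/IV split needs the patient-level teeth count).
#' @export
assess_tooth <- function(landmarks, policy = staging_policy()) {
  d <- measure_distances(landmarks)
  p <- bone_loss_percent(d[["d_crest_mm"]], d[["d_apex_mm"]], policy)
  band <- if (p < policy$stage1_max_percent) "I"
          else if (p <= policy$stage2_max_percent) "II"
          else "III_IV"
  data.frame(tooth_id = as.character(landmarks$tooth_id),
             d_crest_mm = d[["d_crest_mm"]],
             d_apex_mm = d[["d_apex_mm"]],
             bone_loss_percent = p,
             abnormal = flag_abnormal(d[["d_crest_mm"]], policy),
             tooth_stage = band,
             stringsAsFactors = FALSE)
}

#' Stage a patient from per-tooth assessments
#'
#' The patient stage follows the greatest bone loss across all measurable
#' teeth: below 15% Stage I, 15-33% (inclusive) Stage II, above 33% Stage III
#' when at least `min_teeth_for_stage3` teeth remain and Stage IV otherwise.
#'
#' @param assessments Data frame of per-tooth assessments as returned by
#'   [assess_tooth()] (rows are teeth; must contain `bone_loss_percent`).
#' @param teeth_remaining Integer count of remaining teeth, 0-32.
#' @param policy A [staging_policy()].
#' @param patient_id Optional identifier carried into the result.
#' @return An object of class `patient_assessment`: a list with `patient_id`,
#'   `teeth` (the assessments), `teeth_remaining`, `max_bone_loss_percent`
#'   and `patient_stage` (`"I"`, `"II"`, `"III"` or `"IV"`).
#' @examples
#' a <- rbind(assess_tooth(tooth_landmarks(1, c(0, 0), c(0, 30), c(0, 120), 0.1)),
#'            assess_tooth(tooth_landmarks(2, c(0, 0), c(0, 70), c(0, 120), 0.1)))
#' stage_patient(a, teeth_remaining = 24)
#' @export
stage_patient <- function(assessments, teeth_remaining,
                          policy = staging_policy(), patient_id = NA) {
  if (!is.data.frame(assessments) || nrow(assessments) == 0L)
    stopf("patient has no assessable teeth; cannot stage")
  check_number(teeth_remaining, "teeth_remaining", min = 0, max = 32)
  p_max <- max(assessments$bone_loss_percent)
  stage <-
    if (p_max < policy$stage1_max_percent) "I"
    else if (p_max <= policy$stage2_max_percent) "II"
    else if (teeth_remaining >= policy$min_teeth_for_stage3) "III"
    else "IV"
  structure(
    list(patient_id = patient_id, teeth = assessments,
         teeth_remaining = as.integer(teeth_remaining),
         max_bone_loss_percent = p_max, patient_stage = stage),
    class = "patient_assessment"
  )
}

#' @export
print.patient_assessment <- function(x, ...) {
  cat(sprintf("Patient %s: stage %s (max bone loss %.1f%%, %d teeth over %d assessed)\n",
              format(x$patient_id), x$patient_stage, x$max_bone_loss_percent,
              x$teeth_remaining, nrow(x$teeth)))
  invisible(x)
}

#' Assess and stage a whole cohort
#'
#' Batch driver over a long-format landmark table (one row per tooth).
#' Unmeasurable teeth -- coincident landmarks or a root not exceeding the
#' biologic width -- are excluded from the patient maximum and reported;
#' patients with no measurable tooth are listed in the exclusions report and
#' not staged.
#'
#' @param cohort Data frame with columns `patient_id`, `tooth_id`, `cej_x`,
#'   `cej_y`, `crest_x`, `crest_y`, `apex_x`, `apex_y`, `mm_per_px`,
#'   `teeth_remaining` (constant within patient).
#' @param policy A [staging_policy()].
#' @return A list with `assessments` (named list of `patient_assessment`),
#'   `summary` (data frame patient_id / teeth_remaining / max percent /
#'   stage) and `exclusions` (data frame patient_id / tooth_id / reason).
#' @export
assess_cohort <- function(cohort, policy = staging_policy()) {
  required <- c("patient_id", "tooth_id", "cej_x", "cej_y", "crest_x",
                "crest_y", "apex_x", "apex_y", "mm_per_px", "teeth_remaining")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stopf("cohort table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0L) {
    warning("empty cohort table: nothing to assess", call. = FALSE)
    return(list(assessments = list(),
                summary = data.frame(patient_id = character(),
                                     teeth_remaining = integer(),
                                     max_bone_loss_percent = numeric(),
                                     patient_stage = character(),
                                     stringsAsFactors = FALSE),
                exclusions = data.frame(patient_id = character(),
                                        tooth_id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)))
  }

  excl <- list()
  out <- list()
  for (pid in unique(cohort$patient_id)) {
    rows <- cohort[cohort$patient_id == pid, , drop = FALSE]
    per_tooth <- list()
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      res <- tryCatch(
        assess_tooth(tooth_landmarks(r$tooth_id,
                                     c(r$cej_x, r$cej_y),
                                     c(r$crest_x, r$crest_y),
                                     c(r$apex_x, r$apex_y),
                                     r$mm_per_px), policy),
        error = function(e) e)
      if (inherits(res, "error")) {
        excl[[length(excl) + 1L]] <- data.frame(
          patient_id = as.character(pid), tooth_id = as.character(r$tooth_id),
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        per_tooth[[length(per_tooth) + 1L]] <- res
      }
    }
    if (length(per_tooth) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(
        patient_id = as.character(pid), tooth_id = NA_character_,
        reason = "no measurable teeth; patient not staged",
        stringsAsFactors = FALSE)
      next
    }
    out[[as.character(pid)]] <- stage_patient(
      do.call(rbind, per_tooth), rows$teeth_remaining[1L], policy,
      patient_id = pid)
  }

  summary <- do.call(rbind, lapply(out, function(a) data.frame(
    patient_id = as.character(a$patient_id),
    teeth_remaining = a$teeth_remaining,
    max_bone_loss_percent = a$max_bone_loss_percent,
    patient_stage = a$patient_stage, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), tooth_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(assessments = out, summary = summary, exclusions = exclusions)
}
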