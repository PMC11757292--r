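# Phantom generators: landmark cohorts with known stages, radiograph-like
# images with ground-truth masks and polygon annotations, simulated rater
# pairs with a controllable confusion kernel, and perturbed detection sets.
# Every generator is a deterministic function of its spec (seed included).

#' Specification of a synthetic landmark cohort
#'
#' Describes a cohort of patients with per-tooth landmark triples whose
#' geometry is constructed by inverting the bone-loss formula: a target stage
#' is drawn, a bone-loss percentage is drawn inside that stage's band, and
#' the crest landmark is placed so that the measured percentage reproduces it
#' exactly (before optional jitter).
#'
#' @param seed Integer RNG seed.
#' @param n_patients Number of patients (>= 1).
#' @param stage_mix Probability vector over stages I-IV (sums to 1).
#' @param teeth_range Integer range (lo, hi) of remaining teeth per patient,
#'   within `[1, 32]` (default 16-28).
#' @param root_length_mean,root_length_sd Mean and sd (mm) of the truncated
#'   normal from which CEJ-to-apex root lengths are drawn (defaults 13, 1.5).
#' @param root_length_bounds Truncation bounds in mm (default `c(8, 20)`).
#' @param landmark_noise_mm Isotropic Gaussian jitter (sd, mm) added to each
#'   landmark coordinate after exact placement; 0 = noise-free.
#' @param scale_mm_per_px Image calibration (default 0.1 mm/px).
#' @return An object of class `phantom_cohort_spec`.
#' @export
phantom_cohort_spec <- function(seed = 1L, n_patients = 50L,
                                stage_mix = c(0.25, 0.25, 0.25, 0.25),
                                teeth_range = c(16L, 28L),
                                root_length_mean = 13.0, root_length_sd = 1.5,
                                root_length_bounds = c(8, 20),
                                landmark_noise_mm = 0,
                                scale_mm_per_px = 0.1) {
  check_number(seed, "seed")
  check_number(n_patients, "n_patients", min = 1)
  if (length(stage_mix) != 4L)
    stopf("'stage_mix' must have 4 entries (stages I-IV)")
  check_prob_vector(stage_mix, "stage_mix")
  if (length(teeth_range) != 2L || teeth_range[1] > teeth_range[2] ||
      teeth_range[1] < 1 || teeth_range[2] > 32)
    stopf("'teeth_range' must be an increasing pair within [1, 32]")
  check_number(root_length_sd, "root_length_sd", min = 0)
  check_number(landmark_noise_mm, "landmark_noise_mm", min = 0)
  check_number(scale_mm_per_px, "scale_mm_per_px", min = 0, strict_min = TRUE)
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         stage_mix = as.numeric(stage_mix),
         teeth_range = as.integer(teeth_range),
         root_length_mean = root_length_mean, root_length_sd = root_length_sd,
         root_length_bounds = as.numeric(root_length_bounds),
         landmark_noise_mm = landmark_noise_mm,
         scale_mm_per_px = scale_mm_per_px),
    class = "phantom_cohort_spec"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # rejection sampling; acceptance is ~1 at the default parameters
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Bone-loss percent bands used when sampling target severities. Stage I is
# sampled from [2, 15) rather than [0, 15) so that small jitter cannot push a
# tooth below the measurable range; III and IV share the (33, 80] band and
# are separated by the remaining-teeth count.
stage_percent_band <- function(stage) {
  switch(stage,
         I  = c(2, 14.999),
         II = c(15, 33),
         III = c(33.001, 80),
         IV  = c(33.001, 80))
}

#' Generate a synthetic landmark cohort with known stages
#'
#' For each patient a true stage is drawn from `stage_mix` and a maximal
#' bone-loss percentage uniformly inside that stage's band (I: 2-15%,
#' II: 15-33%, III/IV: 33-80%); remaining-teeth counts are drawn >= 20 for
#' Stage III and < 20 for Stage IV. The worst tooth's crest distance is
#' obtained by inverting the bone-loss formula at a sampled root length; the
#' other teeth receive smaller percentages. Landmarks are laid out
#' collinearly along a random tooth axis at the implied pixel distances, then
#' jittered by `landmark_noise_mm`.
#'
#' @param spec A [phantom_cohort_spec()].
#' @return List with `landmarks` (long-format data frame: `patient_id`,
#'   `tooth_id`, landmark coordinates, `mm_per_px`, `teeth_remaining`,
#'   `true_stage`) and `truth` (per-patient data frame: `patient_id`,
#'   `true_stage`, `true_max_percent`, `teeth_remaining`). Output is
#'   reproducible for a fixed spec.
#' @export
gen_cohort <- function(spec) {
  if (!inherits(spec, "phantom_cohort_spec"))
    stopf("'spec' must be a phantom_cohort_spec")
  set.seed(spec$seed)
  stages <- c("I", "II", "III", "IV")
  lo <- spec$teeth_range[1]; hi <- spec$teeth_range[2]
  rows <- vector("list", spec$n_patients)
  truth <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    stage <- sample(stages, 1L, prob = spec$stage_mix)
    band <- stage_percent_band(stage)
    p_max <- stats::runif(1, band[1], band[2])
    pick1 <- function(v) v[sample.int(length(v), 1L)]  # safe for length-1 v
    teeth_remaining <- switch(stage,
      III = pick1(seq(max(20L, lo), hi)),
      IV  = pick1(seq(lo, min(19L, hi))),
      pick1(seq(lo, hi)))
    n_teeth <- teeth_remaining
    # worst tooth gets p_max exactly; others strictly below it
    percents <- c(p_max, stats::runif(n_teeth - 1L, 0, p_max * 0.95))
    roots <- rtruncnorm1(n_teeth, spec$root_length_mean, spec$root_length_sd,
                         spec$root_length_bounds[1], spec$root_length_bounds[2])
    theta <- stats::runif(n_teeth, 0, 2 * pi)
    origin_x <- stats::runif(n_teeth, 100, 2000)
    origin_y <- stats::runif(n_teeth, 100, 1000)
    d_apex <- roots                                   # mm
    d_crest <- 2 + percents / 100 * (d_apex - 2)      # invert the formula
    s <- spec$scale_mm_per_px
    ux <- cos(theta); uy <- sin(theta)
    df <- data.frame(
      patient_id = sprintf("P%04d", i),
      tooth_id = sprintf("T%02d", seq_len(n_teeth)),
      cej_x = origin_x, cej_y = origin_y,
      crest_x = origin_x + ux * d_crest / s,
      crest_y = origin_y + uy * d_crest / s,
      apex_x = origin_x + ux * d_apex / s,
      apex_y = origin_y + uy * d_apex / s,
      mm_per_px = s, teeth_remaining = teeth_remaining,
      true_stage = stage, stringsAsFactors = FALSE)
    if (spec$landmark_noise_mm > 0) {
      jit <- function(n) stats::rnorm(n, 0, spec$landmark_noise_mm / s)
      for (col in c("cej_x", "cej_y", "crest_x", "crest_y", "apex_x", "apex_y"))
        df[[col]] <- df[[col]] + jit(n_teeth)
    }
    rows[[i]] <- df
    truth[[i]] <- data.frame(patient_id = df$patient_id[1], true_stage = stage,
                             true_max_percent = p_max,
                             teeth_remaining = teeth_remaining,
                             stringsAsFactors = FALSE)
  }
  list(landmarks = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Specification of a phantom radiograph-like image
#'
#' @param seed Integer RNG seed.
#' @param width,height Image size in pixels (>= 64).
#' @param n_teeth Number of tooth-like blobs to render (>= 0).
#' @param background_noise_sd Gaussian noise sd in grey levels (default 8).
#' @param background_level Mean background grey level (default 40).
#' @param tooth_intensity Grey-level range `(lo, hi)` of the blobs
#'   (default 150-230).
#' @return An object of class `phantom_image_spec`.
#' @export
phantom_image_spec <- function(seed = 1L, width = 256L, height = 192L,
                               n_teeth = 8L, background_noise_sd = 8,
                               background_level = 40,
                               tooth_intensity = c(150, 230)) {
  check_number(width, "width", min = 64)
  check_number(height, "height", min = 64)
  check_number(n_teeth, "n_teeth", min = 0)
  check_number(background_noise_sd, "background_noise_sd", min = 0)
  if (any(tooth_intensity < 0) || any(tooth_intensity > 255))
    stopf("'tooth_intensity' must lie within [0, 255]")
  structure(
    list(seed = as.integer(seed), width = as.integer(width),
         height = as.integer(height), n_teeth = as.integer(n_teeth),
         background_noise_sd = background_noise_sd,
         background_level = background_level,
         tooth_intensity = as.numeric(tooth_intensity)),
    class = "phantom_image_spec"
  )
}

# Even-odd rule point-in-polygon, vectorized over query points.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon to a logical mask
#'
#' Pixel centres (0-based coordinates `x + 0.5`, `y + 0.5`) inside the
#' polygon under the even-odd rule are TRUE.
#'
#' @param polygon Two-column matrix of `(x, y)` vertices in pixels.
#' @param width,height Mask dimensions.
#' @return `height` x `width` logical matrix (rows = y).
#' @export
polygon_to_mask <- function(polygon, width, height) {
  xs <- rep(seq_len(width) - 0.5, each = height)
  ys <- rep(seq_len(height) - 0.5, times = width)
  matrix(points_in_polygon(xs, ys, polygon[, 1], polygon[, 2]), height, width)
}

#' Generate a phantom radiograph-like image with ground truth
#'
#' Renders bright convex (elliptical, vertex-jittered) tooth-like blobs on a
#' noisy darker background. Each blob is defined by its annotation polygon;
#' the mask is the polygon's rasterization, so masks and annotations agree by
#' construction. Blobs are placed on a jittered grid and never overlap;
#' blobs whose polygon would cross the image border are clipped to it (the
#' blob count is preserved and reported in the metadata).
#'
#' @param spec A [phantom_image_spec()].
#' @return List with `image` (`height` x `width` grey-level matrix), `masks`
#'   (list of logical matrices, one per tooth), `polygons` (list of
#'   two-column vertex matrices), and `meta` (`n_teeth`, `n_clipped`).
#' @export
gen_phantom_image <- function(spec) {
  if (!inherits(spec, "phantom_image_spec"))
    stopf("'spec' must be a phantom_image_spec")
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  img <- matrix(clamp(round_half_away(
    stats::rnorm(w * h, spec$background_level, spec$background_noise_sd)),
    0, 255), h, w)
  masks <- list(); polys <- list()
  n_clipped <- 0L
  if (spec$n_teeth > 0) {
    # jittered grid placement guarantees pairwise-disjoint blobs
    ncol_grid <- ceiling(sqrt(spec$n_teeth * w / h))
    nrow_grid <- ceiling(spec$n_teeth / ncol_grid)
    cw <- w / ncol_grid; ch <- h / nrow_grid
    cells <- expand.grid(gx = seq_len(ncol_grid), gy = seq_len(nrow_grid))
    cells <- cells[seq_len(spec$n_teeth), , drop = FALSE]
    for (k in seq_len(spec$n_teeth)) {
      cx <- (cells$gx[k] - 0.5) * cw + stats::runif(1, -0.1, 0.1) * cw
      cy <- (cells$gy[k] - 0.5) * ch + stats::runif(1, -0.1, 0.1) * ch
      rx <- stats::runif(1, 0.18, 0.3) * cw
      ry <- stats::runif(1, 0.18, 0.35) * ch
      ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
      rad <- 1 + stats::runif(16L, -0.08, 0.08)
      poly <- cbind(cx + rx * rad * cos(ang), cy + ry * rad * sin(ang))
      clipped <- any(poly[, 1] < 0 | poly[, 1] > w | poly[, 2] < 0 | poly[, 2] > h)
      if (clipped) {
        poly[, 1] <- clamp(poly[, 1], 0, w)
        poly[, 2] <- clamp(poly[, 2], 0, h)
        n_clipped <- n_clipped + 1L
      }
      mask <- polygon_to_mask(poly, w, h)
      level <- stats::runif(1, spec$tooth_intensity[1], spec$tooth_intensity[2])
      img[mask] <- clamp(round_half_away(
        level + stats::rnorm(sum(mask), 0, spec$background_noise_sd / 2)), 0, 255)
      masks[[k]] <- mask
      polys[[k]] <- poly
    }
  }
  list(image = img, masks = masks, polygons = polys,
       meta = list(n_teeth = spec$n_teeth, n_clipped = n_clipped))
}

#' Specification of a simulated two-rater agreement study
#'
#' @param seed Integer RNG seed.
#' @param n_subjects Number of rated subjects (>= 1).
#' @param true_stage_mix Probability vector over the K true categories.
#' @param confusion_kernel K x K row-stochastic matrix;
#'   `kernel[i, j] = P(rated j | true i)`. Both raters draw independently
#'   through this kernel. The identity matrix gives perfect agreement.
#' @return An object of class `rater_sim_spec`.
#' @export
rater_sim_spec <- function(seed = 1L, n_subjects = 100L,
                           true_stage_mix, confusion_kernel) {
  check_number(n_subjects, "n_subjects", min = 1)
  check_prob_vector(true_stage_mix, "true_stage_mix")
  K <- length(true_stage_mix)
  if (K < 2) stopf("need at least 2 categories")
  if (!is.matrix(confusion_kernel) || any(dim(confusion_kernel) != K))
    stopf("'confusion_kernel' must be a %d x %d matrix", K, K)
  for (i in seq_len(K)) check_prob_vector(confusion_kernel[i, ],
                                          sprintf("confusion_kernel row %d", i))
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         true_stage_mix = as.numeric(true_stage_mix),
         confusion_kernel = confusion_kernel, K = K),
    class = "rater_sim_spec"
  )
}

#' Simulate a pair of raters over common subjects
#'
#' Each subject's true category is drawn from `true_stage_mix`; each rater's
#' label is drawn independently through the confusion kernel row of the true
#' category. Categories are labelled `0:(K-1)`.
#'
#' @param spec A [rater_sim_spec()].
#' @return List with `ratings_a`, `ratings_b` (integer vectors), `truth`, and
#'   `table` (a [rater_table()], rows = rater A, columns = rater B).
#' @export
gen_rater_pair <- function(spec) {
  if (!inherits(spec, "rater_sim_spec")) stopf("'spec' must be a rater_sim_spec")
  set.seed(spec$seed)
  K <- spec$K
  truth <- sample.int(K, spec$n_subjects, replace = TRUE,
                      prob = spec$true_stage_mix)
  draw <- function(t) vapply(t, function(ti)
    sample.int(K, 1L, prob = spec$confusion_kernel[ti, ]), integer(1))
  a <- draw(truth); b <- draw(truth)
  counts <- matrix(0L, K, K)
  for (s in seq_along(a)) counts[a[s], b[s]] <- counts[a[s], b[s]] + 1L
  list(ratings_a = a - 1L, ratings_b = b - 1L, truth = truth - 1L,
       table = rater_table(counts, as.character(0:(K - 1))))
}

#' Expected cross-tabulation of a simulated rater pair
#'
#' Closed form: `P(A = i, B = j) = sum_t mix_t kernel[t, i] kernel[t, j]`.
#' Useful as an oracle for the kappa that [gen_rater_pair()] converges to.
#'
#' @param spec A [rater_sim_spec()].
#' @return K x K probability matrix wrapped as a [rater_table()]-like
#'   probability table (a plain matrix summing to 1).
#' @export
expected_rater_table <- function(spec) {
  if (!inherits(spec, "rater_sim_spec")) stopf("'spec' must be a rater_sim_spec")
  Kn <- spec$confusion_kernel
  t(Kn) %*% diag(spec$true_stage_mix) %*% Kn
}

#' Perturb ground-truth boxes into a detection set
#'
#' Translates each mask's bounding box by `shift_px` in a random direction
#' and attaches confidence scores, producing a detection set whose mAP50
#' degrades monotonically with the shift.
#'
#' @param masks List of logical matrices (ground-truth masks of one image).
#' @param shift_px Non-negative translation magnitude in pixels.
#' @param seed Integer RNG seed.
#' @param image Image identifier placed in the output (default `"phantom"`).
#' @return List with `ground_truth` and `detections` data frames in the
#'   format of [map50()].
#' @export
gen_perturbed_detections <- function(masks, shift_px, seed = 1L,
                                     image = "phantom") {
  check_number(shift_px, "shift_px", min = 0)
  set.seed(seed)
  boxes <- lapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    # arr.ind: row = y, col = x; box spans pixel extents
    c(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
      x2 = max(idx[, 2]), y2 = max(idx[, 1]))
  })
  boxes <- boxes[!vapply(boxes, is.null, logical(1))]
  if (!length(boxes)) stopf("no non-empty masks to perturb")
  gt <- do.call(rbind, lapply(boxes, function(b)
    data.frame(image = image, class = "tooth",
               x1 = b[["x1"]], y1 = b[["y1"]], x2 = b[["x2"]], y2 = b[["y2"]])))
  theta <- stats::runif(length(boxes), 0, 2 * pi)
  det <- gt
  det$x1 <- det$x1 + shift_px * cos(theta)
  det$x2 <- det$x2 + shift_px * cos(theta)
  det$y1 <- det$y1 + shift_px * sin(theta)
  det$y2 <- det$y2 + shift_px * sin(theta)
  det$score <- stats::runif(length(boxes), 0.5, 1)
  rownames(gt) <- rownames(det) <- NULL
  list(ground_truth = gt, detections = det)
}
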