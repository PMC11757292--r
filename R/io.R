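# Annotation formats, images, dataset splitting and the pipeline driver.
#
# Polygon labels use a minimal LabelMe-style JSON layout: a top-level object
# with imageWidth / imageHeight and a `shapes` array of
# {label, points: [[x, y], ...]} in pixel coordinates. The segmentation text
# format is YOLO-style: one object per line,
# "class x1 y1 x2 y2 ..." with coordinates normalized to [0, 1].

#' Read polygon labels from a JSON file
#'
#' @param path Path to a polygon-JSON label file.
#' @return List with `width`, `height`, and `labels`, a list of records each
#'   holding `label` (string) and `points` (two-column matrix of pixel
#'   coordinates).
#' @export
read_polygon_labels <- function(path) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight))
    stopf("malformed label file %s: missing imageWidth/imageHeight", path)
  shapes <- doc$shapes %||% list()
  if (length(shapes) == 0L)
    warning(sprintf("label file %s contains no shapes", path), call. = FALSE)
  labels <- lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    pts <- s$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    if (is.null(s$label) || is.null(pts) || !is.numeric(pts) ||
        ncol(pts) != 2L || nrow(pts) < 3L)
      stopf("malformed label file %s: shape %d lacks a label or a valid polygon",
            path, i)
    list(label = s$label, points = unname(as.matrix(pts)))
  })
  list(width = doc$imageWidth, height = doc$imageHeight, labels = labels)
}

#' Write polygon labels to a JSON file
#'
#' Inverse of [read_polygon_labels()]; write then read is lossless.
#'
#' @param labels List of records with `label` and `points` (two-column
#'   matrix).
#' @param width,height Image dimensions in pixels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon_labels <- function(labels, width, height, path) {
  shapes <- lapply(labels, function(l) list(
    label = l$label,
    points = lapply(seq_len(nrow(l$points)), function(i)
      as.numeric(l$points[i, ]))))
  doc <- list(imageWidth = width, imageHeight = height, shapes = shapes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert polygon labels to YOLO-style segmentation lines
#'
#' Divides pixel coordinates by the image dimensions and prints each polygon
#' as one line `"class x1 y1 x2 y2 ..."` with 6-decimal fixed formatting.
#'
#' @param labels List of records with `label` and `points` as in
#'   [read_polygon_labels()].
#' @param image_w,image_h Image dimensions in pixels.
#' @param class_map Named integer vector mapping every label name to a class
#'   index (>= 0).
#' @return Character vector of annotation lines.
#' @examples
#' sq <- list(list(label = "tooth",
#'                 points = rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))))
#' to_yolo_seg(sq, 100, 100, c(tooth = 0L))
#' @export
to_yolo_seg <- function(labels, image_w, image_h, class_map) {
  check_number(image_w, "image_w", min = 1)
  check_number(image_h, "image_h", min = 1)
  names_seen <- vapply(labels, function(l) l$label, character(1))
  unmapped <- setdiff(unique(names_seen), names(class_map))
  if (length(unmapped))
    stopf("class_map does not cover label(s): %s", paste(unmapped, collapse = ", "))
  vapply(labels, function(l) {
    xy <- l$points
    if (any(xy[, 1] < 0 | xy[, 1] > image_w | xy[, 2] < 0 | xy[, 2] > image_h))
      stopf("polygon for label '%s' lies outside the image", l$label)
    norm <- rbind(xy[, 1] / image_w, xy[, 2] / image_h)
    paste(class_map[[l$label]],
          paste(sprintf("%.6f", as.numeric(norm)), collapse = " "))
  }, character(1))
}

#' Parse YOLO-style segmentation lines
#'
#' Inverse of [to_yolo_seg()] up to the 6-decimal formatting: coordinates
#' are rescaled back to pixels.
#'
#' @param lines Character vector of annotation lines.
#' @param image_w,image_h Image dimensions in pixels.
#' @return List of records with `class_index` and `points` (pixel
#'   coordinates).
#' @export
read_yolo_seg <- function(lines, image_w, image_h) {
  lapply(seq_along(lines), function(i) {
    f <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    if (length(f) < 7L || (length(f) - 1L) %% 2L != 0L || anyNA(f))
      stopf("malformed YOLO segmentation line %d", i)
    coords <- f[-1]
    if (any(coords < 0 | coords > 1))
      stopf("line %d: normalized coordinates outside [0, 1]", i)
    xy <- matrix(coords, ncol = 2L, byrow = TRUE)  # interleaved x, y pairs
    list(class_index = as.integer(f[1]),
         points = cbind(xy[, 1] * image_w, xy[, 2] * image_h))
  })
}

#' Split ids into train / validation / test sets
#'
#' Seeded shuffle followed by a largest-remainder apportionment of the
#' ratios, so the three partitions are disjoint, exhaustive, and
#' deterministic for a fixed seed. Splitting is by whole id (patient), never
#' by tooth, to avoid leakage between partitions.
#'
#' @param ids Vector of unique identifiers.
#' @param ratios Numeric length-3 vector `(train, val, test)` summing to 1
#'   (default `c(0.70, 0.10, 0.20)`).
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `val`, `test`.
#' @examples
#' lengths(split_dataset(sprintf("img%04d", 1:2000)))  # 1400 / 200 / 400
#' @export
split_dataset <- function(ids, ratios = c(0.70, 0.10, 0.20), seed = 1L) {
  if (anyDuplicated(ids)) stopf("'ids' must be unique")
  if (length(ratios) != 3L) stopf("'ratios' must have 3 entries")
  check_prob_vector(ratios, "ratios")
  n <- length(ids)
  if (n < sum(ratios > 0)) stopf("fewer ids (%d) than nonzero partitions", n)
  base <- floor(n * ratios)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * ratios - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  set.seed(seed)
  shuffled <- sample(ids, n)
  list(train = shuffled[seq_len(base[1])],
       val = shuffled[base[1] + seq_len(base[2])],
       test = shuffled[base[1] + base[2] + seq_len(base[3])])
}

#' Read an 8-bit grayscale image
#'
#' PNG (and TIFF when the `tiff` package is available) to a grey-level
#' matrix 0-255. Multi-channel inputs are rejected.
#'
#' @param path Image path; format inferred from the extension.
#' @return Numeric matrix of grey levels (rows = y).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L)
      stopf("expected a single-channel image; got %d channels", dim(raw)[3])
    raw <- raw[, , 1]
  }
  round_half_away(raw * 255)
}

#' Write an 8-bit grayscale image
#'
#' @param image Grey-level matrix 0-255.
#' @param path Output path (.png, or .tif/.tiff with the `tiff` package).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  scaled <- clamp(image, 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
    },
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  invisible(path)
}

#' Write / read a landmark cohort table as CSV
#'
#' @param cohort Cohort data frame (see [assess_cohort()] for the schema).
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: the
#'   data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the phantom-to-evaluation pipeline
#'
#' End-to-end driver: generates a phantom cohort, stages it, cross-tabulates
#' recovered against true stages, and computes the weighted kappa between
#' them; optionally writes a JSON report. All randomness flows from
#' `config$seed`.
#'
#' @param config Named list (or path to a YAML file) with elements `seed`,
#'   `n_patients`, `landmark_noise_mm`, `stage_mix` and optionally
#'   `out` (report path).
#' @return List with `summary` (per-patient stages), `truth`, `recovery_rate`
#'   (fraction of patients whose stage was recovered), `kappa`
#'   (recovered-vs-true linearly weighted kappa) and `report_path` (or NULL).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("'config' must be a list or a YAML file path")
  for (field in c("seed", "n_patients"))
    if (is.null(config[[field]])) stopf("config lacks required field '%s'", field)

  spec <- phantom_cohort_spec(
    seed = config$seed, n_patients = config$n_patients,
    stage_mix = config$stage_mix %||% c(0.25, 0.25, 0.25, 0.25),
    landmark_noise_mm = config$landmark_noise_mm %||% 0)
  cohort <- gen_cohort(spec)
  res <- assess_cohort(cohort$landmarks)
  merged <- merge(res$summary, cohort$truth, by = "patient_id")
  recovery <- mean(merged$patient_stage == merged$true_stage)
  stages <- c("I", "II", "III", "IV")
  tab <- table(factor(merged$patient_stage, stages),
               factor(merged$true_stage, stages))
  kap <- weighted_kappa(rater_table(unclass(tab) + 0L, stages), "linear")$kappa
  out <- list(summary = res$summary, truth = cohort$truth,
              exclusions = res$exclusions,
              recovery_rate = recovery, kappa = kap, report_path = NULL)
  if (!is.null(config$out)) {
    report <- list(seed = config$seed, n_patients = config$n_patients,
                   recovery_rate = recovery, kappa = kap,
                   patients = res$summary)
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA)
    out$report_path <- config$out
  }
  out
}
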