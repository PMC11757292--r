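# Radiograph enhancement operators: unsharp masking, global histogram
# equalization, and 3x3 Gaussian smoothing. Images are numeric matrices of
# 8-bit grey levels (0-255), rows = y, columns = x. Integer outputs use
# half-away-from-zero rounding so that results are reproducible across
# platforms.

#' Preprocessing configuration
#'
#' @param sharpen_amount Non-negative unsharp-mask gain; 0 is the identity
#'   (default 1).
#' @param equalize_levels Number of grey levels for equalization (default 256).
#' @param border_mode Border padding for convolutions, `"reflect"` (mirror
#'   without repeating the edge pixel) or `"replicate"` (default reflect;
#'   avoids dark-border artefacts near image edges).
#'
#' @return An object of class `preprocess_config`; its `gaussian_kernel`
#'   element is the normalized 3x3 binomial kernel (entries sum to 1).
#' @export
preprocess_config <- function(sharpen_amount = 1.0, equalize_levels = 256L,
                              border_mode = c("reflect", "replicate")) {
  check_number(sharpen_amount, "sharpen_amount", min = 0)
  check_number(equalize_levels, "equalize_levels", min = 2)
  border_mode <- match.arg(border_mode)
  structure(
    list(sharpen_amount = sharpen_amount,
         gaussian_kernel = gaussian3_kernel(),
         equalize_levels = as.integer(equalize_levels),
         border_mode = border_mode),
    class = "preprocess_config"
  )
}

#' The normalized 3x3 binomial (Gaussian) kernel
#'
#' `(1/16) * [1 2 1; 2 4 2; 1 2 1]`, the discrete Gaussian used for smoothing
#' and inside the unsharp mask.
#'
#' @return A 3x3 numeric matrix summing to exactly 1.
#' @export
gaussian3_kernel <- function() {
  matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
}

check_gray_image <- function(image, min_dim = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("expected a single-channel image as a numeric matrix (grey levels 0-255); got %s",
          paste(class(image), collapse = "/"))
  if (length(image) == 0L) stopf("empty image")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stopf("image must be at least %dx%d", min_dim, min_dim)
  invisible(image)
}

pad1 <- function(image, border_mode) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- if (border_mode == "reflect" && nr > 1) c(2L, 1:nr, nr - 1L) else c(1L, 1:nr, nr)
  ci <- if (border_mode == "reflect" && nc > 1) c(2L, 1:nc, nc - 1L) else c(1L, 1:nc, nc)
  image[ri, ci, drop = FALSE]
}

# 3x3 correlation via nine shifted adds on the padded image; kernels here are
# symmetric so correlation == convolution.
conv3 <- function(image, kernel, border_mode) {
  p <- pad1(image, border_mode)
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    w <- kernel[dy + 2L, dx + 2L]
    if (w != 0)
      out <- out + w * p[(2L + dy):(nr + 1L + dy), (2L + dx):(nc + 1L + dx), drop = FALSE]
  }
  out
}

#' Sharpen an image by unsharp masking
#'
#' `out = clip(I + amount * (I - G3(I)), 0, 255)` where `G3` is the 3x3
#' Gaussian blur: the blurred copy is subtracted to isolate edges, which are
#' then added back scaled by `sharpen_amount`. The smoothing is done in
#' floating point; only the final result is rounded (half away from zero).
#'
#' @param image Numeric matrix of grey levels 0-255 (single channel).
#' @param config A [preprocess_config()].
#' @return Matrix of the same dimensions, integer grey levels in `[0, 255]`.
#' @export
sharpen <- function(image, config = preprocess_config()) {
  check_gray_image(image, min_dim = 1L)
  blur <- conv3(image, config$gaussian_kernel, config$border_mode)
  clamp(round_half_away(image + config$sharpen_amount * (image - blur)), 0, 255)
}

#' Global histogram equalization
#'
#' Standard cumulative-distribution remapping:
#' `out(v) = round((L - 1) * (CDF(v) - CDF_min) / (N - CDF_min))` with
#' `L = equalize_levels`, `N` the pixel count and `CDF_min` the CDF at the
#' lowest occupied grey level. The mapping is monotone non-decreasing, so
#' intensity order is preserved. A single-level (constant) image is returned
#' unchanged, the mapping being degenerate there.
#'
#' @inheritParams sharpen
#' @return Equalized image, same dimensions, grey levels in `[0, L - 1]`.
#' @export
equalize_hist <- function(image, config = preprocess_config()) {
  check_gray_image(image, min_dim = 1L)
  L <- config$equalize_levels
  v <- as.integer(clamp(round_half_away(image), 0, L - 1))
  counts <- tabulate(v + 1L, nbins = L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- cdf[which(counts > 0)[1L]]
  if (n == cdf_min) return(image)  # constant image
  map <- round_half_away((L - 1) * (cdf - cdf_min) / (n - cdf_min))
  matrix(map[v + 1L], nrow(image), ncol(image))
}

#' Smooth an image with the 3x3 Gaussian kernel
#'
#' Convolution with `(1/16) [1 2 1; 2 4 2; 1 2 1]` under the configured
#' border mode. Because the kernel sums to 1, the mean grey level is
#' preserved up to rounding. With `integer_output = FALSE` the raw
#' floating-point response is returned (useful for inspecting the impulse
#' response).
#'
#' @inheritParams sharpen
#' @param integer_output Round and clip the result to 8-bit levels
#'   (default TRUE).
#' @return Smoothed image, same dimensions.
#' @export
gaussian3 <- function(image, config = preprocess_config(), integer_output = TRUE) {
  check_gray_image(image, min_dim = 3L)
  out <- conv3(image, config$gaussian_kernel, config$border_mode)
  if (integer_output) clamp(round_half_away(out), 0, 255) else out
}

#' Apply a sequence of enhancement steps
#'
#' @inheritParams sharpen
#' @param steps Character vector drawn from `"sharpen"`, `"equalize"`,
#'   `"gaussian"`, applied in the given order (default all three, in that
#'   order).
#' @return Processed image.
#' @export
preprocess_image <- function(image, steps = c("sharpen", "equalize", "gaussian"),
                             config = preprocess_config()) {
  known <- c(sharpen = "sharpen", equalize = "equalize", gaussian = "gaussian")
  bad <- setdiff(steps, known)
  if (length(bad)) stopf("unknown preprocessing step(s): %s", paste(bad, collapse = ", "))
  for (s in steps) {
    image <- switch(s,
                    sharpen  = sharpen(image, config),
                    equalize = equalize_hist(image, config),
                    gaussian = gaussian3(image, config))
  }
  image
}
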