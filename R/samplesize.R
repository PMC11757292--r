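# Sample-size planning for a two-rater binary agreement study:
#   n = [ (z_{1-a/2} sqrt(Q0) + z_{1-b} sqrt(Q1)) / (k1 - k0) ]^2
# where Q0 and Q1 are the large-sample variance factors (n * var(kappa_hat))
# of the kappa estimate under the null (k0) and alternative (k1) hypotheses.
# The default Q model is the Fleiss-Cohen-Everitt (1969) kappa variance
# evaluated on the 2x2 table induced by the raters' positive-call
# probabilities and the hypothesised kappa.

#' 2x2 cell probabilities for given marginals and kappa
#'
#' For two binary raters with positive-call probabilities `pi_e` (rater 1)
#' and `pi_0` (rater 2), agreement kappa fixes the joint distribution:
#' `P_e = pi_e pi_0 + (1-pi_e)(1-pi_0)`, `P_o = P_e + kappa (1 - P_e)`, and
#' `p11 = (P_o - 1 + pi_e + pi_0) / 2`.
#'
#' @param pi_e,pi_0 Probabilities in (0, 1) that rater 1 / rater 2 call
#'   positive.
#' @param kappa Agreement in `[0, 1]`.
#' With unequal marginals the attainable kappa is bounded below 1; a
#' hypothesised kappa slightly above that bound (a common situation when a
#' relative deviation is applied to a high baseline kappa) yields one
#' marginally negative cell. The algebraic values are kept, with a warning,
#' so the variance factors remain exact polynomial evaluations; a grossly
#' infeasible kappa errors.
#'
#' @return 2x2 probability matrix (rows rater 1, columns rater 2,
#'   positive first).
#' @export
kappa2x2_probs <- function(pi_e, pi_0, kappa) {
  check_number(pi_e, "pi_e", min = 0, strict_min = TRUE)
  check_number(pi_0, "pi_0", min = 0, strict_min = TRUE)
  if (pi_e >= 1 || pi_0 >= 1) stopf("marginal probabilities must be in (0, 1)")
  check_number(kappa, "kappa", min = 0, max = 1)
  pe <- pi_e * pi_0 + (1 - pi_e) * (1 - pi_0)
  po <- pe + kappa * (1 - pe)
  p11 <- (po - 1 + pi_e + pi_0) / 2
  p <- matrix(c(p11, pi_e - p11, pi_0 - p11, 1 - pi_e - pi_0 + p11), 2, 2,
              byrow = TRUE,
              dimnames = list(rater1 = c("pos", "neg"), rater2 = c("pos", "neg")))
  if (any(p < -0.05))
    stopf("kappa %.3f is infeasible for marginals (%.3f, %.3f)", kappa, pi_e, pi_0)
  if (any(p < -1e-12))
    warning(sprintf(paste0(
      "kappa %.4f slightly exceeds the maximum attainable for marginals ",
      "(%.3f, %.3f); proceeding with the algebraic cell values"),
      kappa, pi_e, pi_0), call. = FALSE)
  p
}

# Q = n * var(kappa_hat): Fleiss-Cohen-Everitt large-sample variance of
# unweighted kappa on a 2x2 probability table.
kappa_variance_factor <- function(p) {
  pr <- rowSums(p); pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  s1 <- sum(diag(p) * ((1 - pe) - (pc + pr) * (1 - po))^2)
  s2 <- (1 - po)^2 * (p[1, 2] * (pc[1] + pr[2])^2 + p[2, 1] * (pc[2] + pr[1])^2)
  unname((s1 + s2 - (po * pe - 2 * pe + po)^2) / (1 - pe)^4)
}

#' Alternative kappa from a percentage deviation
#'
#' `k1 = k0 * (1 + deviation_percent / 100)`; errors if the result exceeds 1.
#'
#' @param k0 Null-hypothesis kappa.
#' @param deviation_percent Relative deviation in percent.
#' @return The alternative kappa `k1`.
#' @examples
#' deviation_to_k1(0.766, 25)  # 0.9575
#' @export
deviation_to_k1 <- function(k0, deviation_percent) {
  check_number(k0, "k0", min = 0, max = 1)
  check_number(deviation_percent, "deviation_percent", min = 0)
  k1 <- k0 * (1 + deviation_percent / 100)
  if (k1 > 1) stopf("k1 = %.4f exceeds 1; reduce the deviation", k1)
  k1
}

#' Sample size to detect a kappa difference between two raters
#'
#' Number of subjects needed so that a two-sided level-`alpha` test of
#' `kappa = k0` has the requested power against `kappa = k1`, for two binary
#' raters with stated positive-call probabilities:
#' `n = ceil( ((z_{1-alpha/2} sqrt(Q0) + z_{1-power} sqrt(Q1)) / (k1 - k0))^2 )`.
#'
#' @param k0 Null-hypothesis kappa.
#' @param k1 Alternative kappa (`> k0`); give either `k1` or
#'   `deviation_percent`.
#' @param deviation_percent If `k1` is missing, `k1 = k0 (1 + d/100)`.
#' @param pi_e,pi_0 Positive-call probabilities of rater 1 and rater 2.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Desired power `1 - beta` (default 0.80).
#' @param q_model Variance model mapping a 2x2 probability table to
#'   `Q = n var(kappa_hat)`; defaults to the Fleiss-Cohen-Everitt kappa
#'   variance.
#' @return An object of class `kappa_sample_size`: list with `n` (ceiling),
#'   `n_raw`, `q0`, `q1`, `z_alpha`, `z_beta`, and the inputs.
#' @examples
#' # Planning an agreement study at molar-agreement marginals:
#' kappa_sample_size(k0 = 0.766, deviation_percent = 25,
#'                   pi_e = 0.734, pi_0 = 0.766)  # n = 83
#' @export
kappa_sample_size <- function(k0, k1 = NULL, deviation_percent = NULL,
                              pi_e, pi_0, alpha = 0.05, power = 0.80,
                              q_model = kappa_variance_factor) {
  check_number(k0, "k0", min = 0, max = 1)
  if (is.null(k1)) {
    if (is.null(deviation_percent))
      stopf("supply either 'k1' or 'deviation_percent'")
    k1 <- deviation_to_k1(k0, deviation_percent)
  }
  check_number(k1, "k1", min = 0, max = 1)
  if (k1 <= k0) stopf("'k1' (%.4f) must exceed 'k0' (%.4f)", k1, k0)
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) stopf("'alpha' must be in (0, 1)")
  check_number(power, "power", min = 0, max = 1, strict_min = TRUE)
  if (power >= 1) stopf("'power' must be in (0, 1)")

  q0 <- q_model(kappa2x2_probs(pi_e, pi_0, k0))
  q1 <- q_model(kappa2x2_probs(pi_e, pi_0, k1))
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_beta <- stats::qnorm(power)
  n_raw <- ((z_alpha * sqrt(q0) + z_beta * sqrt(q1)) / (k1 - k0))^2
  structure(
    list(n = as.integer(ceiling(n_raw)), n_raw = n_raw, q0 = q0, q1 = q1,
         z_alpha = z_alpha, z_beta = z_beta, k0 = k0, k1 = k1,
         pi_e = pi_e, pi_0 = pi_0, alpha = alpha, power = power),
    class = "kappa_sample_size"
  )
}

#' @export
print.kappa_sample_size <- function(x, ...) {
  cat(sprintf(
    "Kappa sample size: n = %d (raw %.2f)\n  k0 = %.4f vs k1 = %.4f, marginals (%.3f, %.3f)\n  alpha = %.3f two-sided, power = %.2f, Q0 = %.4f, Q1 = %.4f\n",
    x$n, x$n_raw, x$k0, x$k1, x$pi_e, x$pi_0, x$alpha, x$power, x$q0, x$q1))
  invisible(x)
}
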