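#' Max-Stat adjustment for z-based tests
#'
#' Family-wise error control by the maximum of J independent standard normal
#' statistics. The critical value is approximated by the
#' \eqn{(1-\alpha/2)^{1/J}} quantile of the standard normal (set
#' `exact = TRUE` for \eqn{\Phi^{-1}((1 + (1-\alpha)^{1/J})/2)}; the two
#' agree to three decimals even at J of several hundred). The adjusted
#' p-value is the independence transform \eqn{1 - (1 - p_{raw})^J}, clipped
#' to `[0, 1]`; a hypothesis is rejected when `|z|` exceeds the critical
#' value, equivalently when its adjusted p is at most alpha.
#'
#' @param z numeric vector of signed z scores (one per unit).
#' @param alpha significance level.
#' @param exact use the exact max-of-|normals| quantile instead of the
#'   standard approximation.
#' @return list with `p_raw`, `p_adjusted`, `rejected` (logical),
#'   `critical_value`, `alpha`, `J`.
#' @export
maxstat_adjust_normal <- function(z, alpha = 0.05, exact = FALSE) {
  J <- length(z)
  if (J == 0) stop("no test results")
  critical <- if (exact) {
    stats::qnorm((1 + (1 - alpha)^(1 / J)) / 2)
  } else {
    stats::qnorm((1 - alpha / 2)^(1 / J))
  }
  p_raw <- normal_p_two_sided(z)
  # 1 - (1 - p)^J, computed stably for p near 0 (reduces to ~ J*p)
  p_adj <- pmin(1, -expm1(J * log1p(-p_raw)))
  list(p_raw = p_raw, p_adjusted = p_adj, rejected = abs(z) > critical,
       critical_value = critical, alpha = alpha, J = J)
}

#' Max-Stat adjustment for the likelihood ratio test
#'
#' Step-down rejection against the Monte-Carlo null of the family maximum:
#' unit j is rejected when its LR exceeds the empirical (1 - alpha) quantile
#' of the MLR draws ([mlr_quantile()]); its adjusted p-value is the
#' Monte-Carlo tail probability of the MLR null at the observed LR.
#'
#' @param statistics named numeric vector of observed LR values, names being
#'   unit ids matching `samples`.
#' @param samples [sample_null()] output for the same family.
#' @param alpha significance level.
#' @return list with `p_adjusted`, `rejected`, `critical_value`, `alpha`.
#' @export
maxstat_adjust_lrt <- function(statistics, samples, alpha = 0.05) {
  if (!is.null(names(statistics)) &&
      !setequal(names(statistics), samples$unit_ids))
    stop("unit sets of statistics and null samples differ")
  critical <- mlr_quantile(samples, alpha)
  p_adj <- stats::setNames(mc_p_value(statistics, samples$mlr_draws),
                           names(statistics))
  list(p_adjusted = p_adj, rejected = statistics > critical,
       critical_value = critical, alpha = alpha)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: with ordered p-values \eqn{P_{(1)} \le \dots \le
#' P_{(J)}}, reject the k smallest where k is the largest index with
#' \eqn{P_{(k)} \le (k/J)\alpha}. Adjusted p-values are the standard step-up
#' monotone transform (as in `p.adjust(method = "BH")`), whose comparison
#' against alpha reproduces the raw rule's rejection set.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha target false discovery rate.
#' @return list with `p_adjusted`, `rejected`, `alpha`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = p_adj, rejected = p_adj <= alpha, alpha = alpha)
}
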