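#' Likelihood ratio statistic for host-factor disparity
#'
#' Computes the log-likelihood-ratio statistic for a 2x2 host-factor table.
#' Under the conditional binomial null (exposed group-1 count distributed as
#' Binomial with the margin proportion), the statistic is
#' \deqn{LR = -n \log(n/N) + a_1 \log(a_1/M_1) + a_2 \log(a_2/M_2),}
#' where \eqn{a_1, a_2} are the exposed counts in the two host-factor groups,
#' \eqn{n = a_1 + a_2}, \eqn{M_1, M_2} are the group margins and
#' \eqn{N = M_1 + M_2}. Equivalently \eqn{\sum_s n^{(s)} \log(n^{(s)}/E^{(s)})}
#' with baseline frequency \eqn{E^{(s)} = M_s n / N}. Natural logarithm;
#' the convention \eqn{0 \log 0 = 0} makes zero exposed cells finite.
#'
#' @param family a [table_family] or any data frame with columns
#'   `a1`, `a2`, `b1`, `b2` (exposed group 1/2, unexposed group 1/2).
#' @return numeric vector of nonnegative LR values, one per table.
#' @seealso [z_statistic()], [mlr()], [sample_null()]
#' @examples
#' tab <- data.frame(a1 = 1032, a2 = 1789, b1 = 46798, b2 = 51289)
#' lr_statistic(tab)  # 67.2388
#' @export
lr_statistic <- function(family) {
  cells <- check_cells(family)
  with(cells, {
    n  <- a1 + a2
    M1 <- a1 + b1
    M2 <- a2 + b2
    N  <- M1 + M2
    if (any(M1 <= 0)) stop("group-1 margin (a1 + b1) must be positive")
    if (any(M2 <= 0)) stop("group-2 margin (a2 + b2) must be positive")
    lr <- -xlogx(n, N) + xlogx(a1, M1) + xlogx(a2, M2)
    # clamp tiny negatives from cancellation
    pmax(lr, 0)
  })
}

# x * log(x / denom) with 0 log 0 = 0
xlogx <- function(x, denom) ifelse(x == 0, 0, x * log(x / denom))

# accept a table_family, host table data.frame, or list with cell vectors
check_cells <- function(family) {
  need <- c("a1", "a2", "b1", "b2")
  if (!all(need %in% names(family)))
    stop("need columns/fields a1, a2, b1, b2")
  cells <- lapply(family[need], as.numeric)
  if (any(unlist(cells) < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  cells
}

#' Maximum statistic over a family of tables
#'
#' The family maximum of per-table statistics (e.g. the maximal LR across all
#' drugs for one adverse event), used by the Max-Stat step-down procedure.
#'
#' @param statistics numeric vector of per-table statistics.
#' @return the maximum, a length-one numeric.
#' @export
mlr <- function(statistics) {
  if (length(statistics) == 0) stop("empty statistic collection")
  max(statistics)
}

#' Normal-approximation z statistic for the exposed group-1 proportion
#'
#' The binomial z score comparing the group-1 share among exposed reports,
#' \eqn{a_1/n}, with the overall margin proportion \eqn{p = M_1/N}:
#' \deqn{z = \sqrt{n}\,(a_1/n - p) / \sqrt{p(1-p)}.}
#' Signed: positive when group 1 is over-represented among exposed reports.
#'
#' @inheritParams lr_statistic
#' @return numeric vector of signed z scores.
#' @examples
#' z_statistic(data.frame(a1 = 135, a2 = 94, b1 = 47695, b2 = 52984)) # 3.5011
#' @export
z_statistic <- function(family) {
  cells <- check_cells(family)
  with(cells, {
    n <- a1 + a2
    p <- (a1 + b1) / (a1 + a2 + b1 + b2)
    if (any(p <= 0 | p >= 1)) stop("degenerate margin proportion p in (0,1) required")
    if (any(n <= 0)) stop("exposed total must be positive")
    sqrt(n) * (a1 / n - p) / sqrt(p * (1 - p))
  })
}

#' PRR disparity statistic with delta-method z score
#'
#' The proportional reporting ratio between host-factor groups,
#' \deqn{PRR = \frac{a_1/n}{(M_1 - a_1)/(N - n)},}
#' i.e. the group-1 share among exposed reports relative to the group-1 share
#' among unexposed reports, with a delta-method normal approximation for
#' \eqn{\log PRR} under the conditional binomial null. The z score is
#' \eqn{\sqrt{n}(\log PRR - c)/\sigma} with centering
#' \eqn{c = \log\{p / ((M_1 - n p)/(N - M_1))\}} and
#' \eqn{\sigma^2 = p(1-p)\,\{M_1/(p(M_1 - n p))\}^2}, \eqn{p = M_1/N}.
#'
#' Two centerings are available. The default `"consistent"` centering uses
#' denominator \eqn{N - n}, obtained by plugging the null expectation
#' \eqn{a_1 \approx n p} into the PRR itself, and makes the z score
#' approximately standard normal under the null. The `"printed"` variant
#' divides by \eqn{N - M_1} instead, as some published presentations of the
#' approximation do; it carries a centering bias of
#' \eqn{\log\{(N-n)/(N-M_1)\}} and is kept for sensitivity analysis only.
#'
#' @inheritParams lr_statistic
#' @param variant `"consistent"` (default) or `"printed"` centering.
#' @return data frame with columns `estimate` (the PRR) and `z`.
#' @export
prr_statistic <- function(family, variant = c("consistent", "printed")) {
  variant <- match.arg(variant)
  cells <- check_cells(family)
  with(cells, {
    n  <- a1 + a2
    M1 <- a1 + b1
    M2 <- a2 + b2
    N  <- M1 + M2
    if (any(c(a1, a2, b1, b2) == 0))
      stop("PRR requires all four cells > 0 (apply the min-cell filter)")
    p <- M1 / N
    prr <- (a1 / n) / (b1 / (b1 + b2))
    denom <- if (variant == "printed") N - M1 else N - n
    centre <- log(p / ((M1 - n * p) / denom))
    sigma2 <- p * (1 - p) * (M1 / (p * (M1 - n * p)))^2
    z <- sqrt(n) * (log(prr) - centre) / sqrt(sigma2)
    data.frame(estimate = prr, z = z)
  })
}

#' ROR disparity statistic with delta-method z score
#'
#' The reporting odds ratio between host-factor groups,
#' \deqn{ROR = \frac{a_1/a_2}{(M_1 - a_1)/(M_2 - a_2)},}
#' with a delta-method normal approximation for \eqn{\log ROR}:
#' centering \eqn{c = \log\{ (p/(1-p)) / ((M_1/n - p)/(M_2/n - (1-p))) \}} and
#' \deqn{\sigma^2 = p(1-p)\left[\frac{M_1/n}{p(M_1/n - p)}
#'   + \frac{M_2/n}{(1-p)(a_1/n - (1-p))}\right]^2.}
#' The default `"consistent"` variance uses the group-2 margin analogue
#' \eqn{M_2/n - (1-p)} in its second term, which keeps the z score
#' calibrated and exactly antisymmetric under swapping the group labels.
#' The `"printed"` variant substitutes the observed \eqn{a_1/n} for that
#' term, as some published presentations do; its denominator can approach
#' zero for balanced groups, deflating the z score, and it is kept for
#' sensitivity analysis only.
#'
#' @inheritParams prr_statistic
#' @return data frame with columns `estimate` (the ROR) and `z`.
#' @export
ror_statistic <- function(family, variant = c("consistent", "printed")) {
  variant <- match.arg(variant)
  cells <- check_cells(family)
  with(cells, {
    n  <- a1 + a2
    M1 <- a1 + b1
    M2 <- a2 + b2
    N  <- M1 + M2
    if (any(c(a1, a2, b1, b2) == 0))
      stop("ROR requires all four cells > 0 (apply the min-cell filter)")
    p <- M1 / N
    ror <- (a1 / a2) / (b1 / b2)
    centre <- log((p / (1 - p)) / ((M1 / n - p) / (M2 / n - (1 - p))))
    second <- if (variant == "printed") a1 / n - (1 - p) else M2 / n - (1 - p)
    sigma2 <- p * (1 - p) *
      ((M1 / n) / (p * (M1 / n - p)) + (M2 / n) / ((1 - p) * second))^2
    z <- sqrt(n) * (log(ror) - centre) / sqrt(sigma2)
    data.frame(estimate = ror, z = z)
  })
}

#' Two-sided p-value from a standard normal z score
#'
#' @param z numeric vector of (signed) z scores.
#' @return `2 * (1 - pnorm(|z|))`, vectorized.
#' @export
normal_p_two_sided <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(-abs(z))
}
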