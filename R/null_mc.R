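#' Monte-Carlo null samples of the LR statistic and its family maximum
#'
#' Simulates the conditional binomial null for every table in a family:
#' in replicate k the exposed group-1 count of unit j is drawn as
#' `Binomial(n_j, p)` with `n_j = a1_j + a2_j` and `p = M1 / (M1 + M2)` the
#' family's group-1 margin proportion; the LR statistic is recomputed, and
#' the per-replicate maximum over units gives the null distribution of the
#' family maximum (MLR). Draws are independent across units and replicates.
#'
#' Each unit uses its own random substream seeded deterministically from
#' `(seed, unit index)`, so results do not depend on iteration order and are
#' reproducible for a given seed.
#'
#' @param family a [table_family].
#' @param m number of Monte-Carlo replicates (default 1e5).
#' @param seed integer seed.
#' @return object of class `null_samples`: list with `per_unit` (named list
#'   of m sorted LR draws per unit), `mlr_draws` (m sorted draws of the
#'   family maximum), `m`, `seed`, `unit_ids`, `n_exposed`, `p_null`.
#' @seealso [mc_p_value()], [mlr_quantile()], [maxstat_adjust_lrt()]
#' @export
sample_null <- function(family, m = 1e5, seed = 1L) {
  if (m < 1) stop("m must be >= 1")
  if (nrow(family) == 0) stop("empty family")
  m <- as.integer(m)
  p <- family_p_null(family)
  margins <- family_margins(family)
  n_exp <- family$a1 + family$a2
  J <- nrow(family)
  draws <- matrix(0, nrow = m, ncol = J)
  for (j in seq_len(J)) {
    set.seed(substream_seed(seed, unit_hash(family$unit_id[j])))
    a1 <- stats::rbinom(m, n_exp[j], p)
    draws[, j] <- lr_cells(a1, n_exp[j] - a1, margins[1], margins[2])
  }
  mlr_raw <- do.call(pmax, as.data.frame(draws))
  per_unit <- lapply(seq_len(J), function(j) sort(draws[, j]))
  names(per_unit) <- family$unit_id
  structure(list(per_unit = per_unit,
                 mlr_draws = sort(mlr_raw),
                 m = m, seed = seed,
                 unit_ids = family$unit_id,
                 n_exposed = n_exp,
                 p_null = p),
            class = "null_samples")
}

# deterministic 31-bit substream seed from (seed, index); arithmetic kept in
# doubles (exact below 2^53) before reduction
substream_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2^31) * 48271 + index * 16807) %% 2147483647)
}

# rolling hash of a unit id, so substreams follow unit identity rather than
# row position (results invariant to family row order)
unit_hash <- function(id) {
  h <- 0
  for (v in utf8ToInt(as.character(id))) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

# fast LR from exposed cells and fixed margins (vectorized over a1/a2)
lr_cells <- function(a1, a2, M1, M2) {
  n <- a1 + a2
  N <- M1 + M2
  pmax(-xlogx(n, N) + xlogx(a1, M1) + xlogx(a2, M2), 0)
}

#' @export
print.null_samples <- function(x, ...) {
  cat(sprintf("Monte-Carlo LR null: %d units, m = %d, seed = %d\n",
              length(x$per_unit), x$m, x$seed))
  cat(sprintf("p_null = %.4f; MLR 95th percentile = %.4f\n",
              x$p_null, mlr_quantile(x, 0.05)))
  invisible(x)
}

#' Empirical Monte-Carlo p-value
#'
#' Inclusive upper-tail probability: the proportion of null draws greater
#' than or equal to the observed statistic (ties counted in the tail; the
#' simulated LR distribution is discrete, and an exclusive rule inflates the
#' FDR of downstream step-up adjustment). May be exactly 0 when the observed
#' value exceeds every draw; printed output renders such values as
#' `< 1/m` while 0 is stored.
#'
#' @param observed numeric vector of observed statistics.
#' @param draws numeric vector of null draws, sorted ascending.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
mc_p_value <- function(observed, draws) {
  if (length(draws) == 0) stop("empty draws")
  m <- length(draws)
  # number of draws < observed, via sorted lookup; p = #(draws >= obs) / m
  below <- findInterval(observed, draws, left.open = TRUE)
  (m - below) / m
}

#' Empirical quantile of the family-maximum null
#'
#' The (1 - alpha) quantile of the Monte-Carlo MLR draws, taken as the
#' `ceiling((1 - alpha) * m)`-th order statistic. With this convention the
#' step-down rejection rule `LR > quantile` is exactly equivalent to the
#' Monte-Carlo adjusted p-value ([mc_p_value()] against the MLR draws) being
#' at most alpha.
#'
#' @param samples a [sample_null()] result.
#' @param alpha significance level in (0, 1).
#' @return the empirical critical value.
#' @export
mlr_quantile <- function(samples, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  draws <- samples$mlr_draws
  draws[ceiling((1 - alpha) * length(draws))]
}
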