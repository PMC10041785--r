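#' Generate a synthetic base of table families
#'
#' Emulates the marginal structure of a processed spontaneous-reporting
#' database so that the simulation harness can run without access to raw
#' FAERS extracts: per synthetic adverse event it draws a total report count,
#' a group-1 proportion, a drug count and per-drug exposed totals, splits
#' groups binomially, and keeps only families passing the standard filters
#' (min-cell, more-than-`min_units` drugs, exposed totals within both group
#' margins). Totals follow a log-normal whose 25%/50% quantiles sit at the
#' reference strata cutpoints 674/1337; the group-1 proportion is a Beta
#' centered near the FAERS male share.
#'
#' @param n_aes number of families to produce.
#' @param seed integer seed; output is byte-identical for a given seed.
#' @param total_dist,drugs_dist,prop_dist generator functions of `n` for the
#'   AE total count, the drug count, and the group-1 proportion.
#' @param exposed_share fraction of an AE's reports allocated to its drugs.
#' @param min_exposed floor on per-drug exposed totals before filtering.
#' @param min_cell,min_units filter thresholds, as in [filter_min_cell()]
#'   and [filter_min_units()].
#' @param max_tries attempts allowed before declaring the parameters
#'   infeasible.
#' @return list of [table_family] objects, each with attribute `"n_total"`
#'   (the AE total used for stratum classification).
#' @export
generate_synthetic_base <- function(n_aes = 100, seed = 1L,
                                    total_dist = function(n)
                                      stats::rlnorm(n, log(1337), 1.016),
                                    drugs_dist = function(n)
                                      6 + stats::rpois(n, 6),
                                    prop_dist = function(n)
                                      stats::rbeta(n, 15, 17),
                                    exposed_share = 0.5,
                                    min_exposed = 15,
                                    min_cell = 5, min_units = 5,
                                    max_tries = 200 * n_aes) {
  set.seed(seed)
  out <- vector("list", n_aes)
  got <- 0L
  tries <- 0L
  while (got < n_aes) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("synthetic base generation infeasible under these distributions")
    n_tot <- max(60, round(total_dist(1)))
    J <- max(2, round(drugs_dist(1)))
    p <- min(0.9, max(0.1, prop_dist(1)))
    w <- stats::rgamma(J, shape = 1)
    n_exp <- pmax(round(w / sum(w) * exposed_share * n_tot), min_exposed)
    if (sum(n_exp) > 0.8 * n_tot) next
    a1 <- stats::rbinom(J, n_exp, p)
    rest <- n_tot - sum(n_exp)
    rest1 <- stats::rbinom(1, rest, p)
    M1 <- sum(a1) + rest1
    M2 <- n_tot - M1
    fam <- table_family(data.frame(unit_id = sprintf("drug%02d", seq_len(J)),
                                   a1 = a1, a2 = n_exp - a1,
                                   b1 = M1 - a1, b2 = M2 - (n_exp - a1),
                                   stringsAsFactors = FALSE),
                        orientation = "by_drug",
                        context_id = sprintf("synthAE%04d", got + 1L),
                        group_labels = c("group1", "group2"))
    fam <- filter_min_cell(fam, min_cell)
    if (nrow(fam) <= min_units) next
    if (length(filter_exposed_exceeds_margin(fam)) == 0) next
    attr(fam, "n_total") <- n_tot
    got <- got + 1L
    out[[got]] <- fam
  }
  out
}

#' Disparity-shifted group proportion under the alternative
#'
#' Moves the null group-1 proportion toward balance by the disparity
#' magnitude delta: `p + delta` when `p <= 0.5`, `p - delta` when `p > 0.5`
#' (the indicator is strict, so `p = 0.5` shifts upward). Results outside
#' (0, 1) are clipped to `[0.001, 0.999]` with a warning.
#'
#' @param p_i null group-1 proportion, in (0, 1).
#' @param delta disparity magnitude, typically in `[0, 0.5]`.
#' @return the alternative proportion.
#' @export
alternative_proportion <- function(p_i, delta) {
  stopifnot(all(p_i > 0), all(p_i < 1), all(delta >= 0))
  out <- ifelse(p_i > 0.5, p_i - delta, p_i + delta)
  if (any(out <= 0 | out >= 1)) {
    warning("alternative proportion clipped to [0.001, 0.999]")
    out <- pmin(pmax(out, 0.001), 0.999)
  }
  out
}

# round to nearest whole number, halves away from zero (x >= 0)
round_half_away <- function(x) floor(x + 0.5)

#' Simulate one family under a mixed null/alternative scenario
#'
#' Selects `round(J * alt_fraction)` units (half-cases rounded away from
#' zero) uniformly without replacement to follow the alternative proportion
#' of [alternative_proportion()]; all other units follow the null. Exposed
#' group counts are redrawn binomially with margins held fixed.
#' With `delta = 0` no unit is labelled alternative and every draw is a null
#' draw.
#'
#' @param family a [table_family].
#' @param delta disparity magnitude.
#' @param alt_fraction fraction of units assigned to the alternative
#'   (default 1/5).
#' @param seed optional integer seed.
#' @return list with `family` (the simulated [table_family]) and `alt`
#'   (logical truth labels per unit).
#' @export
simulate_family <- function(family, delta, alt_fraction = 0.2, seed = NULL) {
  if (nrow(family) == 0) stop("empty family")
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(family)
  p <- family_p_null(family)
  margins <- family_margins(family)
  n <- family$a1 + family$a2
  alt <- rep(FALSE, J)
  if (delta > 0) {
    m_k <- round_half_away(J * alt_fraction)
    if (m_k > 0) alt[sample.int(J, m_k)] <- TRUE
  }
  p_unit <- ifelse(alt, alternative_proportion(p, delta), p)
  a1 <- stats::rbinom(J, n, p_unit)
  fam <- new_family_like(family,
                         data.frame(unit_id = family$unit_id,
                                    a1 = a1, a2 = n - a1,
                                    b1 = margins[1] - a1,
                                    b2 = margins[2] - (n - a1),
                                    stringsAsFactors = FALSE))
  list(family = fam, alt = alt)
}

#' Empirical family-wise error rate
#'
#' Proportion of simulation runs (all under the global null) with at least
#' one rejected null hypothesis.
#'
#' @param indicators logical/0-1 vector, one per run.
#' @return the mean indicator.
#' @export
fwer_estimate <- function(indicators) {
  indicators <- as.numeric(indicators)
  if (any(!indicators %in% c(0, 1))) stop("indicators must be 0/1")
  mean(indicators)
}

#' Empirical false discovery rate
#'
#' Mean over runs of (false rejections / total rejections), with the
#' convention 0/0 = 0 for runs rejecting nothing.
#'
#' @param false_rejections,total_rejections integer vectors, one per run.
#' @return the empirical FDR.
#' @export
fdr_estimate <- function(false_rejections, total_rejections) {
  if (any(false_rejections > total_rejections))
    stop("false rejections cannot exceed total rejections")
  ratio <- ifelse(total_rejections == 0, 0,
                  false_rejections / total_rejections)
  mean(ratio)
}

#' Empirical sensitivity
#'
#' Mean over runs of (correct rejections / true alternative hypotheses).
#' Every contributing run must carry at least one true alternative; runs
#' without alternatives belong to FWER accounting instead.
#'
#' @param correct_rejections,alternatives integer vectors, one per run.
#' @return the empirical sensitivity.
#' @export
sensitivity_estimate <- function(correct_rejections, alternatives) {
  if (any(alternatives == 0))
    stop("sensitivity is undefined for runs without true alternatives")
  if (any(correct_rejections > alternatives))
    stop("correct rejections cannot exceed the number of alternatives")
  mean(correct_rejections / alternatives)
}

# vectorized per-family simulation block: returns, for each
# method x adjustment, iteration-level rejection counts
sim_family_block <- function(family, delta, alt_fraction, iterations, alpha,
                             methods, adjustments, m_null, seed,
                             variant = "consistent") {
  J <- nrow(family)
  p <- family_p_null(family)
  margins <- family_margins(family)
  M1 <- unname(margins[1]); M2 <- unname(margins[2]); N <- M1 + M2
  n <- family$a1 + family$a2

  null <- if ("lrt" %in% methods)
    sample_null(family, m = m_null, seed = substream_seed(seed, 777L))
  else NULL

  set.seed(substream_seed(seed, 1L))
  alt <- rep(FALSE, J)
  if (delta > 0) {
    m_k <- round_half_away(J * alt_fraction)
    if (m_k > 0) alt[sample.int(J, m_k)] <- TRUE
  }
  p_unit <- ifelse(alt, alternative_proportion(p, delta), p)
  A1 <- matrix(stats::rbinom(J * iterations, n, p_unit), nrow = J)
  A2 <- n - A1
  B1 <- M1 - A1
  B2 <- M2 - A2

  # per-unit constants for the delta-method tests
  prr_denom <- if (variant == "printed") N - M1 else N - n
  prr_c <- log(p / ((M1 - n * p) / prr_denom))
  prr_s <- sqrt(p * (1 - p)) * (M1 / (p * (M1 - n * p)))
  ror_c <- log((p / (1 - p)) / ((M1 / n - p) / (M2 / n - (1 - p))))

  zmat <- function(method) {
    switch(method,
      normal = sqrt(n) * (A1 / n - p) / sqrt(p * (1 - p)),
      prr = {
        lprr <- log((A1 / n) / (B1 / (B1 + B2)))
        sqrt(n) * (lprr - prr_c) / prr_s
      },
      ror = {
        lror <- log((A1 / A2) / (B1 / B2))
        second <- if (variant == "printed") A1 / n - (1 - p) else M2 / n - (1 - p)
        sig <- sqrt(p * (1 - p)) *
          abs((M1 / n) / (p * (M1 / n - p)) + (M2 / n) / ((1 - p) * second))
        sqrt(n) * (lror - ror_c) / sig
      })
  }

  out <- list()
  for (method in methods) {
    if (method == "lrt") {
      stat <- lr_cells(A1, A2, M1, M2)
      if ("bh" %in% adjustments) {
        praw <- matrix(0, J, iterations)
        for (j in seq_len(J)) {
          below <- findInterval(stat[j, ], null$per_unit[[j]], left.open = TRUE)
          praw[j, ] <- (m_null - below) / m_null
        }
      }
    } else {
      Z <- zmat(method)
      praw <- 2 * stats::pnorm(-abs(Z))
      praw[!is.finite(Z)] <- 0  # degenerate simulated cells: extreme evidence
    }
    for (adjustment in adjustments) {
      rej <- if (adjustment == "maxstat") {
        if (method == "lrt") {
          stat > mlr_quantile(null, alpha)
        } else {
          crit <- stats::qnorm((1 - alpha / 2)^(1 / J))
          abs(Z) > crit | !is.finite(Z)
        }
      } else {
        apply(praw, 2, function(pc) stats::p.adjust(pc, "BH") <= alpha)
      }
      rej <- matrix(rej, nrow = J)
      out[[paste(method, adjustment, sep = ".")]] <-
        data.frame(false = colSums(rej & !alt),
                   correct = colSums(rej & alt),
                   total = colSums(rej),
                   alts = sum(alt))
    }
  }
  out
}

#' Run the empirical FWER / FDR / sensitivity simulation study
#'
#' For each base family (optionally resampled per size stratum), redraws the
#' exposed counts `iterations_per_ae` times under the scenario of
#' [simulate_family()], applies every requested method and multiplicity
#' adjustment at level alpha, and accumulates the empirical error-rate
#' estimators. With `delta = 0` all hypotheses are null and the empirical
#' FWER is reported; with `delta > 0` FDR and sensitivity are reported.
#'
#' Strata are defined by AE total report counts: cutpoints default to the
#' 25% and 50% quantiles of the base totals (pass
#' `strata_cutpoints = c(674, 1337)` for the fixed reference values), giving
#' "small", "moderate" and "large" size classes.
#'
#' @param base list of [table_family] objects (e.g. from
#'   [generate_synthetic_base()]).
#' @param delta disparity magnitude under the alternative.
#' @param alt_fraction fraction of units per family assigned to the
#'   alternative.
#' @param iterations_per_ae simulation replicates per family.
#' @param aes_per_stratum if given, families are sampled (with replacement
#'   when needed) per stratum to this count; otherwise every base family is
#'   used once.
#' @param strata_cutpoints two increasing totals; `NULL` recomputes the
#'   25%/50% quantiles from the base.
#' @param alpha significance level.
#' @param methods subset of `c("lrt", "normal", "prr", "ror")`.
#' @param adjustments subset of `c("maxstat", "bh")`.
#' @param m_null Monte-Carlo replicates for each family's LR null.
#' @param seed integer master seed.
#' @param variant PRR/ROR formula variant.
#' @return data frame of class `sim_outcome`: one row per
#'   method x adjustment x stratum (plus a pooled `"all"` stratum) with
#'   columns `fwer` (NA unless `delta = 0`), `fdr`, `sensitivity`
#'   (NA when no alternatives), `n_runs`, `delta`, `alpha`.
#' @export
run_simulation <- function(base, delta = 0, alt_fraction = 0.2,
                           iterations_per_ae = 2000, aes_per_stratum = NULL,
                           strata_cutpoints = NULL, alpha = 0.05,
                           methods = c("lrt", "normal", "prr", "ror"),
                           adjustments = c("maxstat", "bh"),
                           m_null = 5000, seed = 1L,
                           variant = c("consistent", "printed")) {
  variant <- match.arg(variant)
  methods <- match.arg(methods, several.ok = TRUE)
  adjustments <- match.arg(adjustments, several.ok = TRUE)
  base <- filter_exposed_exceeds_margin(base)
  if (length(base) == 0) stop("empty base after filtering")

  totals <- vapply(base, function(f) {
    nt <- attr(f, "n_total")
    if (is.null(nt)) sum(family_margins(f)) else nt
  }, 0)
  if (is.null(strata_cutpoints))
    strata_cutpoints <- unname(stats::quantile(totals, c(0.25, 0.5)))
  stopifnot(length(strata_cutpoints) == 2, diff(strata_cutpoints) >= 0)
  stratum <- cut(totals, c(-Inf, strata_cutpoints, Inf),
                 labels = c("small", "moderate", "large"))

  if (!is.null(aes_per_stratum)) {
    set.seed(substream_seed(seed, 999L))
    idx <- unlist(lapply(levels(stratum), function(s) {
      pool <- which(stratum == s)
      if (length(pool) == 0) return(integer())
      sample(pool, aes_per_stratum, replace = length(pool) < aes_per_stratum)
    }))
  } else idx <- seq_along(base)

  rows <- list()
  for (k in seq_along(idx)) {
    fam <- base[[idx[k]]]
    blk <- sim_family_block(fam, delta, alt_fraction, iterations_per_ae,
                            alpha, methods, adjustments, m_null,
                            seed = substream_seed(seed, k), variant = variant)
    for (key in names(blk)) {
      blk[[key]]$stratum <- as.character(stratum[idx[k]])
      blk[[key]]$key <- key
      rows[[length(rows) + 1L]] <- blk[[key]]
    }
  }
  runs <- do.call(rbind, rows)

  summarize <- function(df) {
    data.frame(
      fwer = if (delta == 0) fwer_estimate(df$total > 0) else NA_real_,
      fdr = fdr_estimate(df$false, df$total),
      sensitivity = if (any(df$alts > 0))
        sensitivity_estimate(df$correct[df$alts > 0], df$alts[df$alts > 0])
      else NA_real_,
      n_runs = nrow(df))
  }
  grid <- expand.grid(key = unique(runs$key),
                      stratum = c(levels(stratum), "all"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    df <- runs[runs$key == grid$key[i] &
               (grid$stratum[i] == "all" | runs$stratum == grid$stratum[i]), ]
    if (nrow(df) == 0) return(NULL)
    cbind(data.frame(method = sub("\\..*", "", grid$key[i]),
                     adjustment = sub(".*\\.", "", grid$key[i]),
                     stratum = grid$stratum[i], delta = delta,
                     alpha = alpha, stringsAsFactors = FALSE),
          summarize(df))
  }))
  rownames(out) <- NULL
  class(out) <- c("sim_outcome", "data.frame")
  out
}
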