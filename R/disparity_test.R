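#' Test a family of 2x2 host-factor tables for reporting disparities
#'
#' The front door of the package: applies the requested disparity tests to
#' every table of a family and adjusts for multiple testing. The null
#' hypothesis for each table is that the exposed group-1 count follows
#' `Binomial(n, p)` with `p` the family's group-1 margin proportion, i.e.
#' that the host factor does not modify the reporting rate of this unit
#' relative to the family background.
#'
#' Methods: `"lrt"` (likelihood ratio with Monte-Carlo null), `"normal"`
#' (binomial z score), `"prr"` and `"ror"` (delta-method z scores for the
#' log subgroup ratios). Adjustments: `"maxstat"` (step-down family-wise
#' control against the family maximum) or `"bh"` (Benjamini-Hochberg
#' step-up FDR control). For the LRT, raw p-values come from per-unit
#' Monte-Carlo nulls and Max-Stat adjusted p-values from the Monte-Carlo
#' distribution of the family maximum; the z-based tests use closed-form
#' normal machinery throughout.
#'
#' @param family a [table_family].
#' @param methods subset of `c("lrt", "normal", "prr", "ror")`.
#' @param adjust `"maxstat"` or `"bh"`.
#' @param alpha significance level (FWER or FDR target).
#' @param m Monte-Carlo replicates for the LRT null.
#' @param seed seed for the Monte-Carlo null.
#' @param variant PRR/ROR approximation variant, see [prr_statistic()].
#' @param null optional precomputed [sample_null()] result to reuse.
#' @return object of class `disparity_test`: list with `results` (data frame
#'   of unit_id, method, statistic, estimate, p_raw, p_adjusted, rejected),
#'   `family`, `adjustment`, `alpha`, `critical_values`, `null`, `m`, `seed`.
#' @examples
#' fam <- table_family(
#'   data.frame(unit_id = c("d1", "d2"), a1 = c(30, 12), a2 = c(10, 14),
#'              b1 = c(470, 488), b2 = c(490, 486)),
#'   orientation = "by_drug", context_id = "toy_ae")
#' fit <- disparity_test(fam, methods = "normal", adjust = "maxstat")
#' print(fit)
#' @export
disparity_test <- function(family,
                           methods = c("lrt", "normal", "prr", "ror"),
                           adjust = c("maxstat", "bh"),
                           alpha = 0.05, m = 1e5, seed = 1L,
                           variant = c("consistent", "printed"),
                           null = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  adjust <- match.arg(adjust)
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(family) == 0) stop("empty family")
  J <- nrow(family)

  if ("lrt" %in% methods && is.null(null))
    null <- sample_null(family, m = m, seed = seed)

  rows <- list()
  critical <- c()
  for (method in methods) {
    if (method == "lrt") {
      stat <- lr_statistic(family)
      est <- rep(NA_real_, J)
      p_raw <- vapply(seq_len(J), function(j)
        mc_p_value(stat[j], null$per_unit[[j]]), 0)
    } else {
      if (method == "normal") {
        stat <- z_statistic(family)
        est <- rep(NA_real_, J)
      } else {
        sr <- if (method == "prr") prr_statistic(family, variant)
              else ror_statistic(family, variant)
        stat <- sr$z
        est <- sr$estimate
      }
      p_raw <- normal_p_two_sided(stat)
    }
    if (adjust == "maxstat") {
      adj <- if (method == "lrt") {
        maxstat_adjust_lrt(stats::setNames(stat, family$unit_id), null, alpha)
      } else {
        maxstat_adjust_normal(stat, alpha)
      }
      p_adj <- adj$p_adjusted
      rejected <- adj$rejected
      critical[method] <- adj$critical_value
    } else {
      adj <- bh_adjust(p_raw, alpha)
      p_adj <- adj$p_adjusted
      rejected <- adj$rejected
      critical[method] <- NA_real_
    }
    rows[[method]] <- data.frame(unit_id = family$unit_id, method = method,
                                 statistic = stat, estimate = est,
                                 p_raw = p_raw, p_adjusted = p_adj,
                                 rejected = unname(rejected),
                                 stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, family = family, methods = methods,
                 adjustment = adjust, alpha = alpha,
                 critical_values = critical, null = null,
                 m = if (is.null(null)) NA_integer_ else null$m,
                 seed = seed, variant = variant),
            class = "disparity_test")
}

#' @export
print.disparity_test <- function(x, digits = 4, ...) {
  fam <- x$family
  cat(sprintf("Host-factor disparity tests (%s), context '%s'\n",
              attr(fam, "orientation"), attr(fam, "context_id")))
  cat(sprintf("%d tables; groups %s/%s; adjustment: %s at alpha = %g\n",
              nrow(fam), attr(fam, "group_labels")[1],
              attr(fam, "group_labels")[2],
              c(maxstat = "Max-Stat", bh = "Benjamini-Hochberg")[x$adjustment],
              x$alpha))
  df <- x$results
  df$statistic <- round(df$statistic, digits)
  df$estimate <- round(df$estimate, digits)
  floor_p <- if (!is.null(x$null)) 1 / x$null$m else 0
  fmt_p <- function(p, mc) ifelse(mc & p == 0, sprintf("<%g", floor_p),
                                  format(round(p, digits)))
  mc_rows <- df$method == "lrt"
  df$p_raw <- fmt_p(df$p_raw, mc_rows)
  df$p_adjusted <- fmt_p(df$p_adjusted, mc_rows & x$adjustment == "maxstat")
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.disparity_test <- function(object, ...) {
  res <- object$results
  hits <- res[res$rejected, c("unit_id", "method", "statistic", "p_adjusted")]
  structure(list(fit = object, rejected = hits,
                 n_rejected = table(factor(res$method[res$rejected],
                                           levels = object$methods))),
            class = "summary.disparity_test")
}

#' @export
print.summary.disparity_test <- function(x, ...) {
  print(x$fit)
  cat("\nRejections per method:\n")
  print(x$n_rejected)
  invisible(x)
}

#' @export
coef.disparity_test <- function(object, ...) {
  res <- object$results
  out <- do.call(cbind, lapply(split(res$statistic, res$method)[object$methods],
                               identity))
  rownames(out) <- object$family$unit_id
  out
}

#' @export
plot.disparity_test <- function(x, method = x$methods[1], ...) {
  res <- x$results[x$results$method == method, ]
  floor_p <- if (!is.null(x$null)) 1 / x$null$m else .Machine$double.xmin
  logp <- -log10(pmax(res$p_adjusted, floor_p))
  ord <- order(logp)
  graphics::dotchart(logp[ord], labels = res$unit_id[ord],
                     xlab = expression(-log[10] ~ "adjusted p"),
                     main = sprintf("%s, %s adjustment", method, x$adjustment),
                     ...)
  graphics::abline(v = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Simulate null replicates of a table family
#'
#' Draws `nsim` replicate families from the fitted conditional binomial null:
#' each unit's exposed group-1 count is redrawn as `Binomial(n, p)` with the
#' family's margin proportion `p`, margins held fixed.
#'
#' @param object a [table_family].
#' @param nsim number of replicate families.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` [table_family] objects.
#' @export
simulate.table_family <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- family_margins(object)
  p <- family_p_null(object)
  n <- object$a1 + object$a2
  lapply(seq_len(nsim), function(k) {
    a1 <- stats::rbinom(length(n), n, p)
    new_family_like(object,
                    data.frame(unit_id = object$unit_id, a1 = a1, a2 = n - a1,
                               b1 = m[1] - a1, b2 = m[2] - (n - a1),
                               stringsAsFactors = FALSE))
  })
}
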