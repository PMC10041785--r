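test_that("LR statistic reproduces the published analgesic values", {
  fam <- analgesics_family()
  lr <- setNames(lr_statistic(fam), fam$unit_id)
  expect_equal(unname(round(lr["acetaminophen"], 4)), 67.2388)
  expect_equal(unname(round(lr["aspirin"], 4)), 6.1345)
  expect_equal(unname(round(lr["meloxicam"], 4)), 4.3995)
  expect_true(all(lr >= 0))
})

test_that("LR is zero exactly for proportional tables and grows with imbalance", {
  expect_equal(lr_statistic(one_row_family(10, 10, 90, 90)), 0)
  # a1 at the null expectation n*p gives 0; moving away increases LR
  grid <- vapply(2:18, function(a1)
    lr_statistic(one_row_family(a1, 20 - a1, 100 - a1, 100 - (20 - a1))), 0)
  expect_equal(grid[which(2:18 == 10)], 0)
  expect_true(all(diff(grid[2:18 >= 10]) > 0))
  expect_true(all(diff(grid[2:18 <= 10]) < 0))
})

test_that("LR handles zero exposed cells finitely and rejects zero margins", {
  expect_true(is.finite(lr_statistic(one_row_family(0, 10, 50, 40))))
  expect_error(lr_statistic(one_row_family(0, 10, 0, 40)), "margin")
})

test_that("mlr returns the family maximum", {
  expect_equal(mlr(c(67.2388, 6.1345, 4.4538)), 67.2388)
  expect_equal(mlr(5), 5)
  set.seed(3)
  x <- runif(50)
  expect_equal(mlr(x), sort(x, decreasing = TRUE)[1])
  expect_error(mlr(numeric()), "empty")
})

test_that("z statistic reproduces the published analgesic values", {
  fam <- analgesics_family()
  z <- setNames(z_statistic(fam), fam$unit_id)
  expect_equal(unname(round(abs(z["acetaminophen"]), 4)), 11.5059)
  expect_equal(unname(round(z["aspirin"], 4)), 3.5011)
  expect_equal(unname(round(z["meloxicam"], 4)), -2.8949)
})

test_that("z is zero when the exposed proportion equals the margin proportion", {
  expect_equal(z_statistic(one_row_family(10, 10, 90, 90)), 0)
})

test_that("group-label swap leaves LR invariant and flips the z sign", {
  fam <- analgesics_family()
  sw <- swap_groups(fam)
  expect_equal(lr_statistic(sw), lr_statistic(fam))
  expect_equal(z_statistic(sw), -z_statistic(fam))
})

test_that("PRR point estimate and z follow the printed formulas", {
  expect_equal(prr_statistic(one_row_family(10, 10, 90, 90))$estimate, 1)
  fam <- analgesics_family()
  res <- prr_statistic(fam)
  asp <- which(fam$unit_id == "aspirin")
  expect_equal(res$estimate[asp], (135 / 229) / ((47830 - 135) / (100908 - 229)))
  expect_true(is.finite(res$z[asp]))
  expect_equal(sign(res$z), sign(z_statistic(fam)))
  # direct evaluation of the delta-method expressions (consistent centering)
  tab <- one_row_family(40, 60, 960, 940)
  n <- 100; M1 <- 1000; M2 <- 1000; N <- 2000; p <- M1 / N
  prr <- (40 / n) / (960 / (960 + 940))
  centre <- log(p / ((M1 - n * p) / (N - n)))
  sigma2 <- p * (1 - p) * (M1 / (p * (M1 - n * p)))^2
  expect_equal(sigma2, 0.25 * (1000 / 475)^2) # closed form at p = 1/2
  expect_equal(prr_statistic(tab)$z, sqrt(n) * (log(prr) - centre) / sqrt(sigma2))
  # printed centering differs by the documented constant bias
  z_pr <- prr_statistic(tab, variant = "printed")$z
  bias <- sqrt(n) * log((N - n) / (N - M1)) / sqrt(sigma2)
  expect_equal(z_pr - prr_statistic(tab)$z, bias)
})

test_that("ROR point estimate and z follow the printed formulas", {
  expect_equal(ror_statistic(one_row_family(10, 10, 90, 90))$estimate, 1)
  expect_equal(ror_statistic(one_row_family(20, 10, 80, 90))$estimate, 2.25)
  # direct evaluation oracle
  tab <- one_row_family(30, 20, 470, 480)
  n <- 50; M1 <- 500; M2 <- 500; p <- 0.5
  ror <- (30 / 20) / (470 / 480)
  centre <- log((p / (1 - p)) / ((M1 / n - p) / (M2 / n - (1 - p))))
  sigma2 <- p * (1 - p) *
    ((M1 / n) / (p * (M1 / n - p)) + (M2 / n) / ((1 - p) * (M2 / n - (1 - p))))^2
  expect_equal(ror_statistic(tab)$z, sqrt(n) * (log(ror) - centre) / sqrt(sigma2))
})

test_that("label swap inverts subgroup ratios and negates the consistent z", {
  fam <- analgesics_family()
  sw <- swap_groups(fam)
  expect_equal(ror_statistic(sw)$estimate, 1 / ror_statistic(fam)$estimate)
  expect_equal(ror_statistic(sw, "printed")$estimate,
               1 / ror_statistic(fam, "printed")$estimate)
  expect_equal(ror_statistic(sw)$z, -ror_statistic(fam)$z)
})

test_that("subgroup ratios refuse degenerate zero cells", {
  expect_error(prr_statistic(one_row_family(0, 10, 50, 40)), "cell")
  expect_error(ror_statistic(one_row_family(5, 0, 50, 40)), "cell")
})

test_that("two-sided normal p-values match reference quantiles", {
  expect_equal(normal_p_two_sided(0), 1)
  expect_equal(round(normal_p_two_sided(1.959964), 6), 0.05)
  expect_equal(normal_p_two_sided(-2), normal_p_two_sided(2))
  expect_error(normal_p_two_sided(Inf))
})

test_that("2*LR approaches the squared z on large null tables", {
  set.seed(42)
  M1 <- 5e4; M2 <- 5e4; n <- 2000
  a1 <- rbinom(200, n, 0.5)
  fam <- table_family(data.frame(unit_id = sprintf("t%03d", 1:200),
                                 a1 = a1, a2 = n - a1, b1 = M1 - a1,
                                 b2 = M2 - (n - a1)),
                      orientation = "by_drug", context_id = "sim")
  d <- abs(2 * lr_statistic(fam) - z_statistic(fam)^2)
  expect_lt(max(d), 0.05)
})

test_that("two-sided p from z is uniform under the null (KS check)", {
  set.seed(7)
  M1 <- 4e5; M2 <- 4e5; n <- 5000
  a1 <- rbinom(2000, n, 0.5)
  fam <- table_family(data.frame(unit_id = sprintf("t%04d", 1:2000),
                                 a1 = a1, a2 = n - a1, b1 = M1 - a1,
                                 b2 = M2 - (n - a1)),
                      orientation = "by_drug", context_id = "sim")
  p <- normal_p_two_sided(z_statistic(fam))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
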