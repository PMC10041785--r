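# shared fixtures and independent oracles

analgesics_family <- function() {
  read_table_family(system.file("extdata", "analgesics_sex_family.tsv",
                                package = "aedisparity"),
                    group_labels = c("male", "female"))
}

liver_by_ae_tables <- function() {
  utils::read.delim(system.file("extdata", "liver_by_ae_tables.tsv",
                                package = "aedisparity"),
                    stringsAsFactors = FALSE)
}

one_row_family <- function(a1, a2, b1, b2, unit = "u1",
                           orientation = "by_drug") {
  table_family(data.frame(unit_id = unit, a1 = a1, a2 = a2, b1 = b1, b2 = b2),
               orientation = orientation, context_id = "ctx")
}

# random valid family with shared margins (cells comfortably positive)
random_family <- function(seed, J = 6, M1 = 2000, M2 = 2200) {
  set.seed(seed)
  n <- sample(30:120, J, replace = TRUE)
  a1 <- rbinom(J, n, M1 / (M1 + M2))
  a1 <- pmin(pmax(a1, 1), n - 1)
  table_family(data.frame(unit_id = sprintf("d%02d", seq_len(J)),
                          a1 = a1, a2 = n - a1, b1 = M1 - a1,
                          b2 = M2 - (n - a1)),
               orientation = "by_drug", context_id = "rand")
}

# toy report-level TSV written to a temp file; returns the path
toy_reports_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "id\tdrug\trole\tpt\tsex"
  writeLines(c(header, rows), path)
  path
}

# independent brute-force Benjamini-Hochberg step-up rejection set
brute_bh_reject <- function(p, alpha) {
  J <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(J) / J * alpha)
  rejected <- rep(FALSE, J)
  if (length(ok)) rejected[ord[seq_len(max(ok))]] <- TRUE
  rejected
}

# independent LR evaluation (explicit term-by-term arithmetic)
oracle_lr <- function(a1, a2, M1, M2) {
  n <- a1 + a2
  N <- M1 + M2
  term <- function(x, d) if (x == 0) 0 else x * log(x / d)
  -term(n, N) + term(a1, M1) + term(a2, M2)
}

# exact null distribution of LR for one table: enumerate Binomial(n, p)
oracle_lr_null_pmf <- function(n, M1, M2) {
  p <- M1 / (M1 + M2)
  support <- 0:n
  data.frame(a1 = support,
             lr = vapply(support, function(a) oracle_lr(a, n - a, M1, M2), 0),
             prob = dbinom(support, n, p))
}
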