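#' Construct a family of 2x2 host-factor tables
#'
#' A `table_family` holds the J 2x2 host-factor tables that share one context:
#' either all drugs reported with one adverse event (`by_drug`, the
#' drug-stratified orientation) or all adverse events reported with one drug
#' (`by_ae`). Each row is one table with cells `a1`, `a2` (exposed counts in
#' host-factor groups 1 and 2) and `b1`, `b2` (the remaining margin,
#' e.g. reports of the same AE without the drug). Group margins
#' `M1 = a1 + b1` and `M2 = a2 + b2` are constant across the family by
#' construction.
#'
#' @param x data frame with columns `unit_id`, `a1`, `a2`, `b1`, `b2`.
#' @param orientation `"by_drug"` or `"by_ae"`.
#' @param context_id the fixed index: the AE name for `by_drug`, the drug
#'   name for `by_ae`.
#' @param group_labels character pair naming host-factor groups 1 and 2.
#' @return object of class `table_family` (a data frame).
#' @seealso [build_table_family()] to derive a family from a count cube.
#' @export
table_family <- function(x, orientation = c("by_drug", "by_ae"),
                         context_id = "context",
                         group_labels = c("group1", "group2")) {
  orientation <- match.arg(orientation)
  need <- c("unit_id", "a1", "a2", "b1", "b2")
  if (!all(need %in% names(x))) stop("need columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  if (anyDuplicated(x$unit_id)) stop("unit_id values must be distinct")
  if (any(as.matrix(x[c("a1", "a2", "b1", "b2")]) < 0)) stop("negative cell count")
  structure(x,
            orientation  = orientation,
            context_id   = context_id,
            group_labels = group_labels,
            class        = c("table_family", "data.frame"))
}

new_family_like <- function(template, x) {
  table_family(x,
               orientation  = attr(template, "orientation"),
               context_id   = attr(template, "context_id"),
               group_labels = attr(template, "group_labels"))
}

#' @export
print.table_family <- function(x, ...) {
  cat(sprintf("Host-factor table family (%s), context '%s': %d tables\n",
              attr(x, "orientation"), attr(x, "context_id"), nrow(x)))
  cat(sprintf("Groups: %s / %s; margins M1 = %d, M2 = %d\n",
              attr(x, "group_labels")[1], attr(x, "group_labels")[2],
              family_margins(x)[1], family_margins(x)[2]))
  print(as.data.frame(x), ...)
  invisible(x)
}

# (M1, M2) margins, validated to be shared across the family
family_margins <- function(family) {
  M1 <- unique(family$a1 + family$b1)
  M2 <- unique(family$a2 + family$b2)
  if (length(M1) != 1L || length(M2) != 1L)
    stop("tables in a family must share group margins")
  c(M1 = M1, M2 = M2)
}

# group-1 margin proportion p = M1 / N shared by the family
family_p_null <- function(family) {
  m <- family_margins(family)
  unname(m[1] / sum(m))
}

#' Build a table family from a count cube
#'
#' Tabulates the J 2x2 host-factor tables for one context. In the `by_drug`
#' orientation the context is an adverse event i: for each drug j reported
#' with i, `a1`/`a2` are the group-wise report counts of (i, j) and
#' `b1`/`b2` the counts of i with any other drug, so the margins are the
#' AE totals summed over all drugs. In the `by_ae` orientation the context is
#' a drug j and the margins are the drug totals summed over all AEs.
#' Units with zero exposed reports are not emitted (they carry no disparity
#' information and would fall to the min-cell filter regardless).
#'
#' @param cube a [count_cube] (long-format counts per event, drug, group).
#' @param orientation `"by_drug"` or `"by_ae"`.
#' @param context_id the AE (for `by_drug`) or drug (for `by_ae`) to fix.
#' @return a [table_family].
#' @export
build_table_family <- function(cube, orientation = c("by_drug", "by_ae"),
                               context_id) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(cube, "count_cube"))
  labels <- attr(cube, "group_labels")
  fixed  <- if (orientation == "by_drug") "event" else "drug"
  vary   <- if (orientation == "by_drug") "drug" else "event"
  sub <- cube[cube[[fixed]] == context_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("context '", context_id, "' not present in cube")
  g1 <- sub$group == labels[1]
  margin1 <- sum(sub$count[g1])
  margin2 <- sum(sub$count[!g1])
  units <- sort(unique(sub[[vary]]))
  a1 <- vapply(units, function(u) sum(sub$count[g1  & sub[[vary]] == u]), 0)
  a2 <- vapply(units, function(u) sum(sub$count[!g1 & sub[[vary]] == u]), 0)
  keep <- (a1 + a2) > 0
  table_family(data.frame(unit_id = units[keep],
                          a1 = a1[keep], a2 = a2[keep],
                          b1 = margin1 - a1[keep], b2 = margin2 - a2[keep],
                          stringsAsFactors = FALSE),
               orientation = orientation, context_id = context_id,
               group_labels = labels)
}

#' Drop tables with any small cell
#'
#' Removes tables where any of the four 2x2 cells is below `min_cell`
#' (default 5), the standard preprocessing rule guarding the asymptotic
#' approximations. Removed unit ids are recorded in attribute `"removed"`.
#'
#' @param family a [table_family].
#' @param min_cell nonnegative integer threshold; a table is kept only if
#'   every cell is `>= min_cell`.
#' @return the filtered [table_family] (possibly empty).
#' @export
filter_min_cell <- function(family, min_cell = 5) {
  stopifnot(min_cell >= 0)
  keep <- family$a1 >= min_cell & family$a2 >= min_cell &
          family$b1 >= min_cell & family$b2 >= min_cell
  out <- new_family_like(family, as.data.frame(family)[keep, , drop = FALSE])
  attr(out, "removed") <- family$unit_id[!keep]
  out
}

#' Keep families with enough units
#'
#' Restricts a collection of families to those testing more than `min_units`
#' hypotheses (default: strictly more than 5 associated drugs), so that the
#' multiple-testing procedures operate on genuinely multiple tables.
#'
#' @param families list of [table_family] objects.
#' @param min_units families with `J <= min_units` tables are dropped.
#' @return the retained sublist.
#' @export
filter_min_units <- function(families, min_units = 5) {
  stopifnot(min_units >= 1)
  Filter(function(f) nrow(f) > min_units, families)
}

#' Exclude families where an exposed total exceeds a group margin
#'
#' Used when preparing simulation bases: if any table in a family has
#' exposed total `a1 + a2 > min(M1, M2)`, binomial resampling of the exposed
#' counts could exceed a group margin, so the whole family is excluded.
#'
#' @param families list of [table_family] objects (a single family is
#'   accepted and wrapped).
#' @return the retained sublist (or list of length 0/1 for single input).
#' @export
filter_exposed_exceeds_margin <- function(families) {
  if (inherits(families, "table_family")) families <- list(families)
  Filter(function(f) {
    m <- family_margins(f)
    all(f$a1 + f$a2 <= min(m))
  }, families)
}

#' Swap the two host-factor group labels of a family
#'
#' Maps cells (a1, b1) to (a2, b2) and vice versa, reversing the group-label
#' pair. Useful for symmetry checks: LR is invariant, z statistics negate.
#'
#' @param family a [table_family].
#' @return the relabelled [table_family].
#' @export
swap_groups <- function(family) {
  df <- data.frame(unit_id = family$unit_id,
                   a1 = family$a2, a2 = family$a1,
                   b1 = family$b2, b2 = family$b1,
                   stringsAsFactors = FALSE)
  table_family(df,
               orientation  = attr(family, "orientation"),
               context_id   = attr(family, "context_id"),
               group_labels = rev(attr(family, "group_labels")))
}

#' Read / write a table family as TSV
#'
#' Plain-text round trip with columns orientation, context_id, unit_id,
#' a1, a2, b1, b2 (one family per file).
#'
#' @param family a [table_family].
#' @param file path.
#' @param group_labels labels to attach on read.
#' @return `read_table_family` returns a [table_family];
#'   `write_table_family` returns `file` invisibly.
#' @export
write_table_family <- function(family, file) {
  df <- cbind(orientation = attr(family, "orientation"),
              context_id  = attr(family, "context_id"),
              as.data.frame(family))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_table_family
#' @export
read_table_family <- function(file, group_labels = c("group1", "group2")) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  table_family(df,
               orientation  = df$orientation[1],
               context_id   = df$context_id[1],
               group_labels = group_labels)
}
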