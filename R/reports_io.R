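#' Read report-level adverse-event data
#'
#' Reads a delimited file with one row per (report, drug, event) triple and
#' normalizes it into the package's report representation. Drug names and
#' event terms are trimmed, internal whitespace collapsed, and case-folded so
#' that matching is deterministic without external vocabularies. Drug role
#' codes accept FAERS-style abbreviations (`PS`, `SS`, `C`, `I`) as well as
#' spelled-out values. Host-factor values not matching the two declared group
#' labels (e.g. `"UNK"`) are kept as missing, not dropped; exact duplicate
#' (report_id, drug, event_term) triples are collapsed to one record.
#'
#' When the host factor is age, pass the numeric column via
#' `columns["group"]` and set `age_threshold`: ages are dichotomized into
#' "under" vs "at least" the threshold (default 65; the boundary age belongs
#' to the older group) and `group_labels` defaults to
#' `c("under65", "65plus")`.
#'
#' @param file path or connection to a delimited text file.
#' @param columns named character vector mapping the logical fields
#'   `report_id`, `drug`, `role`, `event_term`, `group` to column names in
#'   the file.
#' @param sep field delimiter (default tab; use `"$"` for raw FAERS
#'   quarterly ASCII extracts).
#' @param group_labels the two host-factor levels, in (group 1, group 2)
#'   order; matching is case-insensitive.
#' @param age_threshold if not `NULL`, the group column is numeric age and is
#'   cut at this threshold.
#' @return data frame of class `ae_reports` with columns `report_id`,
#'   `drug`, `role`, `event_term`, `group`, and attribute `group_labels`.
#' @export
read_ae_reports <- function(file,
                            columns = c(report_id = "report_id", drug = "drug",
                                        role = "role", event_term = "event_term",
                                        group = "group"),
                            sep = "\t",
                            group_labels = c("male", "female"),
                            age_threshold = NULL) {
  need <- c("report_id", "drug", "role", "event_term", "group")
  if (!all(need %in% names(columns)))
    stop("columns must map all of: ", paste(need, collapse = ", "))
  raw <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unname(columns[need]), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty report stream")
    return(new_ae_reports(data.frame(report_id = character(), drug = character(),
                                     role = character(), event_term = character(),
                                     group = character(), stringsAsFactors = FALSE),
                          group_labels))
  }
  if (!is.null(age_threshold)) {
    if (identical(group_labels, c("male", "female")))
      group_labels <- c(paste0("under", age_threshold), paste0(age_threshold, "plus"))
    group <- dichotomize_age(suppressWarnings(as.numeric(raw[[columns["group"]]])),
                             threshold = age_threshold, labels = group_labels)
  } else {
    group <- normalize_label(as.character(raw[[columns["group"]]]))
    group <- ifelse(group %in% normalize_label(group_labels),
                    group_labels[match(group, normalize_label(group_labels))],
                    NA_character_)
  }
  df <- data.frame(report_id  = as.character(raw[[columns["report_id"]]]),
                   drug       = normalize_label(raw[[columns["drug"]]]),
                   role       = normalize_role(raw[[columns["role"]]]),
                   event_term = normalize_label(raw[[columns["event_term"]]]),
                   group      = group,
                   stringsAsFactors = FALSE)
  # exact-duplicate removal on the identifying triple (documented
  # simplification of full case de-duplication)
  df <- df[!duplicated(df[c("report_id", "drug", "event_term")]), , drop = FALSE]
  new_ae_reports(df, group_labels)
}

new_ae_reports <- function(df, group_labels) {
  structure(df, group_labels = group_labels,
            class = c("ae_reports", "data.frame"))
}

# trim, collapse internal whitespace, case-fold
normalize_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

normalize_role <- function(x) {
  x <- normalize_label(x)
  map <- c(ps = "primary_suspect", "primary suspect" = "primary_suspect",
           primary_suspect = "primary_suspect",
           ss = "secondary_suspect", "secondary suspect" = "secondary_suspect",
           secondary_suspect = "secondary_suspect",
           c = "concomitant", concomitant = "concomitant",
           i = "interacting", interacting = "interacting")
  out <- unname(map[x])
  out[is.na(out)] <- "other"
  out
}

#' Dichotomize numeric age into two host-factor groups
#'
#' @param age numeric vector of ages.
#' @param threshold cut point (default 65); ages `>= threshold` fall in the
#'   second ("at least") group.
#' @param labels the (under, at-least) pair of labels.
#' @return character vector of group labels, `NA` where age is missing.
#' @export
dichotomize_age <- function(age, threshold = 65,
                            labels = c(paste0("under", threshold),
                                       paste0(threshold, "plus"))) {
  ifelse(is.na(age), NA_character_,
         ifelse(age >= threshold, labels[2], labels[1]))
}

#' Map member Preferred Terms onto a composite event
#'
#' Replaces the event term of every record whose term belongs to the
#' composite definition (e.g. the 53 MedDRA Preferred Terms combined into a
#' single "liver toxicity" event) with the composite name, then collapses
#' records so a report contributing several member terms for the same drug
#' counts once. Matching is case-insensitive after whitespace normalization;
#' the operation is idempotent.
#'
#' @param records an `ae_reports` data frame.
#' @param map list with `event_name` (character) and `member_terms`
#'   (character vector), or the result of [read_composite_map()].
#' @return the mapped `ae_reports`.
#' @export
apply_composite_events <- function(records, map) {
  if (is.null(map$event_name) || length(map$member_terms) == 0)
    stop("composite map needs event_name and non-empty member_terms")
  members <- normalize_label(map$member_terms)
  name <- normalize_label(map$event_name)
  hit <- records$event_term %in% members
  records$event_term[hit] <- name
  records[!duplicated(records[c("report_id", "drug", "event_term")]), ,
          drop = FALSE]
}

#' @rdname apply_composite_events
#' @param file two-column delimited file (event_name, member_term), one
#'   member term per line.
#' @export
read_composite_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("composite map file needs two columns")
  name <- unique(df[[1]])
  if (length(name) != 1) stop("composite map file must define a single event")
  list(event_name = name, member_terms = unique(df[[2]]))
}

#' Preprocess reports into a count cube
#'
#' Applies the standard preprocessing rules: only records whose drug role is
#' in `roles_kept` (default: primary suspect only) are counted, and records
#' with a missing host-factor group are removed. Surviving records are
#' tabulated per (event, drug, group). The number of records each rule
#' removed is recorded in attribute `"removal_log"`.
#'
#' @param records an `ae_reports` data frame.
#' @param roles_kept character vector of drug roles to count.
#' @return object of class `count_cube`: long-format data frame with columns
#'   `event`, `drug`, `group`, `count`, plus attributes `group_labels` and
#'   `removal_log`.
#' @export
preprocess_reports <- function(records, roles_kept = "primary_suspect") {
  labels <- attr(records, "group_labels")
  if (is.null(labels) || length(labels) != 2)
    stop("records must carry two declared group labels")
  n0 <- nrow(records)
  kept <- records[records$role %in% roles_kept, , drop = FALSE]
  n_role <- n0 - nrow(kept)
  kept <- kept[!is.na(kept$group), , drop = FALSE]
  n_missing <- n0 - n_role - nrow(kept)
  if (nrow(kept) == 0)
    stop("no records survive preprocessing; review role/group policy")
  agg <- stats::aggregate(list(count = rep(1L, nrow(kept))),
                          by = list(event = kept$event_term, drug = kept$drug,
                                    group = kept$group),
                          FUN = sum)
  agg <- agg[order(agg$event, agg$drug, agg$group), , drop = FALSE]
  rownames(agg) <- NULL
  count_cube(agg, group_labels = labels,
             removal_log = c(non_primary_role = n_role,
                             missing_group = n_missing))
}

#' Construct a count cube
#'
#' Long-format (event, drug, group) report counts, the tabulated form from
#' which table families are built.
#'
#' @param x data frame with columns `event`, `drug`, `group`, `count`.
#' @param group_labels the ordered (group 1, group 2) label pair.
#' @param removal_log optional named integer vector of preprocessing
#'   removal counts.
#' @return object of class `count_cube`.
#' @export
count_cube <- function(x, group_labels, removal_log = NULL) {
  need <- c("event", "drug", "group", "count")
  if (!all(need %in% names(x))) stop("need columns: ", paste(need, collapse = ", "))
  if (any(x$count < 0)) stop("counts must be >= 0")
  bad <- setdiff(unique(x$group), group_labels)
  if (length(bad)) stop("undeclared group value(s): ", paste(bad, collapse = ", "))
  structure(as.data.frame(x)[need], group_labels = group_labels,
            removal_log = removal_log,
            class = c("count_cube", "data.frame"))
}

#' @export
print.count_cube <- function(x, ...) {
  cat(sprintf("Count cube: %d events x %d drugs, %d reports; groups %s/%s\n",
              length(unique(x$event)), length(unique(x$drug)), sum(x$count),
              attr(x, "group_labels")[1], attr(x, "group_labels")[2]))
  log <- attr(x, "removal_log")
  if (!is.null(log))
    cat("Removed during preprocessing:",
        paste(sprintf("%s = %d", names(log), log), collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Write a count cube as long-format TSV
#'
#' @param cube a [count_cube].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_count_cube <- function(cube, file) {
  utils::write.table(as.data.frame(cube), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
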