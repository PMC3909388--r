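#' Rounded percentage
#'
#' `100 * numerator / denominator`, rounded half-up (not banker's rounding)
#' to the requested number of decimals, as attrition tables conventionally
#' print them.
#'
#' @param numerator,denominator integers; `denominator` must be positive.
#' @param decimals decimal places (default 1).
#' @return a numeric scalar (or vector, recycled over `numerator`).
#' @examples
#' percent(28, 136)  # 20.6
#' percent(41, 177)  # 23.2
#' @export
percent <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("'denominator' must be positive")
  x <- 100 * numerator / denominator
  s <- 10^decimals
  floor(x * s + 0.5 + 1e-9) / s
}

#' Tabulate attrition into a flow table
#'
#' Counts dispositions per label in the fixed reporting order, separating the
#' included/eligible label from the exclusion rows. Row percentages are of
#' the exclusion total; the headline percentage is included over identified.
#'
#' @param dispositions data frame with columns `role` and `label` (one row
#'   per screened candidate), or a bare character vector of labels.
#' @param role `"case"` or `"control"`; when `dispositions` carries a `role`
#'   column it must be homogeneous and equal to this.
#' @return a `flow_table`: list with `role`, `n_identified`, `n_excluded`,
#'   `n_included`, `rows` (tibble `label`, `count`, `percent`),
#'   `headline_percent` (`NA` when nothing was identified) and
#'   `inaccurate_code_percent` (share of exclusions attributed to inaccurate
#'   billing codes).
#' @examples
#' labs <- rep(c("INCLUDED", "NO_STONE"), c(41, 136))
#' tabulate_flow(labs, "case")$headline_percent
#' @export
tabulate_flow <- function(dispositions, role = c("case", "control")) {
  role <- match.arg(role)
  if (is.data.frame(dispositions)) {
    if ("role" %in% names(dispositions) &&
        nrow(dispositions) > 0L &&
        !all(dispositions$role == role)) {
      stop("dispositions mix roles; expected only '", role, "'")
    }
    labels <- dispositions$label
  } else {
    labels <- as.character(dispositions)
  }
  valid <- if (role == "case") case_labels() else control_labels()
  bad <- setdiff(unique(labels), valid)
  if (length(bad) > 0L) {
    stop("invalid ", role, " label(s): ", paste(bad, collapse = ", "))
  }
  included_label <- if (role == "case") "INCLUDED" else "ELIGIBLE"
  row_order <- if (role == "case") case_exclusion_order() else control_exclusion_order()

  n_identified <- length(labels)
  n_included <- sum(labels == included_label)
  n_excluded <- n_identified - n_included
  counts <- as.integer(table(factor(labels, levels = row_order)))
  rows <- tibble::tibble(
    label = row_order,
    count = counts,
    percent = if (n_excluded > 0L) percent(counts, n_excluded) else rep(NA_real_, length(counts)))
  inac <- sum(counts[row_order %in% inaccurate_code_labels()])
  structure(
    list(role = role,
         n_identified = n_identified,
         n_excluded = n_excluded,
         n_included = n_included,
         rows = rows,
         headline_percent = if (n_identified > 0L) percent(n_included, n_identified) else NA_real_,
         inaccurate_code_percent = if (n_excluded > 0L) percent(inac, n_excluded) else NA_real_),
    class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat(render_flow(stats::setNames(list(x), x$role)), sep = "\n")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", format(x, nsmall = 1, trim = TRUE))
}

#' Render flow tables as an aligned text report
#'
#' Produces the side-by-side cases/controls exclusion table (`NA` for rows
#' that do not apply to controls) followed by a linear flow summary for each
#' role. Rendering is deterministic given the tables.
#'
#' @param tables named list of [tabulate_flow()] outputs; names among
#'   `"case"`, `"control"`.
#' @return character vector of report lines.
#' @export
render_flow <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L)
  case_t <- tables[["case"]]
  ctrl_t <- tables[["control"]]
  row_labels <- c(NO_STONE = "No kidney stone",
                  NO_GTUBE = "No G-tube",
                  AGE_RANGE = "Outside of study age range",
                  STUDY_PERIOD = "Outside of study time period",
                  ASYNCHRONOUS = "Kidney stone/G-tube asynchronous",
                  INADEQUATE_DATA = "Inadequate clinical data",
                  NO_CONTROL = "No matching control")
  cell <- function(tab, lab) {
    if (is.null(tab)) return("NA")
    i <- match(lab, tab$rows$label)
    if (is.na(i)) return("NA")
    sprintf("%d (%s)", tab$rows$count[i], fmt_num(tab$rows$percent[i]))
  }
  head_n <- function(tab) if (is.null(tab)) "NA" else as.character(tab$n_excluded)
  lines <- c(
    sprintf("%-34s  %-24s  %s", "Reason for exclusion",
            paste0("Excluded cases (N=", head_n(case_t), ")"),
            paste0("Excluded controls (N=", head_n(ctrl_t), ")")),
    vapply(names(row_labels), function(lab) {
      sprintf("%-34s  %-24s  %s", row_labels[[lab]],
              cell(case_t, lab), cell(ctrl_t, lab))
    }, character(1)))
  for (tab in tables) {
    lines <- c(lines, "",
               sprintf("%s flow: identified %d -> excluded %d -> included %d (%s%%); inaccurate-code exclusions %s%%",
                       tab$role, tab$n_identified, tab$n_excluded,
                       tab$n_included, fmt_num(tab$headline_percent),
                       fmt_num(tab$inaccurate_code_percent)))
  }
  unname(lines)
}

#' Write / read a flow table as TSV
#'
#' The TSV holds one row per disposition label plus summary pseudo-rows
#' prefixed with `.` (identified/excluded/included totals), so a table can be
#' reconstructed exactly from its file.
#'
#' @param table a `flow_table`.
#' @param path output file.
#' @return `write_flow_table()` returns `path` invisibly;
#'   `read_flow_table()` returns the reconstructed `flow_table`.
#' @export
write_flow_table <- function(table, path) {
  stopifnot(inherits(table, "flow_table"))
  out <- tibble::tibble(
    role = table$role,
    label = c(".identified", ".excluded", ".included", table$rows$label),
    count = c(table$n_identified, table$n_excluded, table$n_included,
              table$rows$count))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_flow_table
#' @export
read_flow_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  role <- tab$role[1]
  rows <- tab[!startsWith(tab$label, "."), ]
  labels <- rep(rows$label, rows$count)
  included_label <- if (role == "case") "INCLUDED" else "ELIGIBLE"
  n_inc <- tab$count[tab$label == ".included"]
  tabulate_flow(c(labels, rep(included_label, n_inc)), role)
}
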