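#' Eligibility criteria
#'
#' The clinical criteria applied by simulated chart review: an incident stone
#' diagnosis inside the study period, patient age 1-21 (completed years,
#' inclusive) at diagnosis, and tube feeds in at least 3 of the 12 calendar
#' months ending at the index date. Shared between the generator and the
#' screening functions so both operate under identical definitions.
#'
#' @param study_period length-2 `Date` vector, inclusive at both ends.
#' @param age_range_years length-2 integer vector, inclusive completed years.
#' @param feed_rule list with `min_months` and `window_months`.
#' @return an `eligibility_criteria` object.
#' @export
eligibility_criteria <- function(study_period = as.Date(c("2005-01-01", "2011-12-31")),
                                 age_range_years = c(1L, 21L),
                                 feed_rule = list(min_months = 3L, window_months = 12L)) {
  study_period <- as.Date(study_period)
  stopifnot(length(study_period) == 2L, study_period[1] <= study_period[2],
            length(age_range_years) == 2L,
            age_range_years[1] <= age_range_years[2],
            feed_rule$min_months >= 0L,
            feed_rule$min_months <= feed_rule$window_months)
  structure(list(study_period = study_period,
                 age_range_years = as.integer(age_range_years),
                 feed_rule = feed_rule),
            class = "eligibility_criteria")
}

#' Age in completed years
#'
#' Birthday-based floor: the number of whole years elapsed between `dob` and
#' `on`. A February 29 birthday is treated as attained on March 1 in common
#' years.
#'
#' @param dob,on `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @examples
#' age_at(as.Date("2000-06-15"), as.Date("2021-06-14")) # 20
#' age_at(as.Date("2000-06-15"), as.Date("2021-06-15")) # 21
#' @export
age_at <- function(dob, on) {
  dob <- as.Date(dob)
  on <- as.Date(on)
  n <- max(length(dob), length(on))
  dob <- rep_len(dob, n)
  on <- rep_len(on, n)
  if (any(on < dob, na.rm = TRUE)) stop("'on' precedes 'dob'")
  ldob <- as.POSIXlt(dob)
  lon <- as.POSIXlt(on)
  years <- lon$year - ldob$year
  not_yet <- (lon$mon < ldob$mon) |
    (lon$mon == ldob$mon & lon$mday < ldob$mday)
  as.integer(years - not_yet)
}

#' Count feed months inside the look-back window
#'
#' Counts the distinct tube-feed months that fall inside the `window_months`
#' calendar months ending at (and including the month of) `index_date`.
#'
#' @param feed_months character vector of `"YYYY-MM"` tokens, or a list of
#'   such vectors (one element per patient).
#' @param index_date `Date` (scalar, or one per list element).
#' @param rule list with `min_months`, `window_months`; only `window_months`
#'   is used here.
#' @return integer count(s) of distinct feed months inside the window.
#' @examples
#' feed_months_in_window(c("2009-07", "2009-08", "2009-09"),
#'                       as.Date("2010-06-15")) # 3
#' @export
feed_months_in_window <- function(feed_months, index_date,
                                  rule = list(min_months = 3L, window_months = 12L)) {
  w <- as.integer(rule$window_months)
  if (!is.list(feed_months)) {
    idx <- as.Date(index_date)
    if (is.na(idx)) return(NA_integer_)
    if (length(feed_months) == 0L) return(0L)
    m <- unique(ym_parse(feed_months))
    end <- ym_index(idx)
    return(sum(m > end - w & m <= end))
  }
  ng <- length(feed_months)
  index_date <- rep_len(as.Date(index_date), ng)
  lens <- lengths(feed_months)
  out <- integer(ng)
  out[is.na(index_date)] <- NA_integer_
  if (sum(lens) == 0L) return(out)
  m <- ym_parse(unlist(feed_months, use.names = FALSE))
  grp <- rep.int(seq_len(ng), lens)
  end <- ym_index(index_date)[grp]
  # distinct months per patient inside the window
  keep <- !is.na(end) & m > end - w & m <= end &
    !duplicated(as.numeric(grp) * 1e6 + m)
  hit <- tabulate(grp[keep], nbins = ng)
  out[!is.na(index_date)] <- hit[!is.na(index_date)]
  out
}

#' Screen potential cases against the clinical criteria
#'
#' The in-silico analogue of manual chart review for candidates returned by
#' the case phenotype query. Rules are applied in a fixed precedence order and
#' the first failing rule names the disposition, so every record receives
#' exactly one label:
#'
#' 1. `NO_STONE` - the kidney stone cannot be verified in the chart;
#' 2. `NO_GTUBE` - the G-tube cannot be verified;
#' 3. `STUDY_PERIOD` - the incident stone diagnosis falls outside the study
#'    period;
#' 4. `AGE_RANGE` - age at diagnosis outside the permitted range;
#' 5. `ASYNCHRONOUS` - the stone history predates G-tube placement, or tube
#'    feeds cover fewer than `min_months` of the look-back window;
#' 6. `INADEQUATE_DATA` - nutrition documentation insufficient;
#' 7. otherwise `INCLUDED`.
#'
#' The source study reports mutually exclusive exclusion counts without
#' stating an order; the order above follows the listing order of its
#' criteria and can be overridden via `precedence`.
#'
#' @param records data frame with one row per patient and columns `dob`,
#'   `has_true_stone`, `stone_dx_date`, `has_true_gtube`,
#'   `gtube_placement_date`, `feed_months` (list column of `"YYYY-MM"`
#'   tokens), `nutrition_data_adequate`.
#' @param criteria an [eligibility_criteria].
#' @param precedence character vector ordering the six exclusion rules.
#' @return character vector of case disposition labels, one per row.
#' @export
assess_case <- function(records, criteria = eligibility_criteria(),
                        precedence = c("NO_STONE", "NO_GTUBE", "STUDY_PERIOD",
                                       "AGE_RANGE", "ASYNCHRONOUS",
                                       "INADEQUATE_DATA")) {
  stopifnot(inherits(criteria, "eligibility_criteria"),
            setequal(precedence, c("NO_STONE", "NO_GTUBE", "STUDY_PERIOD",
                                   "AGE_RANGE", "ASYNCHRONOUS", "INADEQUATE_DATA")))
  records <- validate_truth(records)
  n <- nrow(records)
  if (n == 0L) return(character(0))

  fails <- list(
    NO_STONE = !records$has_true_stone,
    NO_GTUBE = !records$has_true_gtube,
    STUDY_PERIOD = !is.na(records$stone_dx_date) &
      (records$stone_dx_date < criteria$study_period[1] |
         records$stone_dx_date > criteria$study_period[2]),
    AGE_RANGE = NA, # computed lazily below
    ASYNCHRONOUS = NA,
    INADEQUATE_DATA = !records$nutrition_data_adequate
  )

  label <- rep(NA_character_, n)
  for (rule in precedence) {
    open <- is.na(label)
    if (!any(open)) break
    f <- switch(
      rule,
      AGE_RANGE = {
        ok <- !is.na(records$stone_dx_date)
        age <- rep(NA_integer_, n)
        age[ok] <- age_at(records$dob[ok], records$stone_dx_date[ok])
        !is.na(age) & (age < criteria$age_range_years[1] |
                         age > criteria$age_range_years[2])
      },
      ASYNCHRONOUS = {
        predates <- !is.na(records$stone_dx_date) &
          !is.na(records$gtube_placement_date) &
          records$stone_dx_date < records$gtube_placement_date
        fed <- feed_months_in_window(records$feed_months,
                                     records$stone_dx_date,
                                     criteria$feed_rule)
        predates | (!is.na(fed) & fed < criteria$feed_rule$min_months)
      },
      fails[[rule]]
    )
    label[open & f] <- rule
  }
  label[is.na(label)] <- "INCLUDED"
  label
}

#' Screen control candidates against a case's index date
#'
#' Controls inherit their temporal anchor from the matched case: eligibility
#' requires a G-tube in place before the case's stone-diagnosis date and tube
#' feeds in at least `min_months` of the window ending at that date. Age and
#' study-period rules do not apply to controls. Precedence: `NO_GTUBE`, then
#' `ASYNCHRONOUS`, then `INADEQUATE_DATA`, else `ELIGIBLE`.
#'
#' @inheritParams assess_case
#' @param case_index_date the matched case's stone-diagnosis date (scalar or
#'   one per row).
#' @return character vector of control disposition labels, one per row.
#' @export
assess_control <- function(records, criteria = eligibility_criteria(),
                           case_index_date = NULL) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  if (is.null(case_index_date) || all(is.na(case_index_date))) {
    stop("control screening requires the matched case's index date")
  }
  records <- validate_truth(records, role = "control")
  n <- nrow(records)
  if (n == 0L) return(character(0))
  idx <- rep_len(as.Date(case_index_date), n)

  label <- rep(NA_character_, n)
  label[!records$has_true_gtube] <- "NO_GTUBE"

  open <- is.na(label)
  not_in_place <- is.na(records$gtube_placement_date) |
    records$gtube_placement_date >= idx
  fed <- feed_months_in_window(records$feed_months, idx, criteria$feed_rule)
  label[open & (not_in_place | fed < criteria$feed_rule$min_months)] <- "ASYNCHRONOUS"

  open <- is.na(label)
  label[open & !records$nutrition_data_adequate] <- "INADEQUATE_DATA"
  label[is.na(label)] <- "ELIGIBLE"
  label
}

# contract checks for the truth layer
validate_truth <- function(records, role = "case") {
  needed <- c("dob", "has_true_stone", "stone_dx_date", "has_true_gtube",
              "gtube_placement_date", "feed_months", "nutrition_data_adequate")
  if (role == "control") needed <- setdiff(needed, c("has_true_stone", "stone_dx_date"))
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("truth table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (role == "case") {
    bad <- xor(records$has_true_stone, !is.na(records$stone_dx_date))
    if (any(bad)) stop("stone_dx_date must be present iff has_true_stone (row ",
                       which(bad)[1], ")")
  }
  bad <- xor(records$has_true_gtube, !is.na(records$gtube_placement_date))
  if (any(bad)) stop("gtube_placement_date must be present iff has_true_gtube (row ",
                     which(bad)[1], ")")
  if (!is.list(records$feed_months)) {
    records$feed_months <- lapply(as.character(records$feed_months), parse_feed_field)
  }
  records
}

# "2009-07,2009-08" -> c("2009-07", "2009-08"); empty/NA -> character(0)
parse_feed_field <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ",", fixed = TRUE)[[1]]
}
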