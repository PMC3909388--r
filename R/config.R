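#' Generator configuration
#'
#' Bundles every numeric condition of the study design: cohort sizes,
#' screening-disposition probabilities, the study period and age range, the
#' tube-feed exposure rule, and the matching parameters. Defaults are
#' calibrated to the observed disposition proportions of the source study's
#' attrition table (177 potential cases resolving as 41 included / 28 / 3 /
#' 42 / 35 / 14 / 13 / 1 across the exclusion categories; a 16.5% per-review
#' control eligibility rate with ineligible reviews split 31:82:293).
#'
#' @param n_potential_cases number of patients returned by the case phenotype
#'   query (default 177).
#' @param case_disposition_probs named probability vector over the eight case
#'   disposition labels ([case_labels()]); must sum to 1.
#' @param control_stream_eligibility probability in (0, 1] that a reviewed
#'   matched control candidate is eligible (default 0.165).
#' @param control_ineligibility_split named probability vector over the three
#'   control exclusion labels, conditional on ineligibility; must sum to 1.
#' @param study_period inclusive `Date` interval of eligible incident
#'   diagnoses.
#' @param age_range_years inclusive completed-years interval at diagnosis.
#' @param feed_rule list: at least `min_months` feed months within the
#'   `window_months` calendar months ending at the index date.
#' @param match_ratio controls sought per case (default 2).
#' @param dob_tolerance_days date-of-birth matching tolerance; 366 days is a
#'   leap-year-safe reading of "plus or minus one year".
#' @param pool_cap maximum control candidates generated per case (default
#'   100); exhaustion before `match_ratio` eligible controls models the
#'   short-matched and unmatched cases.
#' @param horizon simulation date horizon containing all generated events.
#' @param fixed_control_margins list with `n_ineligible` (named integer
#'   vector of exact ineligible-review counts per control exclusion label)
#'   and `n_short_cases` (cases whose pool is exhausted after a single
#'   match); used only by fixed-margins pipeline runs to reproduce the
#'   observed control attrition arithmetic exactly.
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @return a validated `generator_config` object (a classed list).
#' @examples
#' cfg <- generator_config(n_potential_cases = 20, seed = 1)
#' cfg$case_disposition_probs
#' @export
generator_config <- function(n_potential_cases = 177L,
                             case_disposition_probs = default_case_probs(),
                             control_stream_eligibility = 0.165,
                             control_ineligibility_split = default_control_split(),
                             study_period = as.Date(c("2005-01-01", "2011-12-31")),
                             age_range_years = c(1L, 21L),
                             feed_rule = list(min_months = 3L, window_months = 12L),
                             match_ratio = 2L,
                             dob_tolerance_days = 366L,
                             pool_cap = 100L,
                             horizon = as.Date(c("1998-01-01", "2013-12-31")),
                             fixed_control_margins = default_control_margins(),
                             seed = NULL) {
  cfg <- structure(
    list(n_potential_cases = as.integer(n_potential_cases),
         case_disposition_probs = case_disposition_probs,
         control_stream_eligibility = control_stream_eligibility,
         control_ineligibility_split = control_ineligibility_split,
         study_period = as.Date(study_period),
         age_range_years = as.integer(age_range_years),
         feed_rule = lapply(feed_rule, as.integer),
         match_ratio = as.integer(match_ratio),
         dob_tolerance_days = as.integer(dob_tolerance_days),
         pool_cap = as.integer(pool_cap),
         horizon = as.Date(horizon),
         fixed_control_margins = fixed_control_margins,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config")
  validate_config(cfg)
}

#' @rdname generator_config
#' @export
default_case_probs <- function() {
  counts <- c(INCLUDED = 41, NO_STONE = 28, NO_GTUBE = 3, AGE_RANGE = 42,
              STUDY_PERIOD = 35, ASYNCHRONOUS = 14, INADEQUATE_DATA = 13,
              NO_CONTROL = 1)
  counts / sum(counts)
}

#' @rdname generator_config
#' @export
default_control_split <- function() {
  counts <- c(NO_GTUBE = 31, ASYNCHRONOUS = 82, INADEQUATE_DATA = 293)
  counts / sum(counts)
}

default_control_margins <- function() {
  list(n_ineligible = c(NO_GTUBE = 31L, ASYNCHRONOUS = 82L,
                        INADEQUATE_DATA = 293L),
       n_short_cases = 2L)
}

validate_config <- function(cfg) {
  check_probs <- function(p, field, labels) {
    if (is.null(names(p)) || !setequal(names(p), labels)) {
      stop("'", field, "' must be named over: ", paste(labels, collapse = ", "))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("'", field, "' must be a probability vector summing to 1")
    }
  }
  check_probs(cfg$case_disposition_probs, "case_disposition_probs", case_labels())
  check_probs(cfg$control_ineligibility_split, "control_ineligibility_split",
              control_exclusion_order())
  if (cfg$n_potential_cases < 0L) stop("'n_potential_cases' must be >= 0")
  if (cfg$match_ratio < 1L) stop("'match_ratio' must be >= 1")
  if (!(cfg$control_stream_eligibility > 0 && cfg$control_stream_eligibility <= 1)) {
    stop("'control_stream_eligibility' must lie in (0, 1]")
  }
  if (cfg$feed_rule$min_months > cfg$feed_rule$window_months) {
    stop("'feed_rule': min_months must not exceed window_months")
  }
  if (cfg$dob_tolerance_days < 1L) stop("'dob_tolerance_days' must be >= 1")
  if (cfg$pool_cap < 0L) stop("'pool_cap' must be >= 0")
  if (cfg$study_period[1] < cfg$horizon[1] || cfg$study_period[2] > cfg$horizon[2]) {
    stop("'study_period' must lie within 'horizon'")
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  potential cases:", x$n_potential_cases, "\n")
  cat("  study period:", format(x$study_period[1]), "to",
      format(x$study_period[2]), "\n")
  cat("  age range:", x$age_range_years[1], "-", x$age_range_years[2], "years\n")
  cat("  feed rule: >=", x$feed_rule$min_months, "of",
      x$feed_rule$window_months, "months\n")
  cat("  match ratio:", x$match_ratio, " dob tolerance:",
      x$dob_tolerance_days, "days  pool cap:", x$pool_cap, "\n")
  cat("  control eligibility per review:", x$control_stream_eligibility, "\n")
  invisible(x)
}

#' Derive screening criteria from a generator configuration
#'
#' @param config a [generator_config].
#' @return an [eligibility_criteria] sharing the config's study period, age
#'   range and feed rule.
#' @export
criteria_from_config <- function(config) {
  eligibility_criteria(study_period = config$study_period,
                       age_range_years = config$age_range_years,
                       feed_rule = config$feed_rule)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [generator_config()]; absent keys keep their
#' defaults. Probability vectors may be given as named maps of either
#' probabilities or raw counts (counts are normalized).
#'
#' @param path YAML file path.
#' @param seed optional seed overriding any `seed` key in the file.
#' @return a [generator_config].
#' @export
read_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_keys <- c("n_potential_cases", "control_stream_eligibility",
                   "match_ratio", "dob_tolerance_days", "pool_cap", "seed")
  for (k in scalar_keys) if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  for (k in c("case_disposition_probs", "control_ineligibility_split")) {
    if (!is.null(raw[[k]])) {
      p <- unlist(raw[[k]])
      args[[k]] <- p / sum(p)
    }
  }
  for (k in c("study_period", "horizon")) {
    if (!is.null(raw[[k]])) args[[k]] <- as.Date(unlist(raw[[k]]))
  }
  if (!is.null(raw$age_range_years)) args$age_range_years <- unlist(raw$age_range_years)
  if (!is.null(raw$feed_rule)) args$feed_rule <- raw$feed_rule
  if (!is.null(raw$fixed_control_margins)) {
    fcm <- raw$fixed_control_margins
    args$fixed_control_margins <- list(
      n_ineligible = unlist(fcm$n_ineligible),
      n_short_cases = fcm$n_short_cases %||% 0L)
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(generator_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
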