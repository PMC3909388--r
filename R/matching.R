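#' Matching specification
#'
#' Parameters of the two-stage control selection: automated demographic
#' matching (same sex, date of birth within a tolerance), then randomized
#' sequential chart review of matched candidates until `match_ratio` eligible
#' controls are found or the pool is exhausted.
#'
#' @param match_ratio controls sought per case (default 2).
#' @param dob_tolerance_days date-of-birth tolerance in days (366 is a
#'   leap-safe "plus or minus one year").
#' @param sex_exact require identical sex (default `TRUE`).
#' @param replacement may one control serve several cases? Defaults to
#'   `FALSE`, standard matched-design practice.
#' @return a `match_spec` object.
#' @export
match_spec <- function(match_ratio = 2L, dob_tolerance_days = 366L,
                       sex_exact = TRUE, replacement = FALSE) {
  stopifnot(match_ratio >= 1L, dob_tolerance_days >= 0L)
  structure(list(match_ratio = as.integer(match_ratio),
                 dob_tolerance_days = as.integer(dob_tolerance_days),
                 sex_exact = isTRUE(sex_exact),
                 replacement = isTRUE(replacement)),
            class = "match_spec")
}

#' Automated demographic matching
#'
#' The deterministic first stage: filter a candidate list down to those
#' matching the case on sex (when `spec$sex_exact`) and on date of birth
#' within `spec$dob_tolerance_days`. Input order is preserved.
#'
#' @param case 1-row data frame (or list) with `dob` and `sex`.
#' @param candidates data frame with `patient_id`, `dob`, `sex`.
#' @param spec a [match_spec].
#' @return character vector of matching candidate `patient_id`s, in input
#'   order.
#' @export
automated_match_pool <- function(case, candidates, spec = match_spec()) {
  if (is.data.frame(case)) {
    stopifnot(nrow(case) == 1L)
    case <- as.list(case)
  }
  if (nrow(candidates) == 0L) return(character(0))
  keep <- abs(as.numeric(as.Date(candidates$dob) - as.Date(case$dob))) <=
    spec$dob_tolerance_days
  if (spec$sex_exact) keep <- keep & candidates$sex == case$sex
  as.character(candidates$patient_id[keep])
}

#' Randomized sequential chart review of one case's candidate pool
#'
#' Shuffles the pool, then screens candidates one at a time with
#' [assess_control()] against the case's index date, stopping as soon as
#' `spec$match_ratio` eligible controls are found or the pool runs out.
#' Candidates after the stopping point are never reviewed (and never appear
#' in the tallies). `n_reviewed_ineligible` counts reviewed-but-excluded
#' candidates only, matching the convention under which the source study's
#' per-case review statistic equals excluded reviews / cases; set
#' `include_accepted = TRUE` for the variant counting every opened chart.
#'
#' @param case 1-row truth record of the case (needs `stone_dx_date`).
#' @param candidates truth-layer data frame of pool-matched candidates.
#' @param criteria an [eligibility_criteria].
#' @param spec a [match_spec].
#' @param shuffle randomize review order with the current RNG state (default
#'   `TRUE`); `FALSE` reviews in input order (the stream is then assumed to
#'   be pre-randomized).
#' @param include_accepted also count accepted controls in the review count.
#' @return list with `case_id`, `control_ids` (length `<= match_ratio`),
#'   `n_reviewed_ineligible`, `exhausted` (`TRUE` iff the pool ended before
#'   the ratio was met), and `reviewed` (tibble `patient_id`, `label`,
#'   `case_id` of every screened candidate).
#' @export
sequential_review <- function(case, candidates,
                              criteria = eligibility_criteria(),
                              spec = match_spec(), shuffle = TRUE,
                              include_accepted = FALSE) {
  if (is.data.frame(case)) stopifnot(nrow(case) == 1L)
  case_id <- as.character(case$patient_id)
  idx <- as.Date(case$stone_dx_date)
  if (length(idx) == 0L || is.na(idx)) {
    stop("case ", case_id, " has no index date")
  }
  n <- nrow(candidates)
  if (n > 0L && shuffle) candidates <- candidates[sample.int(n), ]
  # screen in blocks: candidates past the stopping point are never assessed
  labels <- character(0)
  stop_at <- n
  block <- max(16L, 4L * spec$match_ratio)
  from <- 1L
  while (from <= n) {
    to <- min(n, from + block - 1L)
    labels <- c(labels, assess_control(candidates[from:to, , drop = FALSE],
                                       criteria, case_index_date = idx))
    hits <- which(labels == "ELIGIBLE")
    if (length(hits) >= spec$match_ratio) {
      stop_at <- hits[spec$match_ratio]
      break
    }
    from <- to + 1L
  }
  reviewed <- labels[seq_len(stop_at)]
  eligible <- which(reviewed == "ELIGIBLE")
  n_inelig <- stop_at - length(eligible)
  list(case_id = case_id,
       control_ids = as.character(candidates$patient_id[eligible]),
       n_reviewed_ineligible = if (include_accepted) stop_at else n_inelig,
       exhausted = length(eligible) < spec$match_ratio,
       reviewed = tibble::tibble(
         patient_id = as.character(candidates$patient_id[seq_len(stop_at)]),
         label = reviewed,
         case_id = rep(case_id, stop_at)))
}

#' Match controls to every case
#'
#' Iterates the cases in sorted `patient_id` order, builds each case's
#' candidate pool, applies [automated_match_pool()] and [sequential_review()],
#' and aggregates per-case review counts and per-category control exclusion
#' tallies. When `spec$replacement` is `FALSE` (the default), a control
#' selected for one case is removed from every later case's pool before
#' review. Cases ending with zero controls are relabeled `NO_CONTROL`.
#'
#' @param cases truth-layer data frame of screened-in cases (one row each).
#' @param candidate_source either a function `function(case)` returning a
#'   candidate truth-layer data frame for that case, or a single shared
#'   candidate data frame.
#' @param criteria an [eligibility_criteria].
#' @param spec a [match_spec].
#' @param shuffle passed to [sequential_review()].
#' @param include_accepted passed to [sequential_review()].
#' @return list with:
#'   * `results`: tibble `case_id`, `control_ids` (list column),
#'     `n_matched`, `n_reviewed_ineligible`, `exhausted`;
#'   * `matches`: long tibble `case_id`, `control_id`, `match_order`;
#'   * `reviewed`: tibble of every reviewed candidate with its disposition
#'     label and reviewing case;
#'   * `tallies`: tibble `label`, `count` over control disposition labels.
#' @export
run_matching <- function(cases, candidate_source,
                         criteria = eligibility_criteria(),
                         spec = match_spec(), shuffle = TRUE,
                         include_accepted = FALSE) {
  ids <- as.character(cases$patient_id)
  if (anyDuplicated(ids) > 0L) stop("duplicate case ids")
  cases <- cases[order(ids), ]
  source_fn <- if (is.function(candidate_source)) {
    candidate_source
  } else {
    shared <- candidate_source
    function(case) shared
  }
  consumed <- character(0)
  res <- vector("list", nrow(cases))
  reviewed <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    pool <- source_fn(case)
    keep <- automated_match_pool(case, pool, spec)
    if (!spec$replacement) keep <- setdiff(keep, consumed)
    pool <- pool[match(keep, as.character(pool$patient_id)), , drop = FALSE]
    r <- sequential_review(case, pool, criteria, spec, shuffle = shuffle,
                           include_accepted = include_accepted)
    if (!spec$replacement) consumed <- c(consumed, r$control_ids)
    res[[i]] <- r
    reviewed[[i]] <- r$reviewed
  }
  results <- tibble::tibble(
    case_id = vapply(res, `[[`, "", "case_id"),
    control_ids = lapply(res, `[[`, "control_ids"),
    n_matched = vapply(res, function(r) length(r$control_ids), integer(1)),
    n_reviewed_ineligible = vapply(res, `[[`, integer(1), "n_reviewed_ineligible"),
    exhausted = vapply(res, `[[`, logical(1), "exhausted"))
  matches_proto <- tibble::tibble(case_id = character(0),
                                  control_id = character(0),
                                  match_order = integer(0))
  matches <- dplyr::bind_rows(c(list(matches_proto), lapply(res, function(r) {
    tibble::tibble(case_id = rep(r$case_id, length(r$control_ids)),
                   control_id = r$control_ids,
                   match_order = seq_along(r$control_ids))
  })))
  reviewed_proto <- tibble::tibble(patient_id = character(0),
                                   label = character(0),
                                   case_id = character(0))
  reviewed <- dplyr::bind_rows(c(list(reviewed_proto), reviewed))
  cnt <- table(factor(reviewed$label, levels = control_labels()))
  tallies <- tibble::tibble(label = control_labels(), count = as.integer(cnt))
  list(results = results, matches = matches, reviewed = reviewed,
       tallies = tallies)
}
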