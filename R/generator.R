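#' Synthetic EHR generation
#'
#' The generator is label-first and constructive: it first samples the
#' *intended* screening disposition for each patient, then builds a truth
#' record guaranteed to screen as exactly that label, together with a coded
#' billing-event layer that always satisfies the relevant phenotype query
#' (this is how coding inaccuracy -- e.g. a stone code with no verifiable
#' stone -- is realized). The approach makes the generator exactly calibrated
#' to the configured disposition probabilities and gives an exact round-trip
#' test against the screening functions.
#'
#' @name synthetic_ehr
#' @keywords internal
NULL

# ---- low-level builders ----------------------------------------------------

# uniform date of birth giving exactly `age` completed years at `on`.
# min_days keeps the birth at least that many days before `on` (used for
# age-0 records so a G-tube placement date after birth exists).
random_dob_for_age <- function(on, age, min_days = 0L) {
  on <- as.Date(on)
  n <- length(on)
  age <- rep_len(as.integer(age), n)
  min_days <- rep_len(as.integer(min_days), n)
  u <- min_days + floor(stats::runif(n) * (365L - min_days))
  dob <- on - round(365.25 * age) - u
  # polish to the exact completed-years band; the initial draw is almost
  # always inside it already (leap-year wobble is a couple of days), so the
  # correction loop touches few records and converges by halving step sizes
  # well below the 365-day band width
  mismatch <- function(i) {
    over <- dob[i] > on[i]
    d <- integer(length(i))
    d[over] <- -1L  # born after the anchor: move the birth earlier
    ok <- !over
    d[ok] <- age_at(dob[i][ok], on[i][ok]) - age[i][ok]
    d
  }
  bad <- which(mismatch(seq_len(n)) != 0L)
  it <- 0L
  while (length(bad) > 0L) {
    it <- it + 1L
    if (it > 1500L) stop("internal: dob construction did not converge")
    d <- mismatch(bad)
    step <- pmax(abs(d) * 365L - 330L, if (it <= 10L) 40L else 1L)
    dob[bad] <- dob[bad] + sign(d) * step
    bad <- bad[mismatch(bad) != 0L]
  }
  dob
}

# consecutive-month token runs: element i is the k[i] months starting at
# month index from[i]
months_from <- function(from, k) {
  k <- pmax(k, 0L)
  tok <- ym_token(sequence(k, from = from))
  unname(split(tok, factor(rep.int(seq_along(from), k),
                           levels = seq_along(from))))
}

# G-tube placement plus tube-feed months for one anchor date per record:
# feed months are the last k calendar months of the look-back window ending
# at the anchor's month (k clipped to the months available after birth), and
# placement falls in [dob + 1, anchor - 1], never after the first feed month.
build_gtube_feed <- function(dob, anchor, k, window_months = 12L) {
  n <- length(dob)
  k <- rep_len(as.integer(k), n)
  wend <- ym_index(anchor)
  wstart <- wend - as.integer(window_months) + 1L
  earliest <- pmax(wstart, ym_index(dob) + 1L)
  avail <- pmax(wend - earliest + 1L, 0L)
  k <- pmin(k, avail)
  first <- wend - k + 1L
  base_month <- first
  base_month[k <= 0L] <- earliest[k <= 0L]
  cand <- ym_start(base_month) - floor(stats::runif(n) * 400)
  placement <- pmin(pmax(cand, dob + 1), as.Date(anchor) - 1)
  list(placement = placement, feed = months_from(first, k), k = k)
}

# billing events for case-query patients: 1-3 G-tube codes and 1-2 stone
# codes each, so every generated potential case matches the case query
# whatever its truth layer says
make_coded_events <- function(ids, config, stone_codes = TRUE) {
  cs <- default_code_sets()
  n <- length(ids)
  ng <- sample.int(3L, n, replace = TRUE)
  gi <- sample.int(nrow(cs$GTUBE_ANY$members), sum(ng), replace = TRUE)
  pid <- rep(ids, ng)
  code_system <- cs$GTUBE_ANY$members$code_system[gi]
  code <- cs$GTUBE_ANY$members$code[gi]
  if (stone_codes) {
    ns <- sample.int(2L, n, replace = TRUE)
    si <- sample.int(nrow(cs$STONE_ICD9$members), sum(ns), replace = TRUE)
    pid <- c(pid, rep(ids, ns))
    code_system <- c(code_system, cs$STONE_ICD9$members$code_system[si])
    code <- c(code, cs$STONE_ICD9$members$code[si])
  }
  ev <- fast_tibble(
    patient_id = pid, code_system = code_system, code = code,
    date = runif_date(length(pid), config$horizon[1], config$horizon[2]))
  ev[order(ev$patient_id, ev$code_system, ev$code, ev$date), ]
}

new_truth <- function(patient_id, dob, sex, has_true_stone, stone_dx_date,
                      has_true_gtube, gtube_placement_date, feed_months,
                      nutrition_data_adequate) {
  fast_tibble(
    patient_id = patient_id, dob = dob, sex = sex,
    has_true_stone = has_true_stone, stone_dx_date = stone_dx_date,
    has_true_gtube = has_true_gtube,
    gtube_placement_date = gtube_placement_date,
    feed_months = feed_months,
    nutrition_data_adequate = nutrition_data_adequate)
}

# ---- case realization ------------------------------------------------------

# vectorized work-horse behind realize_case_disposition()
realize_cases <- function(labels, config, ids = NULL) {
  bad <- setdiff(unique(labels), case_labels())
  if (length(bad) > 0L) {
    stop("unknown case disposition label(s): ", paste(bad, collapse = ", "))
  }
  n <- length(labels)
  if (n == 0L) {
    return(list(records = new_truth(character(0), as.Date(character(0)),
                                    character(0), logical(0),
                                    as.Date(character(0)), logical(0),
                                    as.Date(character(0)), list(),
                                    logical(0)),
                events = make_coded_events(character(0), config)))
  }
  if (is.null(ids)) ids <- sprintf("P%05d", seq_len(n))
  period <- config$study_period
  hor <- config$horizon
  wm <- config$feed_rule$window_months
  mm <- config$feed_rule$min_months

  sex <- sample(c("M", "F"), n, replace = TRUE)

  # reference date: the stone diagnosis (or, for NO_STONE, the date the feed
  # history is anchored to); inside the study period except for STUDY_PERIOD
  ref <- runif_date(n, period[1], period[2])
  sp <- which(labels == "STUDY_PERIOD")
  if (length(sp) > 0L) {
    early <- stats::runif(length(sp)) < 0.5
    d <- as.Date(rep(NA, length(sp)))
    d[early] <- runif_date(sum(early), hor[1] + 420, period[1] - 1)
    d[!early] <- runif_date(sum(!early), period[2] + 1, hor[2] - 60)
    ref[sp] <- d
  }

  # completed age at the reference date
  alo <- config$age_range_years[1]
  ahi <- config$age_range_years[2]
  age <- sample(seq.int(alo, ahi), n, replace = TRUE)
  ar <- which(labels == "AGE_RANGE")
  if (length(ar) > 0L) {
    out_ages <- c(if (alo > 0L) seq.int(0L, alo - 1L),
                  seq.int(ahi + 1L, ahi + 9L))
    age[ar] <- sample(out_ages, length(ar), replace = TRUE)
  }
  dob <- random_dob_for_age(ref, age, min_days = ifelse(age == 0L, 60L, 0L))

  # G-tube placement and feed months
  has_gtube <- labels != "NO_GTUBE"
  placement <- as.Date(rep(NA, n))
  feed <- rep(list(character(0)), n)
  asyn <- labels == "ASYNCHRONOUS"
  # ASYNCHRONOUS realizes either as stone-predates-placement or as a feed
  # history too sparse in the look-back window
  late <- asyn & (stats::runif(n) < 0.5 | mm < 1L)
  k <- sample.int(wm - mm + 1L, n, replace = TRUE) + mm - 1L
  if (mm >= 1L) k[asyn] <- sample.int(mm, n, replace = TRUE)[asyn] - 1L
  base <- which(has_gtube & !late)
  if (length(base) > 0L) {
    bf <- build_gtube_feed(dob[base], ref[base], k[base], wm)
    placement[base] <- bf$placement
    feed[base] <- bf$feed
  }
  lt <- which(late)
  if (length(lt) > 0L) {
    pl <- ref[lt] + 1L + floor(stats::runif(length(lt)) * 700)
    pl <- pmax(pmin(pl, hor[2] - 30), ref[lt] + 1L)
    placement[lt] <- pl
    k2 <- sample.int(6L, length(lt), replace = TRUE)
    pm <- ym_index(pl)
    hm <- ym_index(hor[2])
    feed[lt] <- months_from(pm, pmin(k2, hm - pm + 1L))
  }

  has_stone <- labels != "NO_STONE"
  stone_date <- ref
  stone_date[!has_stone] <- NA

  records <- new_truth(ids, dob, sex, has_stone, stone_date, has_gtube,
                       placement, feed,
                       nutrition_data_adequate = labels != "INADEQUATE_DATA")
  list(records = records, events = make_coded_events(ids, config))
}

#' Construct case records that screen as a requested disposition
#'
#' Builds `n` synthetic patients whose truth layer yields exactly `label`
#' under [assess_case()] with the criteria derived from `config`, and whose
#' event layer always matches the case phenotype query (at least one G-tube
#' code and one stone code) regardless of the truth layer. The intended label
#' `NO_CONTROL` is realized as a fully includable record -- control
#' availability is resolved later, at the matching stage.
#'
#' @param label one of [case_labels()].
#' @param config a [generator_config]. The caller controls the RNG state
#'   (seed beforehand for reproducibility).
#' @param n number of records to build.
#' @param ids optional character vector of patient ids.
#' @return list with `records` (truth-layer tibble) and `events` (coded-event
#'   tibble).
#' @export
realize_case_disposition <- function(label, config = generator_config(),
                                     n = 1L, ids = NULL) {
  stopifnot(length(label) == 1L)
  realize_cases(rep(label, n), config, ids)
}

#' Generate a synthetic potential-case population
#'
#' Samples an intended screening disposition for each of
#' `config$n_potential_cases` patients from `config$case_disposition_probs`
#' (or allocates exact counts by largest remainder when
#' `fixed_margins = TRUE`), then realizes each record constructively. Every
#' generated patient matches the case phenotype query by construction.
#'
#' @param config a [generator_config]; `config$seed`, when non-`NULL`, seeds
#'   the RNG so identical configs give identical populations.
#' @param fixed_margins allocate disposition labels as exact largest-remainder
#'   counts instead of multinomial sampling.
#' @return list with `records`, `events`, and `intended` (tibble
#'   `patient_id`, `intended_label`) for round-trip testing.
#' @examples
#' pop <- generate_population(generator_config(n_potential_cases = 12, seed = 7))
#' table(pop$intended$intended_label)
#' @export
generate_population <- function(config = generator_config(),
                                fixed_margins = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_potential_cases
  probs <- config$case_disposition_probs[case_labels()]
  labels <- if (n == 0L) {
    character(0)
  } else if (fixed_margins) {
    counts <- allocate_counts(probs, n)
    sample(rep(names(counts), counts))
  } else {
    sample(names(probs), n, replace = TRUE, prob = probs)
  }
  ids <- if (n == 0L) character(0) else sprintf("P%05d", seq_len(n))
  out <- realize_cases(labels, config, ids)
  list(records = out$records, events = out$events,
       intended = tibble::tibble(patient_id = ids, intended_label = labels))
}

#' Exact count allocation by largest remainder
#'
#' Splits `n` into integer counts proportional to `probs`: floors first, then
#' hands the remaining units to the largest fractional parts (ties broken by
#' position).
#'
#' @param probs non-negative weights (normalized internally).
#' @param n total count to allocate.
#' @return named integer vector summing to `n`.
#' @export
allocate_counts <- function(probs, n) {
  probs <- probs / sum(probs)
  raw <- probs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

# ---- control candidate streams --------------------------------------------

#' Generate the matched control-candidate stream for one case
#'
#' Candidates match the case on sex and on date of birth within
#' `config$dob_tolerance_days`, carry at least one G-tube code and no stone
#' code (so all satisfy the control phenotype query), and are independently
#' eligible with probability `config$control_stream_eligibility`; ineligible
#' candidates draw their exclusion label from
#' `config$control_ineligibility_split` and are constructed to screen as that
#' label against the case's index date. The stream length is capped at
#' `config$pool_cap` to model pool exhaustion.
#'
#' Candidates intended as `ELIGIBLE` or `INADEQUATE_DATA` must have a G-tube
#' placed (and months of feeds) strictly before the index date, so for cases
#' diagnosed very young the upper end of their date-of-birth offset is
#' tightened below the full tolerance; the other labels use the full window.
#'
#' @param case single truth-layer record (1-row data frame or list) with
#'   `patient_id`, `dob`, `sex`, and a non-missing `stone_dx_date`.
#' @param config a [generator_config]. Caller controls the RNG state.
#' @param n stream length; defaults to `config$pool_cap`.
#' @param intended optional character vector of intended control labels to
#'   realize verbatim (used by fixed-margins pipeline runs); overrides `n`.
#' @return list with `records`, `events`, and `intended` (tibble
#'   `patient_id`, `intended_label`, `case_id`).
#' @export
generate_control_stream <- function(case, config = generator_config(),
                                    n = NULL, intended = NULL) {
  if (is.data.frame(case)) {
    stopifnot(nrow(case) == 1L)
    case <- as.list(case)
    if (is.list(case$feed_months)) case$feed_months <- case$feed_months[[1]]
  }
  idx <- as.Date(case$stone_dx_date)
  if (is.null(idx) || is.na(idx)) {
    stop("case ", case$patient_id, " has no stone diagnosis (index) date")
  }
  if (is.null(n)) n <- config$pool_cap
  if (!is.null(intended)) {
    bad <- setdiff(unique(intended), control_labels())
    if (length(bad) > 0L) {
      stop("unknown control disposition label(s): ", paste(bad, collapse = ", "))
    }
    n <- length(intended)
  }
  if (n == 0L) {
    empty <- realize_cases(character(0), config)
    return(list(records = empty$records, events = empty$events,
                intended = tibble::tibble(patient_id = character(0),
                                          intended_label = character(0),
                                          case_id = character(0))))
  }
  p <- config$control_stream_eligibility
  split <- config$control_ineligibility_split[control_exclusion_order()]
  if (is.null(intended)) {
    elig <- stats::runif(n) < p
    intended <- sample(names(split), n, replace = TRUE, prob = split)
    intended[elig] <- "ELIGIBLE"
  }
  ids <- sprintf("%s-K%04d", case$patient_id, seq_len(n))
  tol <- config$dob_tolerance_days
  case_dob <- as.Date(case$dob)

  # date-of-birth offsets within the matching tolerance
  hi <- rep(tol, n)
  need_room <- intended %in% c("ELIGIBLE", "INADEQUATE_DATA")
  room_hi <- as.integer(idx - 160L - case_dob)
  hi[need_room] <- min(tol, room_hi)
  if (any(hi < -tol)) {
    stop("index date of case ", case$patient_id,
         " leaves no room for eligible controls within the dob tolerance")
  }
  off <- floor(stats::runif(n) * (hi + tol + 1)) - tol
  dob <- case_dob + off

  wm <- config$feed_rule$window_months
  mm <- config$feed_rule$min_months
  has_gtube <- intended != "NO_GTUBE"
  placement <- as.Date(rep(NA, n))
  feed <- rep(list(character(0)), n)
  asyn <- intended == "ASYNCHRONOUS"
  room_b <- dob <= idx - 160L
  late <- asyn & (stats::runif(n) < 0.5 | !room_b | mm < 1L)
  k <- sample.int(wm - mm + 1L, n, replace = TRUE) + mm - 1L
  if (mm >= 1L) k[asyn] <- sample.int(mm, n, replace = TRUE)[asyn] - 1L
  base <- which(has_gtube & !late)
  if (length(base) > 0L) {
    bf <- build_gtube_feed(dob[base], rep(idx, length(base)), k[base], wm)
    placement[base] <- bf$placement
    feed[base] <- bf$feed
  }
  lt <- which(late)
  if (length(lt) > 0L) {
    pl <- idx + 1L + floor(stats::runif(length(lt)) * 700)
    pl <- pmax(pmin(pl, config$horizon[2] - 30), pmax(idx, dob[lt]) + 1L)
    placement[lt] <- pl
    k2 <- sample.int(6L, length(lt), replace = TRUE)
    pm <- ym_index(pl)
    hm <- ym_index(config$horizon[2])
    feed[lt] <- months_from(pm, pmin(k2, hm - pm + 1L))
  }

  records <- new_truth(ids, dob, rep(case$sex, n),
                       has_true_stone = rep(FALSE, n),
                       stone_dx_date = as.Date(rep(NA, n)),
                       has_true_gtube = has_gtube,
                       gtube_placement_date = placement,
                       feed_months = feed,
                       nutrition_data_adequate = intended != "INADEQUATE_DATA")
  list(records = records,
       events = make_coded_events(ids, config, stone_codes = FALSE),
       intended = fast_tibble(patient_id = ids, intended_label = intended,
                              case_id = rep(as.character(case$patient_id), n)))
}
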