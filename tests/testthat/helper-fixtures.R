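# Shared fixtures and independent brute-force oracles. The oracles use only
# calendar iteration / per-patient set logic, never the implementation paths
# they check.

truth_record <- function(patient_id = "X1",
                         dob = as.Date("2000-01-15"),
                         sex = "M",
                         has_true_stone = TRUE,
                         stone_dx_date = as.Date("2008-06-10"),
                         has_true_gtube = TRUE,
                         gtube_placement_date = as.Date("2007-01-05"),
                         feed_months = c("2008-01", "2008-02", "2008-03",
                                         "2008-04"),
                         nutrition_data_adequate = TRUE) {
  tibble::tibble(patient_id = patient_id, dob = dob, sex = sex,
                 has_true_stone = has_true_stone,
                 stone_dx_date = stone_dx_date,
                 has_true_gtube = has_true_gtube,
                 gtube_placement_date = gtube_placement_date,
                 feed_months = list(feed_months),
                 nutrition_data_adequate = nutrition_data_adequate)
}

# k-th birthday by calendar arithmetic; Feb 29 rolls to Mar 1 in common years
anniversary <- function(dob, k) {
  lt <- as.POSIXlt(dob)
  y <- lt$year + 1900L + k
  d <- as.Date(sprintf("%04d-%02d-%02d", y, lt$mon + 1L, lt$mday),
               format = "%Y-%m-%d")
  if (is.na(d)) d <- as.Date(sprintf("%04d-03-01", y))
  d
}

# completed years by counting attained birthdays one at a time
age_oracle <- function(dob, on) {
  age <- 0L
  while (anniversary(dob, age + 1L) <= on) age <- age + 1L
  age
}

# the w calendar-month tokens ending at index_date's month, by iteration
window_tokens <- function(index_date, w = 12L) {
  lt <- as.POSIXlt(index_date)
  y <- lt$year + 1900L
  m <- lt$mon + 1L
  toks <- character(w)
  for (i in seq_len(w)) {
    toks[i] <- sprintf("%04d-%02d", y, m)
    m <- m - 1L
    if (m == 0L) {
      m <- 12L
      y <- y - 1L
    }
  }
  toks
}

feed_oracle <- function(feed_months, index_date, w = 12L) {
  length(intersect(unique(feed_months), window_tokens(index_date, w)))
}

# per-patient set-logic evaluation of a phenotype query
query_oracle <- function(events, query) {
  norm <- function(x) toupper(trimws(x))
  ids <- unique(as.character(events$patient_id))
  hits <- function(pid, cs) {
    ev <- events[events$patient_id == pid, ]
    any(paste(ev$code_system, norm(ev$code)) %in%
          paste(cs$members$code_system, cs$members$code))
  }
  keep <- vapply(ids, function(pid) {
    all(vapply(query$require, function(cs) hits(pid, cs), logical(1))) &&
      !any(vapply(query$forbid, function(cs) hits(pid, cs), logical(1)))
  }, logical(1))
  sort(ids[keep])
}

# small random event tables over a mixed in/out-of-set code universe
random_events <- function(max_patients = 6L, max_events = 8L) {
  universe <- list(c("ICD9-DX", "592.1"), c("ICD9-DX", "592.9"),
                   c("CPT", "43246"), c("ICD9-DX", "V44.1"),
                   c("ICD9-PX", "43.19"), c("ICD9-DX", "599.0"),
                   c("CPT", "90210"), c("ICD9-PX", "96.36"))
  n <- sample.int(max_events, 1L)
  pick <- sample.int(length(universe), n, replace = TRUE)
  tibble::tibble(
    patient_id = sample(letters[seq_len(max_patients)], n, replace = TRUE),
    code_system = vapply(universe[pick], `[`, "", 1L),
    code = vapply(universe[pick], `[`, "", 2L),
    date = as.Date("2006-01-01") + sample.int(2000L, n, replace = TRUE))
}

# brute-force demographic matching filter
pool_oracle <- function(case, candidates, tol_days = 366L, sex_exact = TRUE) {
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ok <- abs(as.numeric(candidates$dob[i] - case$dob)) <= tol_days
    if (sex_exact) ok <- ok && candidates$sex[i] == case$sex
    keep[i] <- ok
  }
  as.character(candidates$patient_id[keep])
}

# screening-stage expectation for an intended generator label
screen_stage_label <- function(intended) {
  ifelse(intended == "NO_CONTROL", "INCLUDED", intended)
}
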