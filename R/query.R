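#' Evaluate a phenotype query over coded events
#'
#' Returns the patients whose event history satisfies the query: for every
#' code set in `query$require` at least one event matches, and no event
#' matches any set in `query$forbid`. The result is independent of event
#' order. `count_query()` is the de-identified mode: the cohort size without
#' patient identifiers, as used for feasibility screening before IRB approval.
#'
#' @param events data frame of coded events with columns `patient_id`,
#'   `code_system` (one of [code_systems()]), `code`, `date`.
#' @param query a [phenotype_query].
#' @return `evaluate_query()`: sorted character vector of matching patient
#'   ids. `count_query()`: a single non-negative integer.
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = c("a", "a", "b"),
#'   code_system = c("ICD9-DX", "CPT", "CPT"),
#'   code = c("592.1", "43246", "43246"),
#'   date = as.Date("2008-03-01")
#' )
#' evaluate_query(ev, case_query())    # "a"
#' evaluate_query(ev, control_query()) # "b"
#' @export
evaluate_query <- function(events, query) {
  stopifnot(inherits(query, "phenotype_query"))
  events <- validate_events(events)
  if (nrow(events) == 0L) return(character(0))
  key <- paste(events$code_system, normalize_code(events$code))
  set_key <- function(cs) paste(cs$members$code_system, cs$members$code)
  ids <- NULL
  for (cs in query$require) {
    hit <- unique(events$patient_id[key %in% set_key(cs)])
    ids <- if (is.null(ids)) hit else intersect(ids, hit)
    if (length(ids) == 0L) return(character(0))
  }
  for (cs in query$forbid) {
    hit <- unique(events$patient_id[key %in% set_key(cs)])
    ids <- setdiff(ids, hit)
  }
  sort(ids)
}

#' @rdname evaluate_query
#' @export
count_query <- function(events, query) {
  length(evaluate_query(events, query))
}

# checks the event-table contract; returns the table with character ids
validate_events <- function(events) {
  needed <- c("patient_id", "code_system", "code")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0L) {
    stop("event table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!(events$code_system %in% code_systems()))
  if (length(bad) > 0L) {
    stop("unknown code_system '", events$code_system[bad[1]],
         "' in event row ", bad[1])
  }
  events$patient_id <- as.character(events$patient_id)
  events
}
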