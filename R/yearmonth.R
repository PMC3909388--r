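#' Calendar-month tokens
#'
#' Tube-feed exposure is recorded at calendar-month granularity as `"YYYY-MM"`
#' tokens. Internally a month is an integer index (`year * 12 + month - 1`) so
#' that window arithmetic is plain integer arithmetic.
#'
#' @param x a `Date` vector (`ym_index`) or character vector of `"YYYY-MM"`
#'   tokens (`ym_parse`).
#' @param idx integer month index.
#' @return `ym_index`/`ym_parse` return integer month indices; `ym_token`
#'   returns `"YYYY-MM"` strings; `ym_start` returns the first day of the
#'   month as a `Date`.
#' @keywords internal
#' @name yearmonth
NULL

#' @rdname yearmonth
#' @export
ym_index <- function(x) {
  lt <- as.POSIXlt(as.Date(x))
  (lt$year + 1900L) * 12L + lt$mon
}

#' @rdname yearmonth
#' @export
ym_token <- function(idx) {
  out <- sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
  out[is.na(idx)] <- NA_character_
  out
}

#' @rdname yearmonth
#' @export
ym_parse <- function(x) {
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}$", x)
  if (any(!ok & !is.na(x))) {
    stop("malformed year-month token(s): ",
         paste(utils::head(x[!ok & !is.na(x)], 3L), collapse = ", "))
  }
  as.integer(substr(x, 1L, 4L)) * 12L + as.integer(substr(x, 6L, 7L)) - 1L
}

#' @rdname yearmonth
#' @export
ym_start <- function(idx) {
  as.Date(sprintf("%04d-%02d-01", idx %/% 12L, idx %% 12L + 1L))
}

# validation-free variants for internal hot paths (token shape is
# guaranteed by construction there)
ym_parse_fast <- function(x) {
  as.integer(substr(x, 1L, 4L)) * 12L + as.integer(substr(x, 6L, 7L)) - 1L
}

# cheap tibble for internal hot paths: columns are pre-validated,
# equal-length vectors
fast_tibble <- function(...) {
  cols <- list(...)
  n <- if (length(cols) == 0L) 0L else length(cols[[1]])
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(n))
}

# uniform random Date in [from, to], inclusive
runif_date <- function(n, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  stopifnot(all(to >= from))
  from + floor(stats::runif(n) * (as.numeric(to - from) + 1))
}
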