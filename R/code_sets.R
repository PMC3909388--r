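#' Code sets and phenotype queries
#'
#' A code set is a named collection of (code system, code) pairs; a phenotype
#' query combines code sets with boolean semantics: a patient matches when at
#' least one of their events hits every `require` set and no event hits any
#' `forbid` set. This is the level at which i2b2-style cohort queries operate
#' over billing data.
#'
#' Codes are normalized on construction (whitespace trimmed, upper-cased), so
#' `"v44.1"` and `"V44.1"` are the same code.
#'
#' @param name single string naming the set.
#' @param code_system character vector; each element one of `"ICD9-DX"`,
#'   `"ICD9-PX"`, `"CPT"` (recycled against `code`).
#' @param code character vector of literal codes.
#' @return `code_set()` returns a `code_set` object: a list with `name` and a
#'   `members` tibble (`code_system`, `code`), de-duplicated.
#' @examples
#' code_set("STONE_ICD9", "ICD9-DX", c("592.1", "592.2", "592.9"))
#' @export
code_set <- function(name, code_system, code) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  code <- normalize_code(code)
  if (length(code) == 0L || any(!nzchar(code))) {
    stop("code set '", name, "' must have non-empty codes")
  }
  code_system <- rep_len(as.character(code_system), length(code))
  bad <- setdiff(unique(code_system), code_systems())
  if (length(bad) > 0L) {
    stop("unknown code_system value(s): ", paste(bad, collapse = ", "))
  }
  members <- dplyr::distinct(tibble::tibble(code_system = code_system, code = code))
  structure(list(name = name, members = members), class = "code_set")
}

#' @rdname code_set
#' @export
code_systems <- function() c("ICD9-DX", "ICD9-PX", "CPT")

normalize_code <- function(code) toupper(trimws(as.character(code)))

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set> ", x$name, ": ", nrow(x$members), " codes\n", sep = "")
  print(x$members, n = Inf)
  invisible(x)
}

#' @export
length.code_set <- function(x) nrow(x$members)

#' Study code sets
#'
#' The literal billing-code definitions used to identify the study population:
#' G-tube presence captured by a mix of ICD-9-CM diagnosis codes (V44.1,
#' V55.1, the 536.4x complication family), ICD-9-CM procedure codes (43.11,
#' 43.19, 96.36, 97.02) and CPT procedure codes; kidney stones captured by
#' ICD-9-CM diagnosis codes only (592.1, 592.2, 592.9). The published G-tube
#' ICD-9 list repeats 43.19; the duplicate collapses, leaving 10 unique codes.
#'
#' @return named list of [code_set] objects: `GTUBE_ICD9` (10 codes),
#'   `GTUBE_CPT` (11 codes), `GTUBE_ANY` (their union, 21 codes), and
#'   `STONE_ICD9` (3 codes).
#' @examples
#' vapply(default_code_sets(), length, integer(1))
#' @export
default_code_sets <- function() {
  cached <- get0("code_sets", envir = .cohortflow_cache)
  if (!is.null(cached)) return(cached)
  gtube_icd9 <- code_set(
    "GTUBE_ICD9",
    c("ICD9-DX", "ICD9-PX", "ICD9-PX", "ICD9-PX", "ICD9-DX", "ICD9-PX",
      "ICD9-PX", "ICD9-DX", "ICD9-DX", "ICD9-DX", "ICD9-DX"),
    c("V44.1", "43.19", "43.11", "43.19", "V55.1", "96.36",
      "97.02", "536.40", "536.41", "536.42", "536.49")
  )
  gtube_cpt <- code_set(
    "GTUBE_CPT", "CPT",
    c("43246", "43653", "43750", "43760", "43830", "43831",
      "43832", "49440", "49450", "49465", "74350")
  )
  gtube_any <- code_set(
    "GTUBE_ANY",
    c(gtube_icd9$members$code_system, gtube_cpt$members$code_system),
    c(gtube_icd9$members$code, gtube_cpt$members$code)
  )
  stone <- code_set("STONE_ICD9", "ICD9-DX", c("592.1", "592.2", "592.9"))
  sets <- list(GTUBE_ICD9 = gtube_icd9, GTUBE_CPT = gtube_cpt,
               GTUBE_ANY = gtube_any, STONE_ICD9 = stone)
  assign("code_sets", sets, envir = .cohortflow_cache)
  sets
}

.cohortflow_cache <- new.env(parent = emptyenv())

#' Read a code set from a two-column delimited file
#'
#' Expects tab- or whitespace-delimited lines `code_system<TAB>code` with a
#' header row (`code_system`, `code`). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param name name for the resulting set; defaults to the file name.
#' @return a [code_set].
#' @export
read_code_set <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  tab <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                           colClasses = "character")
  if (!all(c("code_system", "code") %in% names(tab))) {
    stop("code set file must have columns 'code_system' and 'code'")
  }
  code_set(name, tab$code_system, tab$code)
}

#' Construct a phenotype query
#'
#' @param require list of [code_set] objects; a matching patient must have at
#'   least one event in each. Must be non-empty.
#' @param forbid list of [code_set] objects; a matching patient must have no
#'   event in any.
#' @return a `phenotype_query` object.
#' @examples
#' cs <- default_code_sets()
#' # case definition: >= 1 G-tube code AND >= 1 stone code
#' phenotype_query(require = list(cs$GTUBE_ANY, cs$STONE_ICD9))
#' # control definition: >= 1 G-tube code, no stone code
#' phenotype_query(require = list(cs$GTUBE_ANY), forbid = list(cs$STONE_ICD9))
#' @export
phenotype_query <- function(require, forbid = list()) {
  if (inherits(require, "code_set")) require <- list(require)
  if (inherits(forbid, "code_set")) forbid <- list(forbid)
  stopifnot(is.list(require), is.list(forbid))
  if (length(require) == 0L) stop("'require' must contain at least one code set")
  ok <- vapply(c(require, forbid), inherits, logical(1), what = "code_set")
  if (!all(ok)) stop("'require' and 'forbid' must contain code_set objects")
  structure(list(require = require, forbid = forbid), class = "phenotype_query")
}

#' @export
print.phenotype_query <- function(x, ...) {
  cat("<phenotype_query>\n  require:",
      paste(vapply(x$require, `[[`, "", "name"), collapse = " AND "), "\n")
  if (length(x$forbid) > 0L) {
    cat("  forbid: ", paste(vapply(x$forbid, `[[`, "", "name"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default case and control queries
#'
#' The case query requires at least one G-tube code (ICD-9-CM or CPT) and at
#' least one kidney-stone ICD-9-CM code; the control query requires a G-tube
#' code in the absence of any stone code.
#'
#' @return a `phenotype_query`.
#' @export
case_query <- function() {
  cs <- default_code_sets()
  phenotype_query(require = list(cs$GTUBE_ANY, cs$STONE_ICD9))
}

#' @rdname case_query
#' @export
control_query <- function() {
  cs <- default_code_sets()
  phenotype_query(require = list(cs$GTUBE_ANY), forbid = list(cs$STONE_ICD9))
}
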