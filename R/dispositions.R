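#' Disposition labels
#'
#' Screening one candidate chart yields exactly one disposition: inclusion, or
#' a single named exclusion reason. The labels (and their fixed reporting
#' order) mirror the mutually exclusive rows of the study attrition table.
#'
#' For cases: `INCLUDED`, `NO_STONE` (stone could not be verified in the
#' chart), `NO_GTUBE` (G-tube could not be verified), `AGE_RANGE`,
#' `STUDY_PERIOD`, `ASYNCHRONOUS` (stone history predated G-tube placement, or
#' the tube-feed exposure rule failed), `INADEQUATE_DATA`, and `NO_CONTROL`
#' (assigned at the matching stage when no eligible control exists).
#'
#' For controls: `ELIGIBLE`, `NO_GTUBE`, `ASYNCHRONOUS`, `INADEQUATE_DATA`.
#'
#' @return character vector of valid labels for the role.
#' @export
case_labels <- function() {
  c("INCLUDED", "NO_STONE", "NO_GTUBE", "AGE_RANGE", "STUDY_PERIOD",
    "ASYNCHRONOUS", "INADEQUATE_DATA", "NO_CONTROL")
}

#' @rdname case_labels
#' @export
control_labels <- function() {
  c("ELIGIBLE", "NO_GTUBE", "ASYNCHRONOUS", "INADEQUATE_DATA")
}

# attrition-table row order (exclusions only)
case_exclusion_order <- function() {
  c("NO_STONE", "NO_GTUBE", "AGE_RANGE", "STUDY_PERIOD",
    "ASYNCHRONOUS", "INADEQUATE_DATA", "NO_CONTROL")
}

control_exclusion_order <- function() {
  c("NO_GTUBE", "ASYNCHRONOUS", "INADEQUATE_DATA")
}

# labels attributed to inaccurate billing codes rather than clinical criteria
inaccurate_code_labels <- function() {
  c("NO_STONE", "NO_GTUBE")
}
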